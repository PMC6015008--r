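# Gaze-table input/output -------------------------------------------------

GAZE_COLUMNS <- c("participant_id", "age_group", "phase", "block", "trial_idx",
                  "condition", "t_ms", "left_pupil_mm", "right_pupil_mm",
                  "left_valid", "right_valid", "on_screen")

empty_gaze_table <- function() {
  data.table::data.table(
    participant_id = character(0), age_group = character(0),
    phase = character(0), block = integer(0), trial_idx = integer(0),
    condition = character(0), t_ms = numeric(0),
    left_pupil_mm = numeric(0), right_pupil_mm = numeric(0),
    left_valid = logical(0), right_valid = logical(0), on_screen = logical(0)
  )
}

as_gaze_dataset <- function(dt, seed = NA_integer_, config_hash = NA_character_,
                            sampling_rate = 120) {
  data.table::setattr(dt, "seed", seed)
  data.table::setattr(dt, "config_hash", config_hash)
  data.table::setattr(dt, "sampling_rate", sampling_rate)
  data.table::setattr(dt, "class", c("gaze_dataset", class(dt)))
  dt
}

#' Column schema for gaze exports
#'
#' Maps the canonical column names to the names used in a particular export
#' dialect, and defines how validity is coded. Real exports can therefore be
#' adapted by configuration rather than code.
#'
#' @param columns Named character vector, `canonical = file_column`.
#' @param valid_codes Values of the validity columns that count as valid.
#'   The default accepts logicals and the strings/numbers commonly used.
#' @return A list of class `gaze_schema`.
#' @export
gaze_schema <- function(columns = NULL, valid_codes = c("TRUE", "true", "1")) {
  cols <- stats::setNames(GAZE_COLUMNS, GAZE_COLUMNS)
  if (!is.null(columns)) {
    unknown <- setdiff(names(columns), GAZE_COLUMNS)
    if (length(unknown)) {
      stop("unknown canonical columns in schema: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cols[names(columns)] <- columns
  }
  structure(list(columns = cols, valid_codes = valid_codes),
            class = "gaze_schema")
}

#' Write a gaze dataset as tab-separated text
#'
#' Canonical column order, UTF-8, `.` decimal separator, missing diameters as
#' empty fields. Leading `#` comment lines record the generator seed and the
#' configuration hash so an export is traceable.
#'
#' @param dataset A `gaze_dataset` or plain `data.table` with the canonical
#'   columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(dataset, path) {
  missing_cols <- setdiff(GAZE_COLUMNS, names(dataset))
  if (length(missing_cols)) {
    stop("dataset lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  header <- c(
    "# switchpupil gaze export v1",
    sprintf("# seed: %s", attr(dataset, "seed") %||% NA),
    sprintf("# config_hash: %s", attr(dataset, "config_hash") %||% NA),
    sprintf("# sampling_rate: %s", attr(dataset, "sampling_rate") %||% 120)
  )
  con <- file(path, open = "wb")
  writeLines(header, con)
  close(con)
  data.table::fwrite(
    dataset[, GAZE_COLUMNS, with = FALSE], path,
    sep = "\t", na = "", quote = FALSE, append = TRUE,
    col.names = TRUE, logical01 = FALSE
  )
  invisible(path)
}

#' Read a gaze export table
#'
#' Reads the tab-separated dialect written by [write_gaze_table()] (or any
#' delimited export adapted via a [gaze_schema()]), coerces validity flags,
#' enforces the per-sample invariants, and returns the long sample table.
#'
#' Rows violating the "diameter present iff validity flag set" invariant are
#' rejected: the offending eye is marked invalid, and the affected file line
#' numbers are reported via a message and the `"rejected_lines"` attribute.
#' Diameters outside (0, 10) mm are treated the same way. Non-monotone
#' timestamps within a trial are a data error; trials longer than the nominal
#' duration are truncated to the nominal sample count.
#'
#' @param path File path.
#' @param schema A [gaze_schema()].
#' @param trial_duration_ms Named nominal durations per phase, used to cap
#'   the number of accepted samples per trial (960 for an 8-s test trial at
#'   120 Hz).
#' @return A `gaze_dataset` with attributes recovered from the file header.
#' @export
read_gaze_table <- function(path, schema = gaze_schema(),
                            trial_duration_ms = c(test = 8000,
                                                  familiarization = 9000)) {
  stopifnot(inherits(schema, "gaze_schema"))
  head_lines <- readLines(path, n = 50L)
  n_comment <- 0L
  while (n_comment < length(head_lines) &&
         startsWith(head_lines[n_comment + 1L], "#")) {
    n_comment <- n_comment + 1L
  }
  hdr <- head_lines[seq_len(n_comment)]
  grab <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }

  dt <- data.table::fread(path, sep = "\t", skip = n_comment, na.strings = "",
                          colClasses = list(character = schema$columns[["condition"]]))
  file_cols <- schema$columns
  missing_cols <- setdiff(unname(file_cols), names(dt))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt <- dt[, unname(file_cols), with = FALSE]
  data.table::setnames(dt, unname(file_cols), names(file_cols))

  coerce_valid <- function(x) {
    if (is.logical(x)) return(!is.na(x) & x)
    as.character(x) %in% schema$valid_codes
  }
  dt[, left_valid := coerce_valid(left_valid)]
  dt[, right_valid := coerce_valid(right_valid)]
  dt[, on_screen := coerce_valid(on_screen)]
  dt[, block := as.integer(block)]
  dt[, trial_idx := as.integer(trial_idx)]
  dt[, t_ms := as.numeric(t_ms)]
  dt[, left_pupil_mm := as.numeric(left_pupil_mm)]
  dt[, right_pupil_mm := as.numeric(right_pupil_mm)]

  # line number of each sample in the source file (header + column row)
  dt[, .line := seq_len(.N) + n_comment + 1L]

  rejected <- integer(0)
  for (eye in c("left", "right")) {
    vcol <- paste0(eye, "_valid")
    pcol <- paste0(eye, "_pupil_mm")
    bad <- dt[[vcol]] & (is.na(dt[[pcol]]) | dt[[pcol]] <= 0 | dt[[pcol]] >= 10)
    if (any(bad)) {
      rejected <- union(rejected, dt$.line[bad])
      data.table::set(dt, which(bad), vcol, FALSE)
      data.table::set(dt, which(bad), pcol, NA_real_)
    }
    # diameter present without validity: drop the stray value
    stray <- !dt[[vcol]] & !is.na(dt[[pcol]])
    if (any(stray)) data.table::set(dt, which(stray), pcol, NA_real_)
  }
  if (length(rejected)) {
    message(sprintf("read_gaze_table: rejected %d malformed row(s) (lines %s)",
                    length(rejected),
                    paste(utils::head(sort(rejected), 10), collapse = ", ")))
  }

  keys <- c("participant_id", "phase", "trial_idx")
  bad_t <- dt[, .(bad = any(diff(t_ms) <= 0)), by = keys][bad == TRUE]
  if (nrow(bad_t)) {
    stop("data error: non-monotone timestamps within trial(s): ",
         paste(bad_t$participant_id, bad_t$phase, bad_t$trial_idx,
               sep = "/", collapse = "; "), call. = FALSE)
  }

  rate <- suppressWarnings(as.numeric(grab("sampling_rate")))
  if (is.na(rate)) rate <- if (nrow(dt)) infer_rate(dt$t_ms[dt$.line <= min(dt$.line) + 200]) else 120

  if (!is.null(trial_duration_ms) && nrow(dt)) {
    dt[, .keep := TRUE]
    for (ph in names(trial_duration_ms)) {
      cap <- ceiling(trial_duration_ms[[ph]] * rate / 1000)
      dt[phase == ph, .keep := seq_len(.N) <= cap, by = keys]
    }
    n_drop <- sum(!dt$.keep)
    if (n_drop > 0) {
      message(sprintf("read_gaze_table: dropped %d sample(s) beyond nominal trial duration", n_drop))
      dt <- dt[.keep == TRUE]
    }
    dt[, .keep := NULL]
  }
  dt[, .line := NULL]

  seed <- suppressWarnings(as.integer(grab("seed")))
  out <- as_gaze_dataset(dt, seed = seed, config_hash = grab("config_hash"),
                         sampling_rate = rate)
  if (length(rejected)) data.table::setattr(out, "rejected_lines", rejected)
  out
}
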