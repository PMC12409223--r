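#' Time-resolved delivery log
#'
#' A delivery log is the machine record of one field delivery: 1 kHz samples
#' of two independent cumulative dose-monitor channels (monitor units, MU),
#' the raw Hall-sensor readings of the two scanning magnets (U horizontal,
#' T vertical), and time stamps at 0.1 ms resolution.  Sampling starts when
#' the patient field is loaded, so the record may begin (and end) with
#' beam-off samples.
#'
#' @param field_id Character identifier of the field.
#' @param gantry_angle,couch_angle Angles in degrees.
#' @param arm Delivery arm, `"CONV"` or `"UHDR"`.
#' @param samples Data frame with columns `t_ms`, `mon1`, `mon2`, `hallU`,
#'   `hallT`.  Times must be non-negative multiples of 0.1 ms, strictly
#'   increasing with spacing equal to `sample_period` (within 0.05 ms); both
#'   monitor channels must be non-negative and non-decreasing (cumulative).
#' @param sample_period Nominal sample spacing in ms (default 1.0 = 1 kHz).
#' @param annotations Character vector of free-text event annotations
#'   (e.g. documented interlocks).
#'
#' @return An object of class `delivery_log`.
#' @seealso [read_delivery_log()], [write_delivery_log()], [validate_log()]
#' @export
delivery_log <- function(field_id, gantry_angle, couch_angle,
                         arm = c("CONV", "UHDR"), samples,
                         sample_period = 1.0, annotations = character()) {
  arm <- match.arg(arm)
  stopifnot(is.data.frame(samples))
  required <- c("t_ms", "mon1", "mon2", "hallU", "hallT")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  log <- structure(
    list(
      field_id = as.character(field_id),
      gantry_angle = as.numeric(gantry_angle),
      couch_angle = as.numeric(couch_angle),
      arm = arm,
      sample_period = as.numeric(sample_period),
      samples = samples[required],
      annotations = as.character(annotations)
    ),
    class = "delivery_log"
  )
  violations <- validate_log(log)
  if (length(violations) > 0) {
    stop("invalid delivery log: ", paste(violations, collapse = "; "))
  }
  check_monitor_consistency(log)
  log
}

#' Validate a delivery log against its recording contract
#'
#' Checks every invariant of the log data model and reports violations
#' without raising: non-negative 0.1 ms-quantized times, strictly increasing
#' sample times with spacing equal to the nominal period within 0.05 ms, and
#' non-negative, non-decreasing (cumulative) monitor channels.
#'
#' @param log A `delivery_log` (or a list shaped like one).
#' @return Character vector of human-readable violations; empty if compliant.
#' @export
validate_log <- function(log) {
  v <- character()
  s <- log$samples
  n <- nrow(s)
  if (n == 0) return(v)
  if (any(s$t_ms < 0)) v <- c(v, "sample time negative")
  q <- s$t_ms / TIME_QUANTUM_MS
  off <- which(abs(q - round(q)) > 1e-6)
  if (length(off) > 0) {
    v <- c(v, sprintf("sample time not a multiple of 0.1 ms at sample %d", off[1]))
  }
  if (n > 1) {
    dt <- diff(s$t_ms)
    if (any(dt <= 0)) {
      v <- c(v, sprintf("sample times not strictly increasing at sample %d",
                        which(dt <= 0)[1] + 1L))
    }
    bad <- which(abs(dt - log$sample_period) > 0.05)
    if (length(bad) > 0) {
      v <- c(v, sprintf("sample spacing %.1f ms differs from period %.1f ms at sample %d",
                        dt[bad[1]], log$sample_period, bad[1] + 1L))
    }
  }
  for (ch in c("mon1", "mon2")) {
    x <- s[[ch]]
    if (any(x < 0)) v <- c(v, sprintf("monitor channel %s negative", ch))
    if (n > 1 && any(diff(x) < 0)) {
      v <- c(v, sprintf("monitor channel not monotone: %s decreases at sample %d",
                        ch, which(diff(x) < 0)[1] + 1L))
    }
  }
  v
}

# The two dose monitors are independent; a relative disagreement of their
# final cumulative counts above 1% is suspicious but not fatal.
check_monitor_consistency <- function(log, tol = 0.01) {
  s <- log$samples
  if (nrow(s) == 0) return(invisible(NULL))
  m1 <- s$mon1[nrow(s)]
  m2 <- s$mon2[nrow(s)]
  if (m1 > 0 && abs(m1 - m2) / m1 > tol) {
    warning(sprintf(
      "dose monitor channels disagree: final mon1 = %.6g MU, mon2 = %.6g MU (%.1f%% relative)",
      m1, m2, 100 * abs(m1 - m2) / m1))
  }
  invisible(NULL)
}

#' @export
print.delivery_log <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<delivery_log> field %s  arm %s  gantry %g deg  couch %g deg\n",
              x$field_id, x$arm, x$gantry_angle, x$couch_angle))
  cat(sprintf("  %d samples at %g ms; total MU (mon1): %.6g\n",
              nrow(s), x$sample_period, if (nrow(s)) s$mon1[nrow(s)] else 0))
  if (length(x$annotations)) {
    cat("  annotations:", paste(x$annotations, collapse = " | "), "\n")
  }
  invisible(x)
}

LOG_MAGIC <- "#FLASHQA-LOG v1"

#' Write a delivery log to its plain-text file format
#'
#' The log dialect is UTF-8 text: a magic first line, a single-line JSON
#' header (field metadata), then a CSV table `t_ms,mon1,mon2,hallU,hallT`.
#' Times are printed with exactly one decimal digit (0.1 ms quantum);
#' monitor and Hall values round-trip at full double precision.
#'
#' @param log A valid `delivery_log`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_delivery_log <- function(log, path) {
  stopifnot(inherits(log, "delivery_log"))
  violations <- validate_log(log)
  if (length(violations) > 0) {
    stop("refusing to write invalid log: ", paste(violations, collapse = "; "))
  }
  header <- jsonlite::toJSON(
    list(field_id = log$field_id, gantry_angle = log$gantry_angle,
         couch_angle = log$couch_angle, arm = log$arm,
         sample_period_ms = log$sample_period,
         annotations = as.list(log$annotations)),
    auto_unbox = TRUE, digits = NA)
  s <- log$samples
  rows <- sprintf("%.1f,%s,%s,%s,%s", s$t_ms,
                  fmt_full(s$mon1), fmt_full(s$mon2),
                  fmt_full(s$hallU), fmt_full(s$hallT))
  writeLines(c(LOG_MAGIC, as.character(header),
               "t_ms,mon1,mon2,hallU,hallT", rows), path, useBytes = TRUE)
  invisible(path)
}

# shortest decimal representation that round-trips a double
fmt_full <- function(x) sprintf("%.17g", x)

#' Read a delivery log file
#'
#' Parses and validates a log file written in the package's log dialect
#' (see [write_delivery_log()]).  Malformed headers or rows raise a parse
#' error naming the offending line; invariant violations raise a validation
#' error naming the violated invariant.
#'
#' @param path Path to a log file.
#' @return A validated `delivery_log`.
#' @export
read_delivery_log <- function(path) {
  if (!file.exists(path)) stop("log file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("parse error: file too short (line 1-3 expected)")
  if (lines[1] != LOG_MAGIC) {
    stop("parse error at line 1: expected '", LOG_MAGIC, "'")
  }
  header <- tryCatch(jsonlite::fromJSON(lines[2]),
                     error = function(e) stop("parse error at line 2: invalid JSON header (",
                                              conditionMessage(e), ")"))
  if (lines[3] != "t_ms,mon1,mon2,hallU,hallT") {
    stop("parse error at line 3: expected CSV header 't_ms,mon1,mon2,hallU,hallT'")
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) > 0) {
    fields <- strsplit(body, ",", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 5)) {
      stop(sprintf("parse error at line %d: expected 5 comma-separated values, got %d",
                   which(nf != 5)[1] + 3L, nf[nf != 5][1]))
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 5, byrow = TRUE)
    if (anyNA(m)) {
      stop(sprintf("parse error at line %d: non-numeric value",
                   which(rowSums(is.na(m)) > 0)[1] + 3L))
    }
    samples <- data.frame(t_ms = m[, 1], mon1 = m[, 2], mon2 = m[, 3],
                          hallU = m[, 4], hallT = m[, 5])
  } else {
    samples <- data.frame(t_ms = numeric(), mon1 = numeric(), mon2 = numeric(),
                          hallU = numeric(), hallT = numeric())
  }
  delivery_log(field_id = header$field_id,
               gantry_angle = header$gantry_angle,
               couch_angle = header$couch_angle,
               arm = header$arm,
               samples = samples,
               sample_period = header$sample_period_ms,
               annotations = unlist(header$annotations) %||% character())
}

# Per-sample monitor increments (first sample's increment is its cumulative
# value: accrual since field load).
monitor_increments <- function(log, channel = "mon1") {
  x <- log$samples[[channel]]
  if (length(x) == 0) return(numeric())
  c(x[1], diff(x))
}
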