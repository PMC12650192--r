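#' Construct a breath recording
#'
#' A breath recording is one session's synchronized pressure, temperature and
#' relative-humidity series sampled at a fixed rate, together with subject and
#' session identity. Gaps and missing values are rejected at construction:
#' silent imputation would corrupt cycle timing downstream.
#'
#' @param pressure Numeric series in hPa.
#' @param temperature Numeric series in degrees Celsius.
#' @param humidity Numeric series in %RH.
#' @param fs Sampling rate in Hz (default 10).
#' @param subject_id,session_id Identity strings.
#' @param t0 Session start time in seconds (default 0).
#' @param preprocessed Logical provenance flag; set by
#'   [preprocess_recording()].
#'
#' @return An object of class `breath_recording`: a list with elements
#'   `subject_id`, `session_id`, `fs`, `t0`, `pressure`, `temperature`,
#'   `humidity` and `preprocessed`.
#' @seealso [read_recording()], [write_recording()], [preprocess_recording()]
#' @export
#' @examples
#' t <- seq(0, 59.9, by = 0.1)
#' rec <- breath_recording(
#'   pressure = 1013 - 0.3 * sin(2 * pi * 0.2 * t),
#'   temperature = 27 + 3 * sin(2 * pi * 0.2 * t),
#'   humidity = 70 + 20 * sin(2 * pi * 0.2 * t)
#' )
#' rec
breath_recording <- function(pressure, temperature, humidity, fs = 10,
                             subject_id = "S01", session_id = "R1", t0 = 0,
                             preprocessed = FALSE) {
  series <- list(pressure = pressure, temperature = temperature,
                 humidity = humidity)
  n <- unique(lengths(series))
  if (length(n) != 1L)
    bf_stop("pressure, temperature and humidity must have equal length",
            "bf_data_error")
  if (n < 1L)
    bf_stop("recording must contain at least one sample", "bf_data_error")
  if (any(vapply(series, function(x) anyNA(x) || !is.numeric(x), logical(1))))
    bf_stop("recording series must be numeric with no missing values",
            "bf_data_error")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    bf_stop("fs must be a single positive number", "bf_config_error")
  structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         fs = as.numeric(fs), t0 = as.numeric(t0),
         pressure = as.numeric(pressure),
         temperature = as.numeric(temperature),
         humidity = as.numeric(humidity),
         preprocessed = isTRUE(preprocessed)),
    class = "breath_recording")
}

#' @export
print.breath_recording <- function(x, ...) {
  n <- length(x$pressure)
  cat(sprintf("<breath_recording> %s/%s: %d samples at %g Hz (%.1f s)%s\n",
              x$subject_id, x$session_id, n, x$fs, n / x$fs,
              if (x$preprocessed) ", preprocessed" else ""))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A [breath_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$pressure)

# sample i (1-based) covers time t0 + (i - 1) / fs
rec_times <- function(rec) rec$t0 + (seq_len(n_samples(rec)) - 1) / rec$fs

#' Read a recording from delimited text
#'
#' Expects a header naming time, pressure, temperature and humidity columns
#' (canonically `time_s,pressure_hpa,temperature_c,humidity_rh`); a `schema`
#' map remaps foreign column names. Time must increase at a constant step:
#' the sampling rate is inferred from the median step and every step must
#' agree with it within 1%. Missing cells are an error, never interpolated.
#'
#' @param path File path.
#' @param schema Optional named character vector mapping the canonical names
#'   `time`, `pressure`, `temperature`, `humidity` to the file's column names.
#' @param fs Declared sampling rate in Hz, checked against the inferred rate
#'   within 1%; `NULL` (default) accepts the inferred rate.
#' @param subject_id,session_id Identity assigned to the recording.
#' @return A [breath_recording()].
#' @export
read_recording <- function(path, schema = NULL, fs = NULL,
                           subject_id = "S01", session_id = "R1") {
  cols <- c(time = "time_s", pressure = "pressure_hpa",
            temperature = "temperature_c", humidity = "humidity_rh")
  if (!is.null(schema)) cols[names(schema)] <- schema
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(cols), names(df))
  if (length(missing))
    bf_stop(paste("missing column(s):", paste(missing, collapse = ", ")),
            "bf_schema_error")
  df <- df[, unname(cols)]
  names(df) <- names(cols)
  if (anyNA(df))
    bf_stop("recording file contains missing values", "bf_data_error")
  dt <- diff(df$time)
  if (length(dt) == 0L)
    bf_stop("recording must contain at least two samples to infer fs",
            "bf_format_error")
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > 0.01 * step))
    bf_stop("time column must increase at a constant step (within 1%)",
            "bf_format_error")
  fs_inf <- 1 / step
  if (!is.null(fs) && abs(fs_inf - fs) > 0.01 * fs)
    bf_stop(sprintf("inferred rate %.4g Hz disagrees with declared %g Hz",
                    fs_inf, fs), "bf_format_error")
  breath_recording(df$pressure, df$temperature, df$humidity,
                   fs = fs %||% fs_inf, subject_id = subject_id,
                   session_id = session_id, t0 = df$time[1])
}

#' Write a recording to delimited text
#'
#' Columns `time_s,pressure_hpa,temperature_c,humidity_rh`, UTF-8, "."
#' decimal, LF line ends. Floats are printed with 17 significant digits so
#' that a read-back reproduces the series bit for bit.
#'
#' @param rec A [breath_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "breath_recording"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c("time_s,pressure_hpa,temperature_c,humidity_rh",
             paste(fmt(rec_times(rec)), fmt(rec$pressure),
                   fmt(rec$temperature), fmt(rec$humidity), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
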