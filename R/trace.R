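#' Uniformly sampled electrophysiological trace
#'
#' A trace is a tibble with columns `time_ms` and `value`, carrying the
#' sampling interval, recording mode and units as attributes. Current-clamp
#' traces are in mV, voltage-clamp traces in pA.
#'
#' @param samples Numeric vector of samples (mV or pA).
#' @param dt Sampling interval, ms.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param units `"mV"` or `"pA"`; defaults to the unit implied by `mode`.
#' @param meta Named list of free-form metadata (holding potential, pipette
#'   chloride, junction offset applied, seed, ...).
#'
#' @return A tibble of class `ephys_trace`.
#' @export
#' @examples
#' tr <- new_trace(rnorm(1000, -55), dt = 0.1, mode = "current_clamp")
new_trace <- function(samples, dt, mode = c("current_clamp", "voltage_clamp"),
                      units = NULL, meta = list()) {
  mode <- match.arg(mode)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number (ms)", class = "chloridyn_invalid_parameter")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite", class = "chloridyn_invalid_parameter")
  }
  if (is.null(units)) units <- if (mode == "current_clamp") "mV" else "pA"
  expected <- if (mode == "current_clamp") "mV" else "pA"
  if (units != expected) {
    abort(sprintf("units `%s` inconsistent with mode `%s`", units, mode),
          class = "chloridyn_invalid_parameter")
  }
  out <- tibble(time_ms = (seq_along(samples) - 1) * dt, value = as.numeric(samples))
  structure(out, dt = dt, mode = mode, units = units, meta = meta,
            class = c("ephys_trace", class(out)))
}

trace_dt <- function(trace) attr(trace, "dt")
trace_mode <- function(trace) attr(trace, "mode")

assert_trace <- function(trace, mode = NULL) {
  if (!inherits(trace, "ephys_trace")) {
    abort("expected an `ephys_trace` (see `new_trace()`)",
          class = "chloridyn_invalid_parameter")
  }
  if (!is.null(mode) && trace_mode(trace) != mode) {
    abort(sprintf("expected a %s trace", gsub("_", "-", mode)),
          class = "chloridyn_invalid_parameter")
  }
  invisible(trace)
}

#' Read / write the two-column trace format
#'
#' Plain-text time series: a header block of `# key=value` lines (at least
#' `dt`, `mode`, `units`) followed by two tab-separated columns `time_ms`
#' and `value`. Values round-trip bit-exactly through [write_trace()] /
#' [read_trace()] (full double precision is written).
#'
#' @param trace An `ephys_trace`.
#' @param path File path.
#'
#' @return `read_trace()` returns an `ephys_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  assert_trace(trace)
  meta <- attr(trace, "meta")
  hdr <- c(
    sprintf("# dt=%s", format(trace_dt(trace), digits = 17)),
    sprintf("# mode=%s", trace_mode(trace)),
    sprintf("# units=%s", attr(trace, "units")),
    vapply(names(meta), function(k) sprintf("# %s=%s", k, format(meta[[k]], digits = 17)),
           character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_ms\tvalue", con)
  writeLines(sprintf("%s\t%s",
                     format(trace$time_ms, digits = 17, trim = TRUE, scientific = FALSE),
                     format(trace$value, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  meta <- setNames(lapply(kv, function(x) x[2]), vapply(kv, `[`, character(1), 1))
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t")
  core <- c("dt", "mode", "units")
  extra <- meta[setdiff(names(meta), core)]
  extra <- lapply(extra, function(x) {
    y <- suppressWarnings(as.numeric(x))
    if (is.na(y)) x else y
  })
  new_trace(dat$value, dt = as.numeric(meta$dt), mode = meta$mode,
            units = meta$units, meta = extra)
}

# Strictly causal floating average over `window_n` samples (emulating the
# online detector hardware): m[i] = mean(x[max(1, i-n+1) .. i]).
causal_moving_average <- function(x, window_n) {
  n <- length(x)
  if (window_n > n) {
    abort("averaging window longer than trace", class = "chloridyn_config_error")
  }
  cs <- cumsum(x)
  m <- numeric(n)
  i <- seq_len(n)
  full <- i >= window_n
  m[full] <- (cs[i[full]] - c(0, cs)[i[full] - window_n + 1]) / window_n
  m[!full] <- cs[i[!full]] / i[!full]
  m
}
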