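# Internal helpers: typed errors, numeric parsing, float formatting.

#' @keywords internal
abort_tmr <- function(msg, class) {
  stop(structure(
    class = c(class, "targetmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# 97.5% standard normal quantile used for all 95% intervals, including
# CI -> SE recovery, so that reconstruction round-trips are exact.
Z975 <- 1.959964

#' @keywords internal
z_quantile <- function(ci_level) {
  if (identical(ci_level, 0.95)) Z975 else stats::qnorm(1 - (1 - ci_level) / 2)
}

# Accept unicode minus (U+2212) and scientific notation on parse.
#' @keywords internal
parse_num <- function(x) {
  x <- gsub("−", "-", as.character(x))
  suppressWarnings(as.numeric(x))
}

# ASCII float formatting that survives a write -> read round trip
# (>= 15 significant digits).
#' @keywords internal
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.15g", x))
  out
}

#' @keywords internal
two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
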