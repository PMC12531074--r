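#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft nextn median approx rnorm runif rpois rgamma setNames quantile IQR
#' @importFrom utils head tail modifyList read.csv write.csv
#' @importFrom graphics hist
NULL

stop_if <- function(cond, msg, ...) if (cond) stop(sprintf(msg, ...), call. = FALSE)

#' Peak cross-correlation lag between two signals
#'
#' Computes the unnormalised cross-correlation r(l) = sum_t x(t) y(t + l)
#' over lags `-max_lag..max_lag` via FFT and returns the lag of its maximum.
#' Sign convention: a positive lag means `y` is a delayed copy of `x`
#' (i.e. `x` leads `y`); a negative lag means `y` leads.
#'
#' @param x,y numeric signal vectors (need not be the same length).
#' @param max_lag maximum absolute lag, in samples.
#' @return list with `lag` (samples), `corr` (peak correlation, normalised by
#'   the signal energies so that identical aligned signals give 1).
#' @export
xcorr_lag <- function(x, y, max_lag) {
  stop_if(length(x) < 2 || length(y) < 2, "xcorr_lag: signals too short")
  stop_if(max_lag < 0, "xcorr_lag: max_lag must be >= 0")
  n <- max(length(x), length(y))
  nfft <- stats::nextn(n + max_lag + 1, 2)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  Y <- stats::fft(c(y, numeric(nfft - length(y))))
  r <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  lags <- (-max_lag):max_lag
  idx <- ifelse(lags >= 0, lags + 1L, nfft + lags + 1L)
  vals <- r[idx]
  k <- which.max(vals)
  denom <- sqrt(sum(x^2) * sum(y^2))
  list(lag = lags[k], corr = if (denom > 0) vals[k] / denom else 0)
}

# Maximal runs of TRUE in a logical vector -> data.frame(first, last) (1-based,
# inclusive indices). NA counts as FALSE.
logical_runs <- function(mask) {
  mask <- !is.na(mask) & mask
  if (!any(mask)) {
    return(data.frame(first = integer(0), last = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts[r$values], last = ends[r$values])
}

# Linear interpolation of NA runs shorter than maxgap samples (interior only).
interp_short_gaps <- function(x, maxgap) {
  if (all(is.na(x)) || !anyNA(x)) return(x)
  as.numeric(zoo::na.approx(x, maxgap = maxgap, na.rm = FALSE))
}

# Centered moving median ignoring NAs; width forced odd; shrinking window at
# the edges. Returns NA where the input is NA.
moving_median <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  if (n == 0L || width == 1L) return(x)
  half <- width %/% 2L
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- x[lo:hi]
    if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
  out[is.na(x)] <- NA_real_
  out
}

db <- function(x) 20 * log10(pmax(x, .Machine$double.xmin))
undb <- function(x) 10^(x / 20)

rms <- function(x) sqrt(mean(x^2))

# Integer-sample delay with zero padding, preserving length.
delay_samples <- function(x, d) {
  d <- as.integer(round(d))
  n <- length(x)
  if (d == 0L) return(x)
  if (d > 0L) c(numeric(min(d, n)), x[seq_len(max(0L, n - d))])
  else c(x[(-d + 1L):n], numeric(min(-d, n)))
}
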