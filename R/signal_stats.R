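#' Convert a load-cell ADC readout to weight
#'
#' The bed's load-cell amplifier reports a signed integer ADC value that is
#' proportional to the applied force; dividing by the calibration ratio
#' yields kilograms. The default ratio is the deployed sensor's calibration
#' constant (negative because the bridge inverts polarity).
#'
#' @param adc_out Integer ADC readout (vectorised).
#' @param ratio Calibration constant (ADC counts per kg); must be non-zero.
#' @return Weight in kg.
#' @export
#' @examples
#' adc_to_weight(-41943)   # 1 kg
adc_to_weight <- function(adc_out, ratio = -41943.0) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio == 0)
    stopf("ratio must be a single non-zero number")
  adc_out / ratio
}

#' Summary statistics of one weight window
#'
#' Computes the median \code{m_w}, the mean and the population standard
#' deviation \code{sigma_w} of the last \code{n} weight samples. At 80 Hz a
#' 40-sample window spans half a second, the cadence at which the bed
#' presence rule is evaluated. Population (not sample) standard deviation
#' is used: the window is a fixed-size signal block feeding a binarisation,
#' not a sample from a larger population.
#'
#' @param weights Numeric vector of exactly \code{n} weight values (kg).
#' @param n Expected window length (default 40).
#' @param window_end_ts Optional timestamp of the newest sample.
#' @return List of class \code{window_stats} with \code{m_w},
#'   \code{mean_w}, \code{sigma_w}, \code{n} and \code{window_end_ts}.
#' @export
window_stats <- function(weights, n = 40L, window_end_ts = NA) {
  if (length(weights) != n)
    stopf("expected exactly %d samples, got %d", n, length(weights))
  structure(
    list(m_w = stats::median(weights), mean_w = mean(weights),
         sigma_w = pop_sd(weights), n = as.integer(n),
         window_end_ts = window_end_ts),
    class = "window_stats")
}

#' Windowed statistics over a full load-cell stream
#'
#' Splits the stream into consecutive non-overlapping blocks of \code{n}
#' samples (the cadence at which a FIFO trigger with wrap-around
#' \code{sample_id} fires) and returns one row of statistics per complete
#' block. A trailing partial block is dropped.
#'
#' @param weights Numeric vector of weights (kg).
#' @param ts Timestamps aligned with \code{weights} (POSIXct or numeric).
#' @param n Window length in samples (default 40).
#' @return data.frame with columns \code{m_w}, \code{mean_w},
#'   \code{sigma_w}, \code{window_end_ts}, \code{n}.
#' @export
loadcell_windows <- function(weights, ts, n = 40L) {
  stopifnot(length(weights) == length(ts))
  k <- length(weights) %/% n
  if (k == 0)
    return(data.frame(m_w = numeric(0), mean_w = numeric(0),
                      sigma_w = numeric(0),
                      window_end_ts = ts[0], n = integer(0)))
  m <- matrix(weights[seq_len(k * n)], nrow = n)
  mu <- colMeans(m)
  sg <- sqrt(colMeans(m^2) - mu^2)
  sg[sg < 0 | is.nan(sg)] <- 0
  med <- apply(m, 2, stats::median)
  data.frame(m_w = med, mean_w = mu, sigma_w = sg,
             window_end_ts = ts[seq_len(k) * n], n = rep(as.integer(n), k))
}

# Between-class variance at every interior bin boundary. Bin membership
# quantises the candidate thresholds to the boundary grid, but the class
# moments are exact (per-bin sums of the raw values, not bin centers).
# Returns sigma_B^2(t) for t = 1..nbins-1 (split after bin t).
otsu_between_var <- function(counts, sums) {
  n <- sum(counts)
  total <- sum(sums)
  t <- seq_len(length(counts) - 1L)
  n0 <- cumsum(counts)[t]; n1 <- n - n0
  s0 <- cumsum(sums)[t]
  w0 <- n0 / n; w1 <- n1 / n
  mu0 <- ifelse(n0 > 0, s0 / n0, 0)
  mu1 <- ifelse(n1 > 0, (total - s0) / n1, 0)
  w0 * w1 * (mu0 - mu1)^2
}

otsu_bins <- function(values, n_bins) {
  lo <- min(values)
  width <- (max(values) - lo) / n_bins
  # floor-based binning, top edge closed; a value equal to an interior
  # boundary falls in the upper bin, matching the ">= threshold" class
  idx <- pmin(floor((values - lo) / width), n_bins - 1L) + 1L
  sums <- numeric(n_bins)
  agg <- rowsum(values, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  list(lo = lo, width = width,
       counts = tabulate(idx, nbins = n_bins), sums = sums)
}

#' Otsu threshold of a one-dimensional value distribution
#'
#' Finds the cut point that maximises the between-class variance
#' \eqn{\sigma_B^2(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} when the values
#' are divided into two clusters, the classic histogram formulation used to
#' binarise a signal — here, to separate the occupied-bed from the
#' empty-bed cluster of windowed load-cell statistics.
#'
#' Values are binned into \code{n_bins} uniform bins over
#' \code{[min, max]}; every interior bin boundary is a candidate threshold
#' and ties are broken toward the smaller threshold. A value equal to the
#' returned threshold falls in the upper class.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (a bin boundary), as a single number.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || diff(range(values)) == 0)
    stopf("degenerate distribution: need at least two distinct finite values")
  b <- otsu_bins(values, n_bins)
  bv <- otsu_between_var(b$counts, b$sums)
  t_star <- which.max(bv)            # first maximum = smaller threshold
  b$lo + t_star * b$width
}

#' Otsu class separability
#'
#' The ratio of the between-class variance at the Otsu threshold to the
#' total variance (Otsu's effectiveness measure, in \[0, 1\]). Values near 1
#' indicate two well-separated clusters; a unimodal Gaussian cannot exceed
#' about 0.64. Used to diagnose degenerate calibration data.
#'
#' @inheritParams otsu_threshold
#' @return Separability in \[0, 1\].
#' @export
otsu_separability <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || diff(range(values)) == 0)
    stopf("degenerate distribution: need at least two distinct finite values")
  b <- otsu_bins(values, n_bins)
  bv <- max(otsu_between_var(b$counts, b$sums))
  tot <- mean((values - mean(values))^2)
  if (tot == 0) 0 else bv / tot
}
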