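FIRSTORDER_FEATURES <- c("Mean", "Median", "Minimum", "Maximum", "Range",
                         "Variance", "StandardDeviation", "Skewness",
                         "Kurtosis", "Energy", "Entropy", "Percentile10",
                         "Percentile90", "InterquartileRange",
                         "MeanAbsoluteDeviation",
                         "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                         "Uniformity")

#' First-order (intensity histogram) features over an ROI
#'
#' Eighteen descriptors of the intensity distribution inside the ROI.
#' Variance, skewness and kurtosis use population (1/n) moments; kurtosis is
#' not excess-corrected. Entropy (bits) and uniformity are computed on the
#' fixed-bin-count discretized histogram (`n_bins` bins over the ROI range).
#' A constant ROI has variance, range and entropy 0 and uniformity 1;
#' skewness and kurtosis are defined as 0 there.
#'
#' @param image numeric matrix
#' @param mask logical matrix on the same grid
#' @param n_bins bins for the entropy/uniformity histogram
#' @return named numeric vector of length 18
#' @export
first_order_features <- function(image, mask, n_bins = 32) {
  x <- image[mask > 0]
  if (length(x) < 2) stopf("first_order_features: ROI must have at least 2 pixels")
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mu)^4) / s^4 else 0
  q <- unname(quantile(x, c(0.1, 0.25, 0.75, 0.9), type = 7))
  core <- x[x >= q[1] & x <= q[4]]
  rmad <- if (length(core)) mean(abs(core - mean(core))) else 0
  p <- tabulate(discretize_values(x, n_bins), n_bins) / n
  p <- p[p > 0]
  c(Mean = mu, Median = median(x), Minimum = min(x), Maximum = max(x),
    Range = max(x) - min(x), Variance = v, StandardDeviation = s,
    Skewness = skew, Kurtosis = kurt, Energy = sum(x^2),
    Entropy = -sum(p * log2(p)), Percentile10 = q[1], Percentile90 = q[4],
    InterquartileRange = q[3] - q[2],
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(x^2)),
    Uniformity = sum(p^2))
}

# fixed-bin-count discretization of raw values onto 1..n_bins
discretize_values <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(1L, length(x)))
  b <- floor(n_bins * (x - lo) / (hi - lo)) + 1L
  pmin(b, n_bins)
}

#' Discretize an image over an ROI with a fixed bin count
#'
#' Gray levels are binned to 1..`n_bins` using the ROI's own min/max
#' (fixed-bin-count convention); pixels outside the ROI are set to 0.
#'
#' @param image numeric matrix
#' @param mask logical matrix
#' @param n_bins number of gray levels
#' @return integer matrix, 0 outside the ROI
#' @export
discretize <- function(image, mask, n_bins = 32) {
  out <- matrix(0L, nrow(image), ncol(image))
  out[mask > 0] <- discretize_values(image[mask > 0], n_bins)
  out
}
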