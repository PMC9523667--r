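FILTER_NAMES <- c("wavelet.LL1", "wavelet.LH1", "wavelet.HL1", "wavelet.HH1",
                  "wavelet.LL2", "wavelet.LH2", "wavelet.HL2", "wavelet.HH2",
                  "log.sigma.1.mm", "log.sigma.2.mm", "gradient", "square",
                  "squareroot", "logarithm")

# one-dimensional Haar analysis step of the stationary (a-trous) wavelet
# transform along rows (dim = 1) or columns (dim = 2); taps at offsets
# {0, step}, edge-replicated
swt_step <- function(m, dim, step, high) {
  sh <- if (dim == 1) shift_rep(m, -step, 0) else shift_rep(m, 0, -step)
  if (high) (m - sh) / 2 else (m + sh) / 2
}

#' The 14-transform filter bank
#'
#' Produces the derived images on which the higher-order features are
#' computed: eight stationary-wavelet sub-bands (separable Haar low/high
#' along the two axes at two decomposition levels; level-2 bands are derived
#' from LL1 with dilated filters), Laplacian-of-Gaussian at two scales
#' (sigma 1 mm and 2 mm, response scaled by sigma^2), gradient magnitude
#' (central differences, per mm), and the square, square-root and logarithm
#' point transforms applied after shifting the image to be nonnegative
#' (subtracting its minimum; the logarithm is log(1 + x) on the shifted
#' image).
#'
#' @param image numeric matrix with finite entries
#' @param spacing mm/pixel (scales the LoG sigmas and the gradient)
#' @return named list of 14 full-size numeric matrices
#' @export
filter_bank <- function(image, spacing = 1) {
  if (!all(is.finite(image))) stopf("filter_bank: non-finite input image")
  L1 <- swt_step(image, 1, 1L, FALSE); H1 <- swt_step(image, 1, 1L, TRUE)
  ll1 <- swt_step(L1, 2, 1L, FALSE); lh1 <- swt_step(L1, 2, 1L, TRUE)
  hl1 <- swt_step(H1, 2, 1L, FALSE); hh1 <- swt_step(H1, 2, 1L, TRUE)
  L2 <- swt_step(ll1, 1, 2L, FALSE); H2 <- swt_step(ll1, 1, 2L, TRUE)
  ll2 <- swt_step(L2, 2, 2L, FALSE); lh2 <- swt_step(L2, 2, 2L, TRUE)
  hl2 <- swt_step(H2, 2, 2L, FALSE); hh2 <- swt_step(H2, 2, 2L, TRUE)
  log1 <- laplacian_of_gaussian(image, sigma_mm = 1, spacing = spacing)
  log2_ <- laplacian_of_gaussian(image, sigma_mm = 2, spacing = spacing)
  gx <- (shift_rep(image, -1, 0) - shift_rep(image, 1, 0)) / (2 * spacing)
  gy <- (shift_rep(image, 0, -1) - shift_rep(image, 0, 1)) / (2 * spacing)
  y <- image - min(image)
  out <- list(ll1, lh1, hl1, hh1, ll2, lh2, hl2, hh2, log1, log2_,
              sqrt(gx^2 + gy^2), y^2, sqrt(y), log1p(y))
  names(out) <- FILTER_NAMES
  out
}

laplacian_of_gaussian <- function(image, sigma_mm, spacing) {
  g <- gaussian_blur(image, sigma_px = sigma_mm / spacing)
  lap <- (shift_rep(g, 1, 0) + shift_rep(g, -1, 0) +
            shift_rep(g, 0, 1) + shift_rep(g, 0, -1) - 4 * g) / spacing^2
  sigma_mm^2 * lap
}
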