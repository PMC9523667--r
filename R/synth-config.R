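BORDER_TYPES <- c("smooth", "lobulated", "spiculated", "indistinct")

#' Configuration of a synthetic mesorectal lymph-node cohort
#'
#' Defines the statistical conditions of the simulated cohort: class sizes,
#' per-class short-diameter distributions (truncated normal), in-plane pixel
#' spacing, the mix of border morphologies, internal signal heterogeneity,
#' additive pixel noise, and the expected number of distractor structures
#' (small bright vessels / adjacent nodes) per image.
#'
#' The defaults emulate the published cohort this workflow targets: 298
#' benign nodes with short diameter 4.83 +/- 1.09 mm on 3--9.42 mm, 306
#' malignant nodes with 5.45 +/- 2.17 mm on 3--14 mm, and an in-plane spacing
#' of 0.5625 mm/pixel (18 cm field of view on a 320 matrix). Border-type
#' mixes and heterogeneity levels encode the qualitative radiology: malignant
#' nodes are more often spiculated or indistinct and carry a more
#' inhomogeneous internal signal.
#'
#' @param n_benign,n_malignant class sizes (counts)
#' @param benign_diam_mean,benign_diam_sd,benign_diam_range short-diameter
#'   distribution of benign nodes, in mm (truncated normal)
#' @param malignant_diam_mean,malignant_diam_sd,malignant_diam_range same for
#'   malignant nodes
#' @param pixel_spacing isotropic in-plane spacing, mm/pixel
#' @param image_size side length of each node chip, pixels
#' @param border_type_probs named list with elements `benign` and `malignant`,
#'   each a probability vector over smooth/lobulated/spiculated/indistinct
#' @param heterogeneity_level named vector `c(benign=, malignant=)`: standard
#'   deviation (intensity units) of the smooth internal texture field
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise
#' @param distractor_rate expected number of distractor ellipses per image
#'   (Poisson)
#' @param seed master seed; per-node seeds are derived from it
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_benign = 298,
                          n_malignant = 306,
                          benign_diam_mean = 4.83,
                          benign_diam_sd = 1.09,
                          benign_diam_range = c(3, 9.42),
                          malignant_diam_mean = 5.45,
                          malignant_diam_sd = 2.17,
                          malignant_diam_range = c(3, 14),
                          pixel_spacing = 0.5625,
                          image_size = 96,
                          border_type_probs = list(
                            benign    = c(smooth = 0.55, lobulated = 0.30,
                                          spiculated = 0.05, indistinct = 0.10),
                            malignant = c(smooth = 0.25, lobulated = 0.30,
                                          spiculated = 0.25, indistinct = 0.20)),
                          heterogeneity_level = c(benign = 4, malignant = 10),
                          noise_sd = 5,
                          distractor_rate = 1,
                          seed = 1L) {
  cfg <- list(n_benign = n_benign, n_malignant = n_malignant,
              benign_diam_mean = benign_diam_mean,
              benign_diam_sd = benign_diam_sd,
              benign_diam_range = benign_diam_range,
              malignant_diam_mean = malignant_diam_mean,
              malignant_diam_sd = malignant_diam_sd,
              malignant_diam_range = malignant_diam_range,
              pixel_spacing = pixel_spacing, image_size = image_size,
              border_type_probs = border_type_probs,
              heterogeneity_level = heterogeneity_level,
              noise_sd = noise_sd, distractor_rate = distractor_rate,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  num <- unlist(cfg[c("n_benign", "n_malignant", "benign_diam_mean",
                      "benign_diam_sd", "benign_diam_range",
                      "malignant_diam_mean", "malignant_diam_sd",
                      "malignant_diam_range", "pixel_spacing", "image_size",
                      "noise_sd", "distractor_rate")])
  if (!all(is.finite(num))) stopf("cohort_config: non-finite value in configuration")
  if (!is_count(cfg$n_benign) || !is_count(cfg$n_malignant))
    stopf("cohort_config: class sizes must be nonnegative integers")
  if (cfg$benign_diam_sd < 0 || cfg$malignant_diam_sd < 0)
    stopf("cohort_config: diameter sd must be nonnegative")
  if (cfg$benign_diam_range[1] > cfg$benign_diam_range[2] ||
      cfg$malignant_diam_range[1] > cfg$malignant_diam_range[2])
    stopf("cohort_config: diameter range must satisfy low <= high")
  if (cfg$pixel_spacing <= 0) stopf("cohort_config: pixel spacing must be positive")
  if (cfg$noise_sd < 0 || cfg$distractor_rate < 0)
    stopf("cohort_config: noise_sd and distractor_rate must be nonnegative")
  for (cl in c("benign", "malignant")) {
    p <- cfg$border_type_probs[[cl]]
    if (is.null(p) || length(p) != 4L || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9 ||
        !identical(names(p), BORDER_TYPES))
      stopf("cohort_config: border_type_probs$%s must be a named probability vector over %s",
            cl, paste(BORDER_TYPES, collapse = "/"))
    if (cfg$heterogeneity_level[[cl]] < 0)
      stopf("cohort_config: heterogeneity_level must be nonnegative")
  }
  invisible(cfg)
}
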