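SHAPE_FEATURES <- c("AreaMm2", "PerimeterMm", "PerimeterAreaRatio",
                    "Circularity", "Sphericity", "EquivalentDiameterMm",
                    "MaximumDiameterMm", "MajorAxisMm", "MinorAxisMm",
                    "Elongation", "Eccentricity", "Extent", "Solidity",
                    "Roundness")

# contour perimeter from the ordered boundary chain, with the
# Vossepoel-Smeulders step weights (0.980 straight, 1.406 diagonal) that
# debias the staircase overestimate of digital contours
contour_perimeter_px <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.numeric(mask), nrow(mask)))[[1]]
  if (nrow(oc) < 2) return(4)  # single pixel: unit square boundary
  d <- oc - oc[c(2:nrow(oc), 1), ]
  steps <- sqrt(rowSums(d^2))
  sum(ifelse(steps > 1.2, 1.406, 0.980) * (steps > 0))
}

#' Morphological (shape) features of an ROI mask
#'
#' Fourteen 2D shape descriptors in physical units: area, contour perimeter,
#' their ratio, circularity (4*pi*A/P^2), sphericity (2*sqrt(pi*A)/P),
#' equivalent and maximum diameters, ellipse-fit major/minor axis lengths
#' (4*sqrt of the second-moment eigenvalues), elongation (minor/major),
#' eccentricity, extent (area over bounding box), solidity (area over convex
#' hull), and roundness (4A / (pi * major^2)). Intensities play no role.
#'
#' @param mask logical matrix, nonempty
#' @param spacing mm/pixel
#' @return named numeric vector of length 14
#' @export
shape_features <- function(mask, spacing) {
  n <- sum(mask)
  if (n == 0) stopf("shape_features: empty mask")
  area <- n * spacing^2
  per <- contour_perimeter_px(mask) * spacing
  co <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(co)
  xc <- co[, 1] - ctr[1]; yc <- co[, 2] - ctr[2]
  cov <- matrix(c(mean(xc^2), mean(xc * yc), mean(xc * yc), mean(yc^2)), 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]) * spacing
  minor <- 4 * sqrt(ev[2]) * spacing
  elong <- if (major > 0) minor / major else 1
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  bbox <- (diff(range(co[, 1])) + 1) * (diff(range(co[, 2])) + 1) * spacing^2
  # convex hull area with a half-perimeter digital correction (Pick-style)
  hull <- grDevices::chull(co)
  hp <- co[hull, , drop = FALSE]
  if (nrow(hp) >= 3) {
    x <- hp[, 1]; y <- hp[, 2]
    a_hull <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    p_hull <- sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1), ])^2)))
    hull_area <- (a_hull + p_hull / 2 + 1) * spacing^2
  } else hull_area <- area
  # maximum diameter over boundary pixel centres
  bd <- co
  if (nrow(bd) > 400) {  # boundary only, for large masks
    er <- shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
      shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1) & mask
    bd <- which(mask & !er, arr.ind = TRUE)
  }
  dmax <- sqrt(max(outer(bd[, 1], bd[, 1], "-")^2 +
                     outer(bd[, 2], bd[, 2], "-")^2)) * spacing
  c(AreaMm2 = area,
    PerimeterMm = per,
    PerimeterAreaRatio = per / area,
    Circularity = 4 * pi * area / per^2,
    Sphericity = 2 * sqrt(pi * area) / per,
    EquivalentDiameterMm = 2 * sqrt(area / pi),
    MaximumDiameterMm = dmax,
    MajorAxisMm = major,
    MinorAxisMm = minor,
    Elongation = elong,
    Eccentricity = ecc,
    Extent = area / bbox,
    Solidity = min(area / hull_area, 1),
    Roundness = if (major > 0) min(4 * area / (pi * major^2), 1) else 1)
}
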