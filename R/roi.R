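#' Parameters of the four ROI-derivation geometries
#'
#' Method 1 traces the node contour (the base mask itself). Method 2 expands
#' the contour outward by `dilation_mm` (the published protocol expands by
#' "about 2--3 mm"; the default is the midpoint, 2.5 mm). Method 3 keeps an
#' annular rim of half-widths `ring_outer_mm` outside and `ring_inner_mm`
#' inside the contour. Method 4 is a filled circle of radius
#' `circle_radius_fraction` times the maximal inscribed radius, centred at
#' the inscribed-circle centre.
#'
#' @param dilation_mm outward expansion of method 2, mm (contract: 2--3 mm)
#' @param ring_outer_mm,ring_inner_mm annulus half-widths of method 3, mm
#' @param circle_radius_fraction method-4 radius as a fraction of the maximal
#'   inscribed radius, in (0, 1]
#' @return an object of class `roi_params`
#' @export
roi_params <- function(dilation_mm = 2.5, ring_outer_mm = 1.0,
                       ring_inner_mm = 1.0, circle_radius_fraction = 0.8) {
  if (!is.finite(dilation_mm) || dilation_mm < 2.0 || dilation_mm > 3.0)
    stopf("roi_params: dilation_mm must lie in [2, 3] mm")
  if (ring_outer_mm <= 0 || ring_inner_mm <= 0)
    stopf("roi_params: ring widths must be positive")
  if (circle_radius_fraction <= 0 || circle_radius_fraction > 1)
    stopf("roi_params: circle_radius_fraction must be in (0, 1]")
  structure(list(dilation_mm = dilation_mm, ring_outer_mm = ring_outer_mm,
                 ring_inner_mm = ring_inner_mm,
                 circle_radius_fraction = circle_radius_fraction),
            class = "roi_params")
}

#' Maximal inscribed circle of a mask
#'
#' The inscribed radius is the maximum over mask pixels of the Euclidean
#' distance to the mask complement (pixel-centre metric); the centre is the
#' pixel attaining it, ties broken by smallest row then smallest column.
#'
#' @param mask logical matrix, nonempty
#' @param spacing mm/pixel
#' @return list with `center` (row, col) and `radius_mm`
#' @export
inscribed_circle <- function(mask, spacing) {
  if (!any(mask)) stopf("inscribed_circle: empty mask")
  dm <- as.matrix(EBImage::distmap(matrix(as.numeric(mask), nrow(mask))))
  r <- max(dm)
  hits <- which(dm == r, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(center = unname(hits[1, ]), radius_mm = r * spacing)
}

#' Derive one of the four ROI variants from a base node mask
#'
#' All distances are Euclidean in physical millimetres via an exact distance
#' transform; a pixel belongs to a distance-thresholded region iff its centre
#' satisfies the threshold.
#'
#' @param base logical matrix: the base (method-1) node mask, a single
#'   connected component
#' @param method 1 (contour), 2 (expanded), 3 (annular rim), 4 (inscribed
#'   circle)
#' @param spacing mm/pixel
#' @param params a [roi_params()]
#' @return logical matrix of the derived ROI
#' @export
derive_roi <- function(base, method, spacing, params = roi_params()) {
  if (!any(base)) stopf("derive_roi: empty base mask")
  method <- as.integer(method)
  if (!method %in% 1:4) stopf("derive_roi: method must be 1, 2, 3 or 4")
  base <- base > 0
  out <- switch(method,
    base,
    { # method 2: expand by dilation_mm
      dist_out <- as.matrix(EBImage::distmap(matrix(as.numeric(!base), nrow(base)))) * spacing
      base | (dist_out <= params$dilation_mm & dist_out > 0)
    },
    { # method 3: annular band around the contour
      dist_out <- as.matrix(EBImage::distmap(matrix(as.numeric(!base), nrow(base)))) * spacing
      dist_in <- as.matrix(EBImage::distmap(matrix(as.numeric(base), nrow(base)))) * spacing
      (!base & dist_out <= params$ring_outer_mm & dist_out > 0) |
        (base & dist_in <= params$ring_inner_mm)
    },
    { # method 4: circle at the inscribed-circle centre
      ic <- inscribed_circle(base, spacing)
      rr <- matrix(seq_len(nrow(base)), nrow(base), ncol(base))
      cc <- matrix(seq_len(ncol(base)), nrow(base), ncol(base), byrow = TRUE)
      d <- sqrt((rr - ic$center[1])^2 + (cc - ic$center[2])^2) * spacing
      circ <- d <= params$circle_radius_fraction * ic$radius_mm
      circ & base  # clipped to the base; no clipping occurs for fractions < 1
    })
  if (!any(out)) stopf("derive_roi: method %d produced an empty ROI", method)
  if (method %in% 2:3) {
    edge <- c(out[1, ], out[nrow(out), ], out[, 1], out[, ncol(out)])
    if (any(edge))
      stopf("derive_roi: method %d ROI truncated by the image boundary", method)
  }
  out
}

#' Simulate re-delineation of a node mask
#'
#' Displaces the mask contour by a smooth random field along the contour
#' normal with RMS amplitude `jitter_mm`, emulating a second manual
#' segmentation session for ICC stability studies. Implemented by
#' thresholding the signed distance transform plus a Gaussian-smoothed random
#' field scaled to the requested RMS amplitude; the largest connected
#' component is returned so the result stays a single region.
#'
#' @param base logical matrix
#' @param jitter_mm RMS contour displacement, mm; 0 returns `base` unchanged
#' @param spacing mm/pixel
#' @param seed integer seed
#' @return logical matrix
#' @export
perturb_mask <- function(base, jitter_mm, spacing, seed) {
  if (jitter_mm < 0) stopf("perturb_mask: jitter_mm must be nonnegative")
  base <- base > 0
  if (jitter_mm == 0) return(base)
  set.seed(as.integer(seed))
  field <- gaussian_blur(matrix(rnorm(length(base)), nrow(base)), sigma_px = 3)
  field <- field / sqrt(mean(field^2)) * jitter_mm
  sdist <- signed_distance_mm(base, spacing)
  out <- (sdist + field) > 0
  out <- largest_component(out, connectivity = 4)
  if (!any(out)) stopf("perturb_mask: jitter emptied the mask")
  out
}
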