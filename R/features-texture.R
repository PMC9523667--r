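GLCM_FEATURES <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                   "ClusterTendency", "Contrast", "Correlation",
                   "DifferenceAverage", "DifferenceEntropy",
                   "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
                   "Imc1", "Imc2", "InverseVariance", "JointAverage",
                   "JointEnergy", "JointEntropy", "MCC",
                   "MaximumProbability", "SumAverage", "SumEntropy",
                   "SumSquares")
GLDM_FEATURES <- c("DependenceEntropy", "DependenceNonUniformity",
                   "DependenceNonUniformityNormalized", "DependenceVariance",
                   "GrayLevelNonUniformity", "GrayLevelVariance",
                   "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
                   "LargeDependenceHighGrayLevelEmphasis",
                   "LargeDependenceLowGrayLevelEmphasis",
                   "LowGrayLevelEmphasis", "SmallDependenceEmphasis",
                   "SmallDependenceHighGrayLevelEmphasis",
                   "SmallDependenceLowGrayLevelEmphasis")
GLRLM_FEATURES <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                    "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                    "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                    "RunEntropy", "RunLengthNonUniformity",
                    "RunLengthNonUniformityNormalized", "RunPercentage",
                    "RunVariance", "ShortRunEmphasis",
                    "ShortRunHighGrayLevelEmphasis",
                    "ShortRunLowGrayLevelEmphasis")
GLSZM_FEATURES <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
                    "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
                    "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
                    "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                    "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
                    "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
                    "ZonePercentage", "ZoneVariance")
NGTDM_FEATURES <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                    "Strength")

GLCM_DIRECTIONS <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

#' Texture-matrix discretization and offset configuration
#'
#' @param n_bins fixed bin count for gray-level discretization within the ROI
#' @param distance co-occurrence offset in pixels
#' @return an object of class `disc_config`
#' @export
disc_config <- function(n_bins = 32, distance = 1) {
  if (!is_count(n_bins) || n_bins < 2) stopf("disc_config: n_bins must be >= 2")
  if (!is_count(distance) || distance < 1) stopf("disc_config: distance must be >= 1")
  structure(list(n_bins = as.integer(n_bins), distance = as.integer(distance)),
            class = "disc_config")
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Pooled symmetric gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs (both inside the ROI) separated by `distance`
#' along the four 2D directions (0, 45, 90, 135 degrees) and their
#' opposites, i.e. all eight ordered offsets, which is the symmetric matrix
#' summed over the four directions.
#'
#' @param bins integer matrix from [discretize()] (0 outside the ROI)
#' @param n_bins number of gray levels
#' @param distance offset in pixels
#' @return `n_bins` x `n_bins` count matrix
#' @export
glcm_matrix <- function(bins, n_bins, distance = 1) {
  P <- matrix(0, n_bins, n_bins)
  for (o in GLCM_DIRECTIONS) {
    sb <- shift_mat(bins, o[1] * distance, o[2] * distance, fill = 0L)
    ok <- bins > 0L & sb > 0L
    if (!any(ok)) next
    idx <- bins[ok] + n_bins * (sb[ok] - 1L)
    cnt <- matrix(tabulate(idx, n_bins * n_bins), n_bins, n_bins)
    P <- P + cnt + t(cnt)
  }
  P
}

glcm_features <- function(P, n_bins) {
  feats <- setNames(numeric(length(GLCM_FEATURES)), GLCM_FEATURES)
  tot <- sum(P)
  if (tot == 0) {  # degenerate ROI (no co-occurring pairs): point-mass convention
    P <- matrix(0, n_bins, n_bins); P[1, 1] <- 1; tot <- 1
  }
  p <- P / tot
  i <- matrix(seq_len(n_bins), n_bins, n_bins)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(n_bins) * px); muy <- sum(seq_len(n_bins) * py)
  sx <- sqrt(sum((seq_len(n_bins) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(n_bins) - muy)^2 * py))
  k_diff <- abs(row(p) - col(p))
  pxmy <- vapply(0:(n_bins - 1), function(k) sum(p[k_diff == k]), numeric(1))
  k_sum <- row(p) + col(p)
  pxpy <- vapply(2:(2 * n_bins), function(k) sum(p[k_sum == k]), numeric(1))
  kd <- 0:(n_bins - 1); ks <- 2:(2 * n_bins)
  da <- sum(kd * pxmy)
  hxy <- -sum(xlog2(p))
  pxy_ind <- outer(px, py)
  hxy1 <- -sum(ifelse(p > 0 & pxy_ind > 0, p * log2(pxy_ind), 0))
  hxy2 <- -sum(xlog2(pxy_ind))
  hx <- -sum(xlog2(px)); hy <- -sum(xlog2(py))
  feats["Autocorrelation"] <- sum(i * j * p)
  feats["ClusterProminence"] <- sum((i + j - mux - muy)^4 * p)
  feats["ClusterShade"] <- sum((i + j - mux - muy)^3 * p)
  feats["ClusterTendency"] <- sum((i + j - mux - muy)^2 * p)
  feats["Contrast"] <- sum((i - j)^2 * p)
  feats["Correlation"] <- if (sx > 0 && sy > 0)
    (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  feats["DifferenceAverage"] <- da
  feats["DifferenceEntropy"] <- -sum(xlog2(pxmy))
  feats["DifferenceVariance"] <- sum((kd - da)^2 * pxmy)
  feats["Id"] <- sum(p / (1 + abs(i - j)))
  feats["Idm"] <- sum(p / (1 + (i - j)^2))
  feats["Idmn"] <- sum(p / (1 + ((i - j) / n_bins)^2))
  feats["Idn"] <- sum(p / (1 + abs(i - j) / n_bins))
  feats["Imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  feats["Imc2"] <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  off <- i != j
  feats["InverseVariance"] <- sum(p[off] / (i[off] - j[off])^2)
  feats["JointAverage"] <- sum(i * p)
  feats["JointEnergy"] <- sum(p^2)
  feats["JointEntropy"] <- hxy
  feats["MCC"] <- glcm_mcc(p, px, py)
  feats["MaximumProbability"] <- max(p)
  feats["SumAverage"] <- sum(ks * pxpy)
  feats["SumEntropy"] <- -sum(xlog2(pxpy))
  feats["SumSquares"] <- sum((i - mux)^2 * p)
  feats
}

# maximal correlation coefficient: sqrt of the second-largest eigenvalue of Q
glcm_mcc <- function(p, px, py) {
  pres <- which(px > 0)
  if (length(pres) < 2) return(1)
  pk <- p[pres, pres, drop = FALSE]
  pxk <- px[pres]; pyk <- py[pres]
  Q <- (pk / pxk) %*% (t(pk) / pyk)
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, min(1, ev[2])))
}

# lines of a matrix along the four run directions, mask-gapped with zeros
run_lines <- function(bins, direction) {
  switch(direction,
         horizontal = split(bins, row(bins)),
         vertical = split(bins, col(bins)),
         diagonal = split(bins, col(bins) - row(bins)),
         antidiagonal = split(bins, col(bins) + row(bins)))
}

#' Pooled gray-level run-length matrix over the four 2D directions
#'
#' @inheritParams glcm_matrix
#' @return `n_bins` x Lmax count matrix (runs pooled over directions)
#' @export
glrlm_matrix <- function(bins, n_bins) {
  vals <- integer(0); lens <- integer(0)
  for (d in c("horizontal", "vertical", "diagonal", "antidiagonal")) {
    for (line in run_lines(bins, d)) {
      r <- rle(as.integer(line))
      keep <- r$values > 0L
      vals <- c(vals, r$values[keep]); lens <- c(lens, r$lengths[keep])
    }
  }
  lmax <- max(lens, 1L)
  matrix(tabulate(vals + n_bins * (lens - 1L), n_bins * lmax), n_bins, lmax)
}

# generic size-distribution features shared by GLRLM / GLSZM / GLDM
size_matrix_features <- function(P, names, np) {
  Nz <- sum(P)
  p <- P / Nz
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  j <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  pg <- rowSums(p); ps <- colSums(p)
  mui <- sum(seq_len(nrow(P)) * pg); muj <- sum(seq_len(ncol(P)) * ps)
  out <- c(
    GLN = sum(rowSums(P)^2) / Nz,
    GLNN = sum(pg^2),
    GLV = sum(p * (i - mui)^2),
    HGLE = sum(p * i^2),
    LE = sum(p * j^2),
    LHGLE = sum(p * i^2 * j^2),
    LLGLE = sum(p * j^2 / i^2),
    LGLE = sum(p / i^2),
    SN = sum(colSums(P)^2) / Nz,
    SNN = sum(ps^2),
    SE_small = sum(p / j^2),
    SHGLE = sum(p * i^2 / j^2),
    SLGLE = sum(p / (i^2 * j^2)),
    ENT = -sum(xlog2(p)),
    PCT = Nz / np,
    SV = sum(p * (j - muj)^2))
  setNames(out, names)
}

glrlm_features <- function(P, np) {
  size_matrix_features(P, np = np,
    names = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelRunEmphasis",
              "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
              "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
              "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
              "ShortRunLowGrayLevelEmphasis", "RunEntropy", "RunPercentage",
              "RunVariance"))[GLRLM_FEATURES]
}

#' Gray-level size-zone matrix (8-connected zones)
#'
#' Zones are connected sets (8-connectivity) of ROI pixels sharing a gray
#' level; the matrix counts zones by (gray level, zone size). All gray
#' levels are labelled in a single graph pass.
#'
#' @inheritParams glcm_matrix
#' @return `n_bins` x Smax count matrix
#' @export
glszm_matrix <- function(bins, n_bins) {
  nr <- nrow(bins)
  idx <- which(bins > 0L)
  if (length(idx) == 0L) stopf("glszm_matrix: empty ROI")
  edges <- integer(0)
  for (o in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb <- idx + o[1] + o[2] * nr
    r <- ((idx - 1L) %% nr) + 1L
    ok <- (r + o[1] >= 1L) & (r + o[1] <= nr) & nb >= 1L & nb <= length(bins)
    ok[ok] <- bins[nb[ok]] == bins[idx[ok]] & bins[nb[ok]] > 0L
    if (any(ok)) edges <- c(edges, rbind(match(idx[ok], idx), match(nb[ok], idx)))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  glev <- bins[idx][match(seq_along(sizes), comp)]
  smax <- max(sizes)
  matrix(tabulate(glev + n_bins * (sizes - 1L), n_bins * smax), n_bins, smax)
}

glszm_features <- function(P, np) {
  size_matrix_features(P, np = np,
    names = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
              "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
              "ZonePercentage", "ZoneVariance"))[GLSZM_FEATURES]
}

NEIGH8 <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 1L),
               c(1L, -1L), c(1L, 0L), c(1L, 1L))

#' Gray-level dependence matrix (dependence threshold alpha = 0)
#'
#' The dependence size of an ROI pixel is 1 (itself) plus the number of its
#' 8-neighbours inside the ROI with an identical discretized gray level.
#'
#' @inheritParams glcm_matrix
#' @return `n_bins` x 9 count matrix (dependence sizes 1..9)
#' @export
gldm_matrix <- function(bins, n_bins) {
  roi <- bins > 0L
  dep <- matrix(1L, nrow(bins), ncol(bins))
  for (o in NEIGH8) {
    sb <- shift_mat(bins, o[1], o[2], fill = 0L)
    dep <- dep + (roi & sb == bins & sb > 0L)
  }
  idx <- which(roi)
  matrix(tabulate(bins[idx] + n_bins * (dep[idx] - 1L), n_bins * 9L), n_bins, 9L)
}

gldm_features <- function(P, np) {
  size_matrix_features(P, np = np,
    names = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized_unused",
              "GrayLevelVariance", "HighGrayLevelEmphasis",
              "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
              "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
              "DependenceNonUniformity", "DependenceNonUniformityNormalized",
              "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
              "SmallDependenceLowGrayLevelEmphasis", "DependenceEntropy",
              "Percent_unused", "DependenceVariance"))[GLDM_FEATURES]
}

#' Neighbourhood gray-tone difference features
#'
#' Uses the 8-connected neighbourhood (Chebyshev radius 1); pixels with no
#' ROI neighbour are excluded. Degenerate single-gray-level ROIs follow the
#' limiting conventions: contrast, busyness and strength are 0 and
#' coarseness is capped at 1e6.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of length 5
#' @export
ngtdm_features <- function(bins, n_bins) {
  roi <- bins > 0L
  nsum <- matrix(0, nrow(bins), ncol(bins))
  ncnt <- matrix(0L, nrow(bins), ncol(bins))
  for (o in NEIGH8) {
    sb <- shift_mat(bins, o[1], o[2], fill = 0L)
    nsum <- nsum + sb
    ncnt <- ncnt + (sb > 0L)
  }
  use <- roi & ncnt > 0L
  gi <- bins[use]
  abar <- nsum[use] / ncnt[use]
  N <- length(gi)
  if (N == 0) return(setNames(c(0, 1e6, 0, 0, 0), NGTDM_FEATURES))
  ni <- tabulate(gi, n_bins)
  si <- vapply(seq_len(n_bins),
               function(g) sum(abs(g - abar[gi == g])), numeric(1))
  pi_ <- ni / N
  pres <- which(ni > 0)
  ngp <- length(pres)
  coarse <- sum(pi_ * si)
  coarseness <- if (coarse > 0) min(1 / coarse, 1e6) else 1e6
  if (ngp > 1) {
    pg <- expand.grid(i = pres, j = pres)
    dij <- pg$i - pg$j
    pipj <- pi_[pg$i] * pi_[pg$j]
    contrast <- sum(pipj * dij^2) / (ngp * (ngp - 1)) * sum(si) / N
    busy_den <- sum(abs(pg$i * pi_[pg$i] - pg$j * pi_[pg$j]))
    busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
    complexity <- sum(abs(dij) * (pi_[pg$i] * si[pg$i] + pi_[pg$j] * si[pg$j]) /
                        (pi_[pg$i] + pi_[pg$j])) / N
    strength <- if (sum(si) > 0)
      sum((pi_[pg$i] + pi_[pg$j]) * dij^2) / sum(si) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  setNames(c(busyness, coarseness, complexity, contrast, strength),
           NGTDM_FEATURES)
}

#' The 75 texture features of one (image, ROI) pair
#'
#' Gray levels are discretized to `disc$n_bins` within the ROI; the five
#' matrix families contribute GLCM 24, GLDM 14, GLRLM 16, GLSZM 16 and
#' NGTDM 5 features. GLCM pairs are counted at `disc$distance` over the four
#' 2D directions, symmetric and pooled; run and zone statistics are pooled
#' over directions / 8-connected components.
#'
#' @param image numeric matrix
#' @param mask logical matrix
#' @param disc a [disc_config()]
#' @return named numeric vector of length 75 (prefixes glcm_/gldm_/glrlm_/glszm_/ngtdm_)
#' @export
texture_features <- function(image, mask, disc = disc_config()) {
  if (sum(mask) < 2) stopf("texture_features: ROI must have at least 2 pixels")
  nb <- disc$n_bins
  bins <- discretize(image, mask, nb)
  np <- sum(mask > 0)
  out <- c(
    setNames(glcm_features(glcm_matrix(bins, nb, disc$distance), nb),
             paste0("glcm_", GLCM_FEATURES)),
    setNames(gldm_features(gldm_matrix(bins, nb), np),
             paste0("gldm_", GLDM_FEATURES)),
    setNames(glrlm_features(glrlm_matrix(bins, nb), np),
             paste0("glrlm_", GLRLM_FEATURES)),
    setNames(glszm_features(glszm_matrix(bins, nb), np),
             paste0("glszm_", GLSZM_FEATURES)),
    setNames(ngtdm_features(bins, nb), paste0("ngtdm_", NGTDM_FEATURES)))
  stopifnot(all(is.finite(out)))
  out
}
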