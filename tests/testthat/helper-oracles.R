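# Fixture builders and independent oracle implementations used across the
# suite. Oracles are deliberately naive (loops, enumeration) so they share
# no code path with the package.

disk_mask <- function(n, radius_px, center = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius_px^2
}

random_blob <- function(n = 32, seed = 1) {
  set.seed(seed)
  m <- disk_mask(n, n / 4)
  noise <- matrix(rnorm(n * n), n, n)
  sm <- as.matrix(EBImage::gblur(noise, sigma = 3))
  blob <- m & (sm > quantile(sm[m], 0.2))
  lab <- nodiomics:::label_components(blob, 4)
  if (max(lab) == 0) return(m)
  sizes <- tabulate(lab[lab > 0])
  blob <- lab == which.max(sizes)
  blob
}

# per-pixel Euclidean distance from each pixel centre to the nearest pixel
# centre of `mask`, by exhaustive search
brute_distance_to_mask <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    out[r, c] <- sqrt(min((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
  out
}

# GLCM count matrix by explicit enumeration of all ordered ROI pixel pairs
# at Chebyshev-direction offsets of the given distance
brute_glcm <- function(bins, distance, n_bins) {
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1),
               c(0, -1), c(-1, 0), c(-1, -1), c(-1, 1))
  P <- matrix(0, n_bins, n_bins)
  nr <- nrow(bins); nc <- ncol(bins)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (bins[r, c] == 0) next
    for (o in offs) {
      r2 <- r + o[1] * distance; c2 <- c + o[2] * distance
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && bins[r2, c2] > 0)
        P[bins[r, c], bins[r2, c2]] <- P[bins[r, c], bins[r2, c2]] + 1
    }
  }
  P
}

# the list of ordered co-occurring bin pairs, for moment-style GLCM oracles
brute_glcm_pairs <- function(bins, distance) {
  P <- brute_glcm(bins, distance, max(bins))
  idx <- which(P > 0, arr.ind = TRUE)
  list(g1 = rep(idx[, 1], P[P > 0]), g2 = rep(idx[, 2], P[P > 0]))
}

# run-length counts by explicit line walking
brute_glrlm <- function(bins, n_bins) {
  nr <- nrow(bins); nc <- ncol(bins)
  runs <- list()
  walk <- function(r, c, dr, dc) {
    out <- integer(0)
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      out <- c(out, bins[r, c]); r <- r + dr; c <- c + dc
    }
    out
  }
  lines <- list()
  for (r in seq_len(nr)) lines <- c(lines, list(walk(r, 1, 0, 1)))
  for (c in seq_len(nc)) lines <- c(lines, list(walk(1, c, 1, 0)))
  for (r in seq_len(nr)) lines <- c(lines, list(walk(r, 1, 1, 1)))
  for (c in seq(2, nc)) lines <- c(lines, list(walk(1, c, 1, 1)))
  for (r in seq_len(nr)) lines <- c(lines, list(walk(r, nc, 1, -1)))
  for (c in seq_len(nc - 1)) lines <- c(lines, list(walk(1, c, 1, -1)))
  vals <- integer(0); lens <- integer(0)
  for (l in lines) {
    i <- 1
    while (i <= length(l)) {
      j <- i
      while (j < length(l) && l[j + 1] == l[i]) j <- j + 1
      if (l[i] > 0) { vals <- c(vals, l[i]); lens <- c(lens, j - i + 1) }
      i <- j + 1
    }
  }
  lmax <- max(lens)
  P <- matrix(0, n_bins, lmax)
  for (i in seq_along(vals)) P[vals[i], lens[i]] <- P[vals[i], lens[i]] + 1
  P
}

# zone sizes by recursive 8-connected flood fill
brute_glszm <- function(bins, n_bins) {
  nr <- nrow(bins); nc <- ncol(bins)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (bins[r, c] == 0 || seen[r, c]) next
    g <- bins[r, c]
    stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            !seen[r2, c2] && bins[r2, c2] == g) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  smax <- max(vapply(zones, `[`, numeric(1), 2))
  P <- matrix(0, n_bins, smax)
  for (z in zones) P[z[1], z[2]] <- P[z[1], z[2]] + 1
  P
}

# trapezoidal area under the empirical ROC curve
brute_auc_trapezoid <- function(scores, labels) {
  y <- as.integer(labels == max(labels))
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(th))
  for (i in seq_along(th)) {
    sens[i] <- mean(scores[y == 1] >= th[i])
    spec[i] <- mean(scores[y == 0] < th[i])
  }
  fpr <- 1 - spec
  sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
}

# DeLong placement values by explicit double loop
brute_delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  psi <- function(x, yv) if (x > yv) 1 else if (x == yv) 0.5 else 0
  v10 <- vapply(pos, function(x) mean(vapply(neg, function(yv) psi(x, yv),
                                             numeric(1))), numeric(1))
  v01 <- vapply(neg, function(yv) mean(vapply(pos, function(x) psi(x, yv),
                                              numeric(1))), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

# ICC(3,1) consistency via R's own ANOVA decomposition
aov_icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- anova(aov(y ~ subject + rater, data = df))
  msr <- tab["subject", "Mean Sq"]; mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse)
}

# radial profile peak count of a mask contour (for border-morphology
# checks); the profile is circularly smoothed and a peak must rise at least
# `prominence` pixels above the mean to discount staircase artefacts
radial_peak_count <- function(mask, n_bins = 24, prominence = 0.5) {
  co <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(co)
  oc <- EBImage::ocontour(matrix(as.numeric(mask), nrow(mask)))[[1]] + 1
  th <- atan2(oc[, 2] - ctr[2], oc[, 1] - ctr[1])
  rad <- sqrt((oc[, 1] - ctr[1])^2 + (oc[, 2] - ctr[2])^2)
  bin <- pmin(floor((th + pi) / (2 * pi) * n_bins) + 1, n_bins)
  prof <- vapply(seq_len(n_bins),
                 function(b) if (any(bin == b)) max(rad[bin == b]) else NA_real_,
                 numeric(1))
  prof <- prof[!is.na(prof)]
  nb <- length(prof)
  sm <- vapply(seq_len(nb), function(i)
    mean(prof[c(((i - 2) %% nb) + 1, i, (i %% nb) + 1)]), numeric(1))
  peaks <- 0
  for (i in seq_len(nb)) {
    prev <- sm[((i - 2) %% nb) + 1]; nxt <- sm[(i %% nb) + 1]
    if (sm[i] > prev && sm[i] >= nxt && sm[i] > mean(sm) + prominence)
      peaks <- peaks + 1
  }
  peaks
}

tiny_cohort <- function(n_per_class = 5, seed = 42, image_size = 64, ...) {
  generate_cohort(cohort_config(n_benign = n_per_class,
                                n_malignant = n_per_class,
                                image_size = image_size, seed = seed, ...))
}
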