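# mean and sd of a normal(mu, sigma) truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  lam <- (dnorm(al) - dnorm(be)) / z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - lam^2)
  c(mean = unname(m), sd = unname(sqrt(max(v, 0))))
}

# underlying normal parameters whose truncation to [a, b] has the target
# mean and sd; published cohort summaries are range-limited statistics, so
# the generator matches the truncated moments, not the untruncated ones
truncnorm_match <- function(mean, sd, range) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), range[1], range[2])
    (mo["mean"] - mean)^2 / sd^2 + (mo["sd"] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

# Exact truncated-normal sampling by inverse-CDF; robust even when the
# matched underlying normal places little mass on the range.
rtruncnorm_rej <- function(n, mean, sd, range) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < range[1] || mean > range[2])
      stopf("degenerate diameter distribution outside its range")
    return(rep(mean, n))
  }
  plo <- pnorm(range[1], mean, sd)
  phi <- pnorm(range[2], mean, sd)
  pmin(pmax(stats::qnorm(runif(n, plo, phi), mean, sd), range[1]), range[2])
}

#' Sample the per-node records of a synthetic cohort
#'
#' Draws node-level attributes (label, short diameter, border morphology,
#' heterogeneity, per-node seed) without rendering any pixel data. Diameters
#' are truncated-normal within the configured class range; border types are
#' drawn from the per-class morphology mix. Per-node seeds are derived from
#' the master seed by index, so a cohort is stable under reordering.
#'
#' @param config a [cohort_config()]
#' @return a data.frame with columns node_id, label, short_diameter_mm,
#'   border_type, heterogeneity, seed, image_ref
#' @export
sample_node_records <- function(config) {
  validate_cohort_config(config)
  n <- config$n_benign + config$n_malignant
  label <- rep(c("benign", "malignant"), c(config$n_benign, config$n_malignant))
  set.seed(mix_seed(config$seed, 0L))
  diam <- numeric(n)
  if (config$n_benign > 0) {
    pb <- if (config$benign_diam_sd > 0)
      truncnorm_match(config$benign_diam_mean, config$benign_diam_sd,
                      config$benign_diam_range)
    else c(mean = config$benign_diam_mean, sd = 0)
    diam[label == "benign"] <- rtruncnorm_rej(
      config$n_benign, pb["mean"], pb["sd"], config$benign_diam_range)
  }
  if (config$n_malignant > 0) {
    pm <- if (config$malignant_diam_sd > 0)
      truncnorm_match(config$malignant_diam_mean, config$malignant_diam_sd,
                      config$malignant_diam_range)
    else c(mean = config$malignant_diam_mean, sd = 0)
    diam[label == "malignant"] <- rtruncnorm_rej(
      config$n_malignant, pm["mean"], pm["sd"], config$malignant_diam_range)
  }
  border <- character(n)
  for (cl in c("benign", "malignant")) {
    k <- sum(label == cl)
    if (k > 0)
      border[label == cl] <- sample(BORDER_TYPES, k, replace = TRUE,
                                    prob = config$border_type_probs[[cl]])
  }
  het <- unname(config$heterogeneity_level[label])
  ids <- sprintf("node%04d", seq_len(n))
  data.frame(node_id = ids, label = label, short_diameter_mm = diam,
             border_type = border, heterogeneity = het,
             seed = vapply(seq_len(n), function(i) mix_seed(config$seed, i),
                           integer(1)),
             image_ref = ids, stringsAsFactors = FALSE)
}

# radius of the node boundary (mm) as a function of polar angle, before
# border-type perturbation: an ellipse with minor diameter = short diameter
ellipse_radius <- function(theta, b, aspect, phi) {
  a <- b * aspect
  t <- theta - phi
  a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
}

#' Render one synthetic lymph node as an image chip and base mask
#'
#' Produces a grayscale chip (background + node signal + smooth internal
#' texture field + pixel noise + distractor ellipses) and the ground-truth
#' base mask. The border morphology controls the contour: smooth nodes are
#' plain ellipses, lobulated nodes carry a low-frequency radial modulation,
#' spiculated nodes carry narrow radial spikes, and indistinct nodes keep a
#' smooth mask but have the node--background transition band blurred in the
#' image. The mask minor axis tracks the record's short diameter.
#'
#' @param record one row of [sample_node_records()]
#' @param config the [cohort_config()]
#' @return list with elements `image` (numeric matrix), `mask` (logical
#'   matrix), `spacing` (mm/pixel)
#' @export
render_node <- function(record, config) {
  sp <- config$pixel_spacing
  sz <- config$image_size
  d_px <- record$short_diameter_mm / sp
  if (d_px < 3) stopf("node %s: short diameter %.2f mm is below the resolvable size at spacing %.4f",
                      record$node_id, record$short_diameter_mm, sp)
  set.seed(record$seed)
  cx <- (sz + 1) / 2 + runif(1, -2, 2)
  cy <- (sz + 1) / 2 + runif(1, -2, 2)
  aspect <- runif(1, 1.0, 1.3)
  phi <- runif(1, 0, pi)
  b <- record$short_diameter_mm / 2

  rr <- matrix(seq_len(sz), sz, sz)
  cc <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
  dx <- (rr - cx) * sp
  dy <- (cc - cy) * sp
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  rfun <- ellipse_radius(theta, b, aspect, phi)
  if (record$border_type == "lobulated") {
    k <- sample(3:5, 1)
    ph2 <- runif(1, 0, 2 * pi)
    rfun <- rfun * (1 + 0.18 * cos(k * theta + ph2))
  } else if (record$border_type == "spiculated") {
    nsp <- sample(4:7, 1)
    ang <- runif(nsp, -pi, pi)
    w <- 0.25
    bump <- 0
    for (a in ang) {
      dtheta <- atan2(sin(theta - a), cos(theta - a))
      bump <- bump + exp(-0.5 * (dtheta / w)^2)
    }
    rfun <- rfun * (1 + 0.30 * pmin(bump, 1))
  }
  mask <- rho <= rfun
  mask <- largest_component(mask, connectivity = 4)
  if (sum(mask) < 5L)
    stopf("node %s: rendered mask too small to analyse", record$node_id)

  img <- matrix(60, sz, sz)
  img[mask] <- img[mask] + 40
  if (record$heterogeneity > 0) {
    field <- gaussian_blur(matrix(rnorm(sz * sz), sz, sz), sigma_px = 2)
    field <- field / stats::sd(field) * record$heterogeneity
    img[mask] <- img[mask] + field[mask]
  }
  # distractors: small bright ellipses whose centres stay clear of the node
  ndis <- rpois(1, config$distractor_rate)
  if (ndis > 0) {
    sdist <- signed_distance_mm(mask, sp)
    cand <- which(sdist < -3)  # at least 3 mm outside the node
    for (i in seq_len(ndis)) {
      if (length(cand) == 0) break
      ctr <- cand[sample.int(length(cand), 1)]
      dr <- ((ctr - 1) %% sz) + 1
      dc <- ((ctr - 1) %/% sz) + 1
      rad <- runif(1, 0.5, 1.25)          # mm
      asp2 <- runif(1, 1, 2)
      ph3 <- runif(1, 0, pi)
      ddx <- (rr - dr) * sp; ddy <- (cc - dc) * sp
      rot <- ddx * cos(ph3) + ddy * sin(ph3)
      ort <- -ddx * sin(ph3) + ddy * cos(ph3)
      dmask <- (rot / (rad * asp2))^2 + (ort / rad)^2 <= 1
      img[dmask & !mask] <- img[dmask & !mask] + 50
    }
  }
  if (record$border_type == "indistinct") {
    sdist <- signed_distance_mm(mask, sp)
    band <- abs(sdist) <= 1.0
    blurred <- gaussian_blur(img, sigma_px = 2)
    img[band] <- blurred[band]
  }
  if (config$noise_sd > 0)
    img <- img + matrix(rnorm(sz * sz, 0, config$noise_sd), sz, sz)
  list(image = img, mask = mask, spacing = sp)
}

#' Generate a labelled synthetic cohort
#'
#' Samples node records with [sample_node_records()] and renders every node
#' with [render_node()]. Identical configuration (including seed) yields a
#' bit-identical cohort.
#'
#' @param config a [cohort_config()]
#' @return an object of class `node_cohort`: list with `records` (data.frame),
#'   `images` and `masks` (named lists of matrices), and `spacing`
#' @export
generate_cohort <- function(config) {
  records <- sample_node_records(config)
  images <- vector("list", nrow(records))
  masks <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- render_node(records[i, ], config)
    images[[i]] <- r$image
    masks[[i]] <- r$mask
  }
  names(images) <- names(masks) <- records$node_id
  structure(list(records = records, images = images, masks = masks,
                 spacing = config$pixel_spacing),
            class = "node_cohort")
}

#' @exportS3Method base::print
print.node_cohort <- function(x, ...) {
  cat(sprintf("Synthetic node cohort: %d nodes (%d malignant, %d benign), spacing %.4f mm/px\n",
              nrow(x$records), sum(x$records$label == "malignant"),
              sum(x$records$label == "benign"), x$spacing))
  invisible(x)
}
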