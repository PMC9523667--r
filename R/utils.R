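#' @importFrom stats rnorm runif rpois quantile var sd median aov anova
#'   pnorm dnorm optim glm binomial predict coef setNames
#' @importFrom utils head read.csv write.csv
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

#' Deterministic child seed derived from a master seed
#'
#' Mixes a master seed with an index so that per-node seeds are stable under
#' reordering of the cohort. Kept strictly below 2^31 so the result is a
#' valid R integer seed.
#'
#' @param master integer master seed
#' @param index positive integer stream index
#' @return an integer seed
#' @keywords internal
mix_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  # two rounds of a multiplicative congruential mix, index-keyed
  s <- (s * 48271 + 7919 * as.numeric(index)) %% m
  s <- (s * 48271 + 104729) %% m
  as.integer(s)
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# shift with edge replication (for filters)
shift_rep <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' @param mask logical or 0/1 matrix
#' @param connectivity 4 or 8
#' @return integer matrix of component labels (0 = background)
#' @keywords internal
label_components <- function(mask, connectivity = 4) {
  mask <- mask > 0
  nr <- nrow(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, ncol(mask))
  if (length(idx) == 0L) return(lab)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (o in offs) {
    nb <- idx + o[1] + o[2] * nr
    r <- ((idx - 1L) %% nr) + 1L
    ok <- (r + o[1] >= 1L) & (r + o[1] <= nr) & nb >= 1L & nb <= length(mask)
    ok[ok] <- mask[nb[ok]]
    if (any(ok)) edges <- c(edges, rbind(match(idx[ok], idx), match(nb[ok], idx)))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

largest_component <- function(mask, connectivity = 4) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Signed Euclidean distance to the mask contour, in millimetres
#'
#' Positive inside the mask, negative outside. Distances are measured between
#' pixel centres via an exact Euclidean distance transform.
#'
#' @keywords internal
signed_distance_mm <- function(mask, spacing) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  inside <- EBImage::distmap(m)
  outside <- EBImage::distmap(1 - m)
  (as.matrix(inside) - as.matrix(outside)) * spacing
}

# separable Gaussian smoothing with edge replication; kernel truncated at
# 3 sigma (works on images smaller than the kernel, unlike brush filters)
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq.int(-r, r), sd = sigma_px)
  k <- k / sum(k)
  pass <- function(x, dim) {
    out <- matrix(0, nrow(x), ncol(x))
    for (o in seq.int(-r, r))
      out <- out + k[o + r + 1] *
        (if (dim == 1) shift_rep(x, o, 0) else shift_rep(x, 0, o))
    out
  }
  pass(pass(m, 1), 2)
}
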