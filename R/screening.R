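#' Two-way consistency intraclass correlation (single measures)
#'
#' ICC of a subjects-by-raters table under the two-way mixed, consistency,
#' single-measure model: (MS_rows - MS_error) / (MS_rows + (k-1) MS_error)
#' from the subjects x raters ANOVA decomposition. With zero between-subject
#' variance the coefficient is undefined and `NaN` is returned.
#'
#' @param x numeric matrix, n subjects (rows) by k >= 2 ratings (columns)
#' @return a single ICC value in [-1, 1], or `NaN` when undefined
#' @export
icc_consistency <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2) stopf("icc_consistency: need >= 3 subjects and >= 2 ratings")
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse <= 0) return(NaN)
  (msr - mse) / (msr + (k - 1) * mse)
}

#' ICC stability gate against repeated segmentations
#'
#' Computes, per feature, the intra-observer ICC (first rater's two
#' sessions) and the inter-observer ICC (the two raters' first sessions);
#' a feature is retained iff both exceed the threshold. Features with an
#' undefined ICC (no between-subject variance) are not retained.
#'
#' @param features_r1a,features_r1b,features_r2 numeric matrices over the
#'   same nodes (rows) and features (columns): rater 1 session 1, rater 1
#'   session 2, rater 2
#' @param threshold retention gate (default 0.75)
#' @return data.frame with feature, icc_intra, icc_inter, retained
#' @export
stability_filter <- function(features_r1a, features_r1b, features_r2,
                             threshold = 0.75) {
  a <- as.matrix(features_r1a); b <- as.matrix(features_r1b)
  c2 <- as.matrix(features_r2)
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(c2)))
    stopf("stability_filter: feature tables have mismatched shapes")
  if (!identical(colnames(a), colnames(b)) ||
      !identical(colnames(a), colnames(c2)))
    stopf("stability_filter: feature names differ between tables")
  if (!is.null(rownames(a)) &&
      (!identical(rownames(a), rownames(b)) ||
       !identical(rownames(a), rownames(c2))))
    stopf("stability_filter: node sets differ between tables")
  intra <- vapply(seq_len(ncol(a)),
                  function(j) icc_consistency(cbind(a[, j], b[, j])), numeric(1))
  inter <- vapply(seq_len(ncol(a)),
                  function(j) icc_consistency(cbind(a[, j], c2[, j])), numeric(1))
  und <- is.nan(intra) | is.nan(inter)
  if (any(und))
    warning(sprintf("stability_filter: %d features with undefined ICC treated as unstable",
                    sum(und)), call. = FALSE)
  data.frame(feature = colnames(a), icc_intra = intra, icc_inter = inter,
             retained = !und & intra > threshold & inter > threshold,
             stringsAsFactors = FALSE)
}

#' Variance-threshold filter
#'
#' @param x numeric feature matrix (rows = nodes)
#' @param min_variance keep features with sample variance strictly above this
#'   (default 0: drop constants)
#' @return character vector of surviving feature names
#' @export
variance_filter <- function(x, min_variance = 0) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("variance_filter: need >= 2 rows")
  v <- apply(x, 2, var)
  colnames(x)[v > min_variance]
}

# vectorized one-way ANOVA F statistic of each column between two classes
anova_f_stat <- function(x, labels) {
  g <- split(seq_len(nrow(x)), labels)
  if (length(g) < 2) stopf("anova_f_stat: need two classes")
  n <- nrow(x)
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (idx in g) {
    m <- colMeans(x[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (m - grand)^2
    ssw <- ssw + colSums((x[idx, , drop = FALSE] -
                            matrix(m, length(idx), ncol(x), byrow = TRUE))^2)
  }
  dfb <- length(g) - 1
  dfw <- n - length(g)
  (ssb / dfb) / (ssw / dfw)
}

#' Select the k features with the largest between-class ANOVA F statistic
#'
#' Ties are broken by the fixed column order; `k >= ncol(x)` keeps all.
#'
#' @param x numeric feature matrix
#' @param labels two-class vector aligned with rows
#' @param k number of features to keep
#' @return character vector of surviving feature names, in original order
#' @export
select_k_best <- function(x, labels, k) {
  x <- as.matrix(x)
  if (length(unique(labels)) < 2) stopf("select_k_best: labels contain a single class")
  if (!is_count(k) || k < 1) stopf("select_k_best: k must be a positive integer")
  if (k >= ncol(x)) return(colnames(x))
  f <- anova_f_stat(x, labels)
  f[!is.finite(f)] <- Inf  # zero within-class variance: perfectly separating
  keep <- order(-f, seq_along(f))[seq_len(k)]
  colnames(x)[sort(keep)]
}

#' Lasso signature selection with cross-validated penalty choice
#'
#' Standardizes the features (on the provided table), fits an L1-penalized
#' logistic path over the alpha grid, chooses alpha by `n_folds`-fold
#' cross-validated deviance (seeded fold assignment), and returns the
#' features with nonzero coefficients at the chosen alpha. Both alpha and
#' -log10(alpha) are reported.
#'
#' @param x numeric feature matrix
#' @param labels two-class vector; the second factor level (or "malignant")
#'   is the positive class
#' @param alpha_grid penalty grid (default 100 points, log-spaced on
#'   [1e-4, 1])
#' @param n_folds folds for the cross-validated choice of alpha
#' @param seed integer seed for the fold assignment
#' @return list with alpha, neglog10_alpha, survivors, coefficients
#' @export
lasso_select <- function(x, labels, alpha_grid = 10^seq(-4, 0, length.out = 100),
                         n_folds = 5, seed = 1L) {
  x <- as.matrix(x)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stopf("lasso_select: labels contain a single class")
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  set.seed(as.integer(seed))
  foldid <- stratified_fold_ids(y, n_folds)
  grid <- sort(alpha_grid, decreasing = TRUE)
  cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                          lambda = grid, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  alpha <- cv$lambda.min
  cf <- coef(cv, s = alpha)[-1, 1]
  survivors <- names(cf)[cf != 0]
  list(alpha = alpha, neglog10_alpha = -log10(alpha),
       survivors = survivors, coefficients = cf[cf != 0])
}

#' Penalty strength on the -log10 reporting scale
#'
#' The selection trace reports the Lasso penalty both as alpha and as
#' -log10(alpha), the scale used on regularization-path plots (for example,
#' alpha = 0.0149 is reported as 1.827).
#'
#' @param alpha penalty strength, > 0
#' @return -log10(alpha)
#' @export
neglog10_alpha <- function(alpha) {
  if (any(alpha <= 0)) stopf("neglog10_alpha: alpha must be positive")
  -log10(alpha)
}

#' Run the variance -> SelectKBest -> Lasso screening cascade
#'
#' @param x numeric feature matrix (typically the ICC-stable features of the
#'   training set)
#' @param labels two-class vector
#' @param min_variance variance-threshold stage parameter
#' @param k SelectKBest stage parameter
#' @param alpha_grid,n_folds,seed Lasso stage parameters
#' @return a selection trace: list with per-stage survivors, `kbest_k`,
#'   `lasso_alpha`, `lasso_neglog10_alpha`, `nonzero_coefficients`
#' @export
screen_features <- function(x, labels, min_variance = 0, k = 100,
                            alpha_grid = 10^seq(-4, 0, length.out = 100),
                            n_folds = 5, seed = 1L) {
  x <- as.matrix(x)
  s1 <- variance_filter(x, min_variance)
  s2 <- select_k_best(x[, s1, drop = FALSE], labels, k)
  las <- lasso_select(x[, s2, drop = FALSE], labels, alpha_grid, n_folds, seed)
  list(stages = c("variance", "kbest", "lasso"),
       variance = s1, kbest = s2, lasso = las$survivors,
       kbest_k = k, lasso_alpha = las$alpha,
       lasso_neglog10_alpha = las$neglog10_alpha,
       nonzero_coefficients = las$coefficients)
}
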