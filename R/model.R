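# normalize labels to 0/1 with "malignant" (or the larger level) positive
as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(labels %in% c(0, 1)) && length(u) == 2)
      return(as.integer(labels == u[2]))
    return(as.integer(labels))
  }
  l <- as.character(labels)
  if (all(l %in% c("benign", "malignant"))) return(as.integer(l == "malignant"))
  u <- sort(unique(l))
  if (length(u) != 2) stopf("labels must have exactly two classes")
  as.integer(l == u[2])
}

# stratified fold ids, seeded by the caller
stratified_fold_ids <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' Stratified train/test split with the floor rule
#'
#' The training set has exactly `floor(ratio * N)` items; per-class training
#' counts follow largest-remainder allocation of the stratified targets, so
#' class proportions are preserved to within one item.
#'
#' @param labels two-class vector (names, if present, become the returned ids)
#' @param ratio training fraction in (0, 1); default 0.7
#' @param seed integer seed
#' @return list with `train` and `test` index vectors (disjoint, exhaustive)
#' @export
stratified_split <- function(labels, ratio = 0.7, seed = 1L) {
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1)
    stopf("stratified_split: ratio must be in (0, 1)")
  n <- length(labels)
  if (n < 2) stopf("stratified_split: need at least 2 items")
  n_train <- floor(ratio * n)
  y <- as.character(labels)
  classes <- sort(unique(y))
  target <- ratio * table(y)[classes]
  base <- floor(target)
  rem <- n_train - sum(base)
  if (rem > 0) {
    extra <- order(-(target - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  set.seed(as.integer(seed))
  train <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(y == classes[i])
    train <- c(train, sample(idx, min(base[i], length(idx))))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Mann-Whitney AUC with half credit for ties
#'
#' @param scores numeric scores (higher = more malignant)
#' @param labels two-class vector
#' @return AUC in [0, 1]
#' @export
auc_mw <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stopf("auc_mw: both classes required")
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC metric suite at a fixed probability cutoff
#'
#' AUC via the Mann-Whitney statistic (ties get half credit, equivalent to
#' the trapezoidal empirical ROC area); sensitivity, specificity and
#' accuracy at `score >= cutoff` predicted positive.
#'
#' @param scores numeric scores
#' @param labels two-class vector
#' @param cutoff decision threshold on the score (default 0.5)
#' @return named vector auc/acc/se/sp
#' @export
roc_metrics <- function(scores, labels, cutoff = 0.5) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stopf("roc_metrics: both classes required")
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  c(auc = auc_mw(scores, y), acc = (tp + tn) / length(y),
    se = tp / sum(y == 1), sp = tn / sum(y == 0))
}

#' Diagnostic metrics of a binary rater from a 2x2 table
#'
#' For a yes/no reader the empirical ROC has a single interior operating
#' point, so its area is (SE + SP) / 2 exactly.
#'
#' @param tp,fp,fn,tn counts of the diagnosis-versus-pathology table
#' @return named vector auc/acc/se/sp
#' @export
rater_metrics <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  cnt <- c(tp, fp, fn, tn)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stopf("rater_metrics: counts must be nonnegative integers")
  if (tp + fn == 0 || fp + tn == 0)
    stopf("rater_metrics: need both positives and negatives")
  se <- tp / (tp + fn); sp <- tn / (tn + fp)
  c(auc = (se + sp) / 2, acc = (tp + tn) / sum(cnt), se = se, sp = sp)
}

#' Optimal cutoff by the Youden index
#'
#' Scans the midpoints of adjacent sorted unique values; the threshold
#' maximizing SE + SP - 1 is returned (ties broken by the smaller
#' threshold), with the SE/SP attained there and the AUC of the raw values.
#' Classification rule: value >= threshold predicts positive.
#'
#' @param values numeric marker (e.g. node short diameter, mm)
#' @param labels two-class vector
#' @return list with threshold, se, sp, youden, auc
#' @export
youden_threshold <- function(values, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stopf("youden_threshold: both classes required")
  u <- sort(unique(values))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best <- NULL
  for (t in cand) {
    se <- mean(values[y == 1] >= t)
    sp <- mean(values[y == 0] < t)
    j <- se + sp - 1
    if (is.null(best) || j > best$youden + 1e-15)
      best <- list(threshold = t, se = se, sp = sp, youden = j)
  }
  c(best, list(auc = auc_mw(values, y)))
}

#' Logistic model with stratified k-fold cross-validation
#'
#' Standardizes the features (training statistics), assigns seeded
#' stratified folds, fits a logistic regression with intercept on each
#' training portion and evaluates AUC/ACC/SE/SP on the held-out fold at the
#' given probability cutoff; the final model is refit on all rows. The
#' returned object predicts probabilities on new data via [predict_prob()].
#'
#' @param x numeric feature matrix
#' @param labels two-class vector
#' @param n_folds number of folds (default 5)
#' @param seed integer seed for fold assignment
#' @param cutoff probability cutoff for ACC/SE/SP
#' @return object of class `node_logistic`: list with coefficients, scaling,
#'   `fold_metrics` (one row per fold), `cv_mean` metrics, `train_metrics`
#'   (refit model on its training rows)
#' @export
fit_logistic_cv <- function(x, labels, n_folds = 5, seed = 1L, cutoff = 0.5) {
  x <- as.matrix(x)
  if (ncol(x) < 1) stopf("fit_logistic_cv: need at least one feature")
  y <- as_binary_labels(labels)
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  set.seed(as.integer(seed))
  foldid <- stratified_fold_ids(y, n_folds)
  fit_one <- function(rows) {
    df <- data.frame(y = y[rows], xs[rows, , drop = FALSE])
    m <- suppressWarnings(glm(y ~ ., data = df, family = binomial(),
                              control = list(maxit = 100)))
    if (!m$converged) stopf("fit_logistic_cv: logistic fit did not converge (%d rows, %d features)",
                            length(rows), ncol(x))
    m
  }
  fold_metrics <- t(vapply(seq_len(n_folds), function(f) {
    tr <- which(foldid != f); te <- which(foldid == f)
    m <- fit_one(tr)
    p <- predict(m, newdata = data.frame(xs[te, , drop = FALSE]),
                 type = "response")
    roc_metrics(p, y[te], cutoff)
  }, numeric(4)))
  final <- fit_one(seq_along(y))
  p_all <- predict(final, type = "response")
  structure(list(coefficients = coef(final), center = ctr, scale = scl,
                 cutoff = cutoff, foldid = foldid,
                 fold_metrics = as.data.frame(fold_metrics),
                 cv_mean = colMeans(fold_metrics),
                 train_metrics = roc_metrics(p_all, y, cutoff)),
            class = "node_logistic")
}

#' Predicted malignancy probabilities from a fitted logistic model
#'
#' @param fit a `node_logistic` from [fit_logistic_cv()]
#' @param newx numeric matrix with the model's feature columns
#' @return vector of probabilities
#' @export
predict_prob <- function(fit, newx) {
  newx <- as.matrix(newx)
  xs <- sweep(sweep(newx, 2, fit$center), 2, fit$scale, "/")
  eta <- fit$coefficients[1] + drop(xs %*% fit$coefficients[-1])
  1 / (1 + exp(-eta))
}

# placement values (structural components) of each case, O(n log n)
delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  pos_r <- rank(pos, ties.method = "average")
  neg_r <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - pos_r) / n          # P(X > Y) + 0.5 P(X = Y)
  v01 <- 1 - (all_r[m + seq_len(n)] - neg_r) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors on the same items via the
#' placement-value (structural-component) covariance estimate; z is the AUC
#' difference over its standard error and p the two-sided normal tail.
#' Swapping the arguments negates z and leaves p unchanged. Identical score
#' vectors give p = 1 by convention; a zero-variance difference with a
#' nonzero AUC difference is an error.
#'
#' @param scores_a,scores_b paired score vectors
#' @param labels two-class vector
#' @return list with auc1, auc2, z, p
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stopf("delong_test: both classes required")
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    stopf("delong_test: scores must be paired on identical items")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    if (abs(d) < 1e-12) return(list(auc1 = pa$auc, auc2 = pb$auc, z = 0, p = 1))
    stopf("delong_test: degenerate variance with unequal AUCs")
  }
  z <- d / sqrt(v)
  list(auc1 = pa$auc, auc2 = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' @importFrom stats cov
NULL
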