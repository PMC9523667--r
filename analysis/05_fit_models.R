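#!/usr/bin/env Rscript
# Fivefold logistic modelling of each method's Lasso signature, evaluation
# on the held-out test set, and pairwise DeLong comparison of the four
# methods' test-set scores.

suppressMessages(library(nodiomics))

seed <- 1L
cohort <- read_cohort("results/cohort")
labels <- cohort$records$label
split <- readRDS("results/split.rds")
screening <- readRDS("results/screening.rds")

rows <- list(); scores <- list()
for (m in 1:4) {
  fx <- feature_matrix(read.csv(sprintf("results/features_method%d.csv", m),
                                check.names = FALSE))
  sel <- screening[[m]]$trace$lasso
  if (!length(sel)) sel <- screening[[m]]$trace$kbest[1]
  fit <- fit_logistic_cv(fx[split$train, sel, drop = FALSE],
                         labels[split$train], seed = seed + m)
  sc <- predict_prob(fit, fx[split$test, sel, drop = FALSE])
  scores[[m]] <- sc
  te <- roc_metrics(sc, labels[split$test])
  rows[[length(rows) + 1]] <- data.frame(method = m, set = "train_refit",
                                         t(fit$train_metrics))
  rows[[length(rows) + 1]] <- data.frame(method = m, set = "cv_mean",
                                         t(fit$cv_mean))
  rows[[length(rows) + 1]] <- data.frame(method = m, set = "test", t(te))
  cat(sprintf("method %d: signature %d features, cv AUC %.3f, test AUC %.3f\n",
              m, length(sel), fit$cv_mean["auc"], te["auc"]))
}
metrics <- do.call(rbind, rows)
write.csv(metrics, "results/model_metrics.csv", row.names = FALSE)
saveRDS(scores, "results/test_scores.rds")

pairs <- combn(4, 2)
delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
  a <- pairs[1, j]; b <- pairs[2, j]
  d <- delong_test(scores[[a]], scores[[b]], labels[split$test])
  data.frame(method_a = a, method_b = b, auc_a = d$auc1, auc_b = d$auc2,
             z = d$z, p = d$p)
}))
write.csv(delong, "results/delong_comparisons.csv", row.names = FALSE)
cat("pairwise DeLong p-values:\n")
print(delong)
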