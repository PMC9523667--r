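#!/usr/bin/env Rscript
# Benchmarks the radiomic models are compared against: the short-diameter
# size criterion (Youden-optimal cutoff on the full-size record table) and
# the three human readers' published diagnosis-vs-pathology tables.

suppressMessages(library(nodiomics))

full <- read.csv("results/records_full.csv")
yd <- youden_threshold(full$short_diameter_mm, full$label)
cat(sprintf("short diameter: AUC %.3f; Youden threshold %.2f mm (SE %.3f, SP %.3f)\n",
            yd$auc, yd$threshold, yd$se, yd$sp))
size <- data.frame(benchmark = "short_diameter", auc = yd$auc,
                   threshold_mm = yd$threshold, se = yd$se, sp = yd$sp)

raters <- list(junior = c(tp = 112, fp = 47, fn = 194, tn = 251),
               middle = c(tp = 169, fp = 85, fn = 137, tn = 213),
               senior = c(tp = 120, fp = 15, fn = 186, tn = 283))
reader <- do.call(rbind, lapply(names(raters), function(nm) {
  ct <- raters[[nm]]
  data.frame(benchmark = paste0("reader_", nm),
             t(rater_metrics(ct[["tp"]], ct[["fp"]], ct[["fn"]], ct[["tn"]])))
}))
print(reader)

model <- read.csv("results/model_metrics.csv")
best <- model[model$set == "test", ]
cat(sprintf("best radiomic test AUC: %.3f (method %d) vs size criterion %.3f and best reader %.3f\n",
            max(best$auc), best$method[which.max(best$auc)], yd$auc,
            max(reader$auc)))

out <- rbind(size[, c("benchmark", "auc", "se", "sp")],
             reader[, c("benchmark", "auc", "se", "sp")])
write.csv(out, "results/benchmarks.csv", row.names = FALSE)
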