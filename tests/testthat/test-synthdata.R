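test_that("cohort counts, labels and determinism match the configuration", {
  cfg <- cohort_config(n_benign = 6, n_malignant = 7, image_size = 48,
                       seed = 5)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$records), 13)
  expect_equal(sum(co$records$label == "malignant"), 7)
  expect_equal(sum(co$records$label == "benign"), 6)
  co2 <- generate_cohort(cfg)
  expect_identical(co$records, co2$records)
  expect_identical(co$images, co2$images)
  expect_identical(co$masks, co2$masks)
  empty <- generate_cohort(cohort_config(n_benign = 0, n_malignant = 0))
  expect_equal(nrow(empty$records), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_benign = -1), "nonnegative")
  expect_error(cohort_config(pixel_spacing = 0), "spacing")
  expect_error(cohort_config(benign_diam_range = c(5, 3)), "range")
  expect_error(cohort_config(noise_sd = NaN), "non-finite")
  expect_error(cohort_config(border_type_probs = list(
    benign = c(smooth = 0.5, lobulated = 0.5, spiculated = 0.1,
               indistinct = 0.1),
    malignant = c(smooth = 0.25, lobulated = 0.25, spiculated = 0.25,
                  indistinct = 0.25))), "probability")
})

test_that("no sampled diameter falls outside the configured class range", {
  rec <- sample_node_records(cohort_config(n_benign = 800, n_malignant = 800,
                                           seed = 9))
  b <- rec$short_diameter_mm[rec$label == "benign"]
  m <- rec$short_diameter_mm[rec$label == "malignant"]
  expect_true(all(b >= 3 & b <= 9.42))
  expect_true(all(m >= 3 & m <= 14))
})

test_that("sampled diameter means recover the configured class means", {
  # the generator moment-matches the truncated distribution, so the sample
  # mean must sit within 3 SE of the configured value; the analytic
  # truncated-normal mean of the matched parameters is the oracle
  cfg <- cohort_config(n_benign = 5000, n_malignant = 5000, seed = 101)
  rec <- sample_node_records(cfg)
  for (cl in c("benign", "malignant")) {
    x <- rec$short_diameter_mm[rec$label == cl]
    target <- if (cl == "benign") 4.83 else 5.45
    rng <- if (cl == "benign") c(3, 9.42) else c(3, 14)
    sdv <- if (cl == "benign") 1.09 else 2.17
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - target), 3 * se)
    par <- nodiomics:::truncnorm_match(target, sdv, rng)
    mo <- nodiomics:::truncnorm_moments(par["mean"], par["sd"], rng[1], rng[2])
    expect_lt(abs(mean(x) - mo["mean"]), 3 * se)
  }
})

test_that("an unperturbed noise-free node renders as a constant-interior near-circular mask", {
  cfg <- cohort_config(image_size = 64, noise_sd = 0, distractor_rate = 0,
                       heterogeneity_level = c(benign = 0, malignant = 0),
                       seed = 3)
  rec <- data.frame(node_id = "n1", label = "benign", short_diameter_mm = 6,
                    border_type = "smooth", heterogeneity = 0, seed = 77L,
                    image_ref = "n1")
  r <- render_node(rec, cfg)
  expect_equal(length(unique(r$image[r$mask])), 1)
  sf <- shape_features(r$mask, r$spacing)
  expect_gte(sf[["Circularity"]], 0.85)
})

test_that("the rendered mask minor axis tracks the record short diameter", {
  cfg <- cohort_config(image_size = 96, seed = 3)
  for (s in 1:6) {
    rec <- data.frame(node_id = "n1", label = "benign",
                      short_diameter_mm = 6, border_type = "smooth",
                      heterogeneity = 0, seed = 1000L + s, image_ref = "n1")
    r <- render_node(rec, cfg)
    # moments-based minor axis oracle, independent of shape_features
    co <- which(r$mask, arr.ind = TRUE)
    cv <- cov(co) * (nrow(co) - 1) / nrow(co)
    minor_mm <- 4 * sqrt(min(eigen(cv)$values)) * r$spacing
    expect_gte(minor_mm, 5.1)
    expect_lte(minor_mm, 6.9)
  }
})

test_that("lobulated borders show more radial contour maxima than smooth twins", {
  cfg <- cohort_config(image_size = 96, noise_sd = 0, distractor_rate = 0,
                       seed = 3)
  wins <- 0
  for (s in 1:10) {
    mk <- function(bt) {
      rec <- data.frame(node_id = "n1", label = "benign",
                        short_diameter_mm = 8, border_type = bt,
                        heterogeneity = 0, seed = 2000L + s, image_ref = "n1")
      render_node(rec, cfg)$mask
    }
    pl <- radial_peak_count(mk("lobulated"))
    ps <- radial_peak_count(mk("smooth"))
    expect_gte(pl, 2)
    if (pl > ps) wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("nodes below the resolvable size are rejected", {
  cfg <- cohort_config(pixel_spacing = 2)  # 3 mm is only 1.5 px here
  rec <- data.frame(node_id = "n1", label = "benign", short_diameter_mm = 3,
                    border_type = "smooth", heterogeneity = 0, seed = 1L,
                    image_ref = "n1")
  expect_error(render_node(rec, cfg), "resolvable")
})

test_that("malignant interiors are more heterogeneous than benign ones", {
  cfg <- cohort_config(n_benign = 300, n_malignant = 300, image_size = 48,
                       distractor_rate = 0, seed = 21)
  co <- generate_cohort(cfg)
  v <- vapply(co$records$node_id,
              function(id) var(co$images[[id]][co$masks[[id]]]), numeric(1))
  vm <- v[co$records$label == "malignant"]
  vb <- v[co$records$label == "benign"]
  gap <- mean(vm) - mean(vb)
  se <- sqrt(var(vm) / length(vm) + var(vb) / length(vb))
  expect_gt(gap, 3 * se)
})

test_that("cohorts round-trip losslessly through a directory", {
  co <- tiny_cohort(5, seed = 8, image_size = 48)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(man))
  back <- read_cohort(dir)
  expect_identical(back$records$node_id, co$records$node_id)
  expect_identical(back$records$label, co$records$label)
  expect_identical(back$masks, co$masks)
  for (id in co$records$node_id)
    expect_equal(back$images[[id]], co$images[[id]], tolerance = 1e-6)
})

test_that("a manifest referencing a missing image names the file in the error", {
  co <- tiny_cohort(3, seed = 8, image_size = 48)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  bad <- co$records$node_id[2]
  unlink(file.path(dir, sprintf("%s_img.nii.gz", bad)))
  expect_error(read_cohort(dir), sprintf("%s_img", bad))
})

test_that("the manifest has one data row per node", {
  # cohort assembled by hand so the full published size is cheap to write
  n <- 604
  recs <- data.frame(node_id = sprintf("node%04d", 1:n),
                     label = rep(c("malignant", "benign"), c(306, 298)),
                     short_diameter_mm = 5, border_type = "smooth",
                     heterogeneity = 0, seed = 1L,
                     image_ref = sprintf("node%04d", 1:n))
  img <- matrix(1, 4, 4); msk <- matrix(TRUE, 4, 4)
  co <- structure(list(records = recs,
                       images = setNames(rep(list(img), n), recs$node_id),
                       masks = setNames(rep(list(msk), n), recs$node_id),
                       spacing = 0.5625), class = "node_cohort")
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_equal(nrow(read.csv(man)), 604)
})
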