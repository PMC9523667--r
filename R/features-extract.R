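#' Names of the complete radiomic feature vector, in canonical order
#'
#' The full bank has 14 shape + (18 first-order + 75 texture) on the
#' original image + the same 93 intensity/texture features on each of the
#' 14 filtered images: 14 + 93 + 14 x 93 = 1,409 names.
#'
#' @param filters character vector of filter names (default: the full bank)
#' @return character vector of feature names
#' @export
feature_names <- function(filters = FILTER_NAMES) {
  tex <- c(paste0("glcm_", GLCM_FEATURES), paste0("gldm_", GLDM_FEATURES),
           paste0("glrlm_", GLRLM_FEATURES), paste0("glszm_", GLSZM_FEATURES),
           paste0("ngtdm_", NGTDM_FEATURES))
  per_image <- c(paste0("firstorder_", FIRSTORDER_FEATURES), tex)
  c(paste0("original_shape_", SHAPE_FEATURES),
    paste0("original_", per_image),
    unlist(lapply(filters, function(f) paste0(f, "_", per_image)),
           use.names = FALSE))
}

#' Extract the full radiomic feature vector of one (image, ROI) pair
#'
#' Computes 14 shape features of the ROI, 18 first-order and 75 texture
#' features on the original image, and the same 93 intensity/texture
#' features on each image of the filter bank: 1,409 features in total with
#' the complete bank. The result is deterministic given inputs and
#' configuration, and every value is finite.
#'
#' @param image numeric matrix
#' @param mask logical matrix: the ROI
#' @param spacing mm/pixel
#' @param disc a [disc_config()]
#' @param filters filter subset (default the full 14-transform bank); pass
#'   `character(0)` for an original-image-only extraction
#' @return named numeric vector (length 1,409 for the complete bank)
#' @export
extract_features <- function(image, mask, spacing, disc = disc_config(),
                             filters = FILTER_NAMES) {
  if (!identical(dim(image), dim(mask)))
    stopf("extract_features: image and mask dimensions differ")
  mask <- mask > 0
  out <- c(setNames(shape_features(mask, spacing),
                    paste0("original_shape_", SHAPE_FEATURES)),
           per_image_features(image, mask, disc, "original"))
  if (length(filters)) {
    bank <- filter_bank(image, spacing)[filters]
    for (f in filters)
      out <- c(out, per_image_features(bank[[f]], mask, disc, f))
  }
  stopifnot(identical(names(out), feature_names(filters)))
  out
}

per_image_features <- function(img, mask, disc, prefix) {
  tex <- texture_features(img, mask, disc)
  c(setNames(first_order_features(img, mask, disc$n_bins),
             paste0(prefix, "_firstorder_", FIRSTORDER_FEATURES)),
    setNames(tex, paste0(prefix, "_", names(tex))))
}

#' Extract a per-node feature table for a cohort
#'
#' @param cohort a `node_cohort`
#' @param masks named list of ROI masks to use (defaults to the cohort's base
#'   masks); names must cover the cohort node ids
#' @param disc a [disc_config()]
#' @param filters filter subset passed to [extract_features()]
#' @return data.frame with node_id, label, then one column per feature
#' @export
extract_feature_table <- function(cohort, masks = cohort$masks,
                                  disc = disc_config(),
                                  filters = FILTER_NAMES) {
  ids <- cohort$records$node_id
  if (!all(ids %in% names(masks)))
    stopf("extract_feature_table: masks missing for some nodes")
  rows <- lapply(ids, function(id)
    extract_features(cohort$images[[id]], masks[[id]], cohort$spacing,
                     disc, filters))
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(node_id = ids, label = cohort$records$label,
                   stringsAsFactors = FALSE), tab)
}

#' Numeric feature matrix of a feature table
#'
#' Drops the node_id/label bookkeeping columns and returns the numeric
#' matrix with node ids as rownames.
#'
#' @param table a feature table from [extract_feature_table()]
#' @return numeric matrix
#' @export
feature_matrix <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), c("node_id", "label")),
                       drop = FALSE])
  rownames(m) <- table$node_id
  m
}
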