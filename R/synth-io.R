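#' Write a cohort to a directory
#'
#' Writes one NIfTI image and one NIfTI mask per node plus a `manifest.csv`
#' with one row per node (node_id, label, short_diameter_mm, border_type,
#' heterogeneity, image, mask, spacing_mm). Masks round-trip losslessly;
#' intensities round-trip to stored (float32) precision.
#'
#' @param cohort a `node_cohort`
#' @param dir output directory (created if missing)
#' @return the manifest path, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- cohort$records
  img_files <- sprintf("%s_img.nii.gz", rec$node_id)
  msk_files <- sprintf("%s_mask.nii.gz", rec$node_id)
  for (i in seq_len(nrow(rec))) {
    RNifti::writeNifti(
      RNifti::asNifti(cohort$images[[i]], pixdim = rep(cohort$spacing, 2)),
      file.path(dir, img_files[i]))
    RNifti::writeNifti(
      RNifti::asNifti(matrix(as.integer(cohort$masks[[i]]),
                             nrow(cohort$masks[[i]])),
                      pixdim = rep(cohort$spacing, 2)),
      file.path(dir, msk_files[i]))
  }
  man <- data.frame(node_id = rec$node_id, label = rec$label,
                    short_diameter_mm = rec$short_diameter_mm,
                    border_type = rec$border_type,
                    heterogeneity = rec$heterogeneity,
                    image = img_files, mask = msk_files,
                    spacing_mm = cohort$spacing,
                    stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`
#' @return a `node_cohort`
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stopf("read_cohort: missing manifest file %s", man_path)
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  need <- c("node_id", "label", "short_diameter_mm", "border_type",
            "heterogeneity", "image", "mask", "spacing_mm")
  if (!all(need %in% names(man)))
    stopf("read_cohort: manifest lacks columns: %s",
          paste(setdiff(need, names(man)), collapse = ", "))
  images <- masks <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    fi <- file.path(dir, man$image[i])
    fm <- file.path(dir, man$mask[i])
    if (!file.exists(fi)) stopf("read_cohort: missing image file %s", fi)
    if (!file.exists(fm)) stopf("read_cohort: missing mask file %s", fm)
    images[[i]] <- matrix(as.numeric(RNifti::readNifti(fi)),
                          dim(RNifti::readNifti(fi))[1])
    masks[[i]] <- matrix(as.numeric(RNifti::readNifti(fm)),
                         dim(RNifti::readNifti(fm))[1]) > 0
  }
  names(images) <- names(masks) <- man$node_id
  rec <- man[, c("node_id", "label", "short_diameter_mm", "border_type",
                 "heterogeneity")]
  rec$image_ref <- man$node_id
  structure(list(records = rec, images = images, masks = masks,
                 spacing = man$spacing_mm[1]),
            class = "node_cohort")
}
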