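# Real-data ingestion: NIfTI CT volumes with paired integer label volumes,
# sliced to 2D axial training items. Intensities are windowed to a configured
# Hounsfield-unit range and scaled to [0, 1]; labels collapse to a binary
# kidney mask. The reference preprocessing description for the challenge data
# is ambiguous about its overlapping-patch scheme, so this module implements
# plain per-slice extraction with optional resizing - a deliberate,
# documented simplification.

#' Load a CT volume and its segmentation volume
#'
#' @param image_path,label_path NIfTI files (`.nii` / `.nii.gz`).
#' @return list with `image` (3D numeric array), `labels` (3D integer array),
#'   `spacing` (mm per voxel along each axis). Axis order is (row, col,
#'   slice): axial slices are `image[, , s]`.
#' @export
load_volume <- function(image_path, label_path) {
  img <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(label_path)
  if (!identical(dim(img), dim(lab))) {
    abort(sprintf("image and label volumes differ in shape: %s vs %s",
                  paste(dim(img), collapse = "x"),
                  paste(dim(lab), collapse = "x")))
  }
  sp_i <- RNifti::pixdim(img)
  sp_l <- RNifti::pixdim(lab)
  if (max(abs(sp_i - sp_l)) > 1e-6) {
    abort("image and label volumes differ in voxel spacing")
  }
  list(image = unclass(img)[, , , drop = FALSE],
       labels = array(as.integer(round(unclass(lab))), dim(lab)),
       spacing = as.numeric(sp_i))
}

# affine HU window to [0, 1]; monotone inside the window, clamped outside
window_hu <- function(x, window = c(-200, 300)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  pmin(pmax((x - window[1]) / (window[2] - window[1]), 0), 1)
}

resize_image <- function(m, size, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("resizing requires the EBImage package")
  }
  out <- EBImage::resize(m, w = size, h = size,
                         filter = if (mode == "bilinear") "bilinear" else "none")
  matrix(as.numeric(out), size, size)
}

#' Slice a labelled volume into 2D training items
#'
#' @param volume 3D intensity array (Hounsfield units).
#' @param labels 3D integer label array of the same shape.
#' @param spacing voxel spacing (mm), length 3.
#' @param window HU window mapped affinely to \[0, 1\]; values outside are
#'   clamped.
#' @param kidney_labels label values collapsed to foreground (default `1`;
#'   use `c(1, 2)` to merge a tumour label into the kidney mask).
#' @param known_labels all label values allowed in `labels`; anything else
#'   raises an error listing the offenders.
#' @param target_size optional square output size (divisible by 8); images
#'   are resized bilinearly, masks with nearest-neighbour.
#' @param skip_blank drop slices whose mask is empty.
#' @return list with `pairs` (image/mask/meta items, order-stable in slice
#'   index) and `manifest` tibble (slice, has_fg, fg_fraction, spacing).
#' @export
slice_dataset <- function(volume, labels, spacing = c(1, 1, 1),
                          window = c(-200, 300), kidney_labels = 1L,
                          known_labels = 0:2, target_size = NULL,
                          skip_blank = TRUE) {
  stopifnot(identical(dim(volume), dim(labels)), length(dim(volume)) == 3)
  bad <- setdiff(unique(as.integer(labels)), as.integer(known_labels))
  if (length(bad)) {
    abort(sprintf("unknown label values: %s", paste(sort(bad), collapse = ", ")))
  }
  if (!is.null(target_size)) check_divisible(target_size, target_size, 8L)
  ns <- dim(volume)[3]
  sp2 <- spacing[1:2]
  pairs <- list()
  rows <- list()
  for (s in seq_len(ns)) {
    msk <- matrix(as.integer(labels[, , s] %in% kidney_labels),
                  dim(volume)[1], dim(volume)[2])
    if (skip_blank && sum(msk) == 0) next
    img <- window_hu(volume[, , s], window)
    out_sp <- sp2
    if (!is.null(target_size)) {
      scale <- dim(img)[1] / target_size
      img <- resize_image(img, target_size, "bilinear")
      msk <- resize_image(msk, target_size, "nearest")
      msk <- matrix(as.integer(msk > 0.5), target_size, target_size)
      out_sp <- sp2 * scale
    }
    pairs[[length(pairs) + 1L]] <- list(
      image = img, mask = msk,
      meta = tibble(index = s - 1L, slice = s, n_regions = NA_integer_))
    rows[[length(rows) + 1L]] <- tibble(
      slice = s, has_fg = sum(msk) > 0, fg_fraction = mean(msk),
      spacing_row_mm = out_sp[1], spacing_col_mm = out_sp[2])
  }
  list(pairs = pairs,
       manifest = if (length(rows)) purrr::list_rbind(rows) else
         tibble(slice = integer(), has_fg = logical(), fg_fraction = numeric(),
                spacing_row_mm = numeric(), spacing_col_mm = numeric()))
}

#' Write a small synthetic NIfTI volume pair (testing/demo helper)
#'
#' @param dir output directory.
#' @param image,labels 3D arrays.
#' @param spacing voxel spacing in mm.
#' @return named list of the two file paths.
#' @export
write_volume_pair <- function(dir, image, labels, spacing = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ip <- file.path(dir, "image.nii.gz")
  lp <- file.path(dir, "labels.nii.gz")
  im <- RNifti::asNifti(image)
  RNifti::pixdim(im) <- spacing
  lb <- RNifti::asNifti(labels + 0)
  RNifti::pixdim(lb) <- spacing
  RNifti::writeNifti(im, ip)
  RNifti::writeNifti(lb, lp)
  list(image = ip, labels = lp)
}
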