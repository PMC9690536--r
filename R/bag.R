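# Bag construction: grid patching, foreground threshold filtering,
# flip/rotate balancing to a fixed bag size, bilinear resize.

#' Bag-construction configuration
#'
#' @param grid_rows,grid_cols Tiling grid (default 14 x 7, i.e. 98 patches).
#' @param foreground_threshold Intensity above which a pixel counts as
#'   foreground (tissue) rather than background/noise.
#' @param min_foreground_fraction Minimum fraction of foreground pixels a
#'   patch needs to survive filtering.
#' @param target_bag_size Number of instances every finished bag must have.
#' @param patch_side Side length each instance is resized to (default 224).
#' @param seed Integer seed (reserved for seeded variants of balancing;
#'   the default balancing rule is deterministic).
#' @return An object of class `oomil_bag_config`.
#' @export
bag_build_config <- function(grid_rows = 14L, grid_cols = 7L,
                             foreground_threshold = 0.08,
                             min_foreground_fraction = 0.25,
                             target_bag_size = 70L,
                             patch_side = 224L,
                             seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1,
            foreground_threshold >= 0, foreground_threshold <= 1,
            min_foreground_fraction >= 0, min_foreground_fraction <= 1,
            target_bag_size >= 1, patch_side >= 1)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 foreground_threshold = foreground_threshold,
                 min_foreground_fraction = min_foreground_fraction,
                 target_bag_size = as.integer(target_bag_size),
                 patch_side = as.integer(patch_side),
                 seed = as.integer(seed)),
            class = "oomil_bag_config")
}

new_instance <- function(pixels, grid_row, grid_col,
                         augmentation_tag = "none", hidden_label = NA_integer_) {
  structure(list(pixels = pixels,
                 grid_row = as.integer(grid_row),
                 grid_col = as.integer(grid_col),
                 augmentation_tag = augmentation_tag,
                 hidden_label = hidden_label),
            class = "oomil_instance")
}

#' Split an image into a grid of patch instances
#'
#' Tiles the image into `grid_rows x grid_cols` non-overlapping patches in
#' row-major order, each tagged with its 0-based `(grid_row, grid_col)`
#' position. If the image dimensions are not divisible by the grid it is
#' first center-cropped to the largest divisible size.
#'
#' @param image Grayscale matrix (intensities in \[0,1\]).
#' @param grid_rows,grid_cols Grid shape.
#' @return A list of `oomil_instance` objects, length
#'   `grid_rows * grid_cols`.
#' @export
grid_patch <- function(image, grid_rows = 14L, grid_cols = 7L) {
  stopifnot(is.matrix(image), grid_rows >= 1, grid_cols >= 1)
  h <- nrow(image); w <- ncol(image)
  ch <- h %/% grid_rows; cw <- w %/% grid_cols
  if (ch < 1 || cw < 1) stop("grid finer than the image", call. = FALSE)
  if (h %% grid_rows != 0 || w %% grid_cols != 0) {
    top <- (h - ch * grid_rows) %/% 2
    left <- (w - cw * grid_cols) %/% 2
    image <- image[(top + 1):(top + ch * grid_rows),
                   (left + 1):(left + cw * grid_cols), drop = FALSE]
  }
  out <- vector("list", grid_rows * grid_cols)
  k <- 0L
  for (r in seq_len(grid_rows)) {
    for (cc in seq_len(grid_cols)) {
      k <- k + 1L
      out[[k]] <- new_instance(
        image[((r - 1) * ch + 1):(r * ch), ((cc - 1) * cw + 1):(cc * cw), drop = FALSE],
        grid_row = r - 1L, grid_col = cc - 1L
      )
    }
  }
  out
}

foreground_fraction <- function(instance, threshold) {
  mean(instance$pixels > threshold)
}

#' Drop patches dominated by background or border noise
#'
#' Keeps exactly the patches whose fraction of pixels brighter than
#' `foreground_threshold` is at least `min_foreground_fraction`,
#' preserving input order.
#'
#' @param patches List of `oomil_instance`.
#' @param cfg A [bag_build_config()].
#' @return The surviving patches.
#' @export
threshold_filter <- function(patches, cfg) {
  stopifnot(length(patches) > 0, inherits(cfg, "oomil_bag_config"))
  fg <- vapply(patches, foreground_fraction, numeric(1),
               threshold = cfg$foreground_threshold)
  keep <- fg >= cfg$min_foreground_fraction
  if (!any(keep)) stop("empty bag after filtering", call. = FALSE)
  patches[keep]
}

#' Balance a bag to its target size
#'
#' With more survivors than `target_bag_size`, keeps the patches with the
#' highest foreground fraction (ties broken toward the earlier, i.e. lower
#' row-major, patch), preserving their relative order. With fewer, appends
#' augmented copies: extras cycle round-robin over the surviving patches,
#' moving to the next transform in the fixed ordered list (`hflip`,
#' `vflip`, `rot90`, `rot180`, `rot270`, `hflip+rot90`, ...) once each
#' survivor has been copied under the current one. The
#' `augmentation_tag` of each copy records its transform; copies inherit
#' the source patch's grid position and hidden label.
#'
#' @param patches Surviving patches from [threshold_filter()].
#' @param cfg A [bag_build_config()].
#' @return A list of exactly `cfg$target_bag_size` instances.
#' @export
balance_bag <- function(patches, cfg) {
  stopifnot(length(patches) > 0, inherits(cfg, "oomil_bag_config"))
  n <- length(patches)
  target <- cfg$target_bag_size
  if (n == target) return(patches)
  if (n > target) {
    fg <- vapply(patches, foreground_fraction, numeric(1),
                 threshold = cfg$foreground_threshold)
    # order() is stable: ties resolve toward the earlier patch
    keep <- sort(order(-fg)[seq_len(target)])
    return(patches[keep])
  }
  n_extra <- target - n
  extras <- vector("list", n_extra)
  n_transforms <- length(AUG_TRANSFORMS)
  for (i in seq_len(n_extra)) {
    src <- patches[[((i - 1L) %% n) + 1L]]
    tag <- AUG_TRANSFORMS[[(((i - 1L) %/% n) %% n_transforms) + 1L]]
    aug <- src
    aug$pixels <- apply_transform(src$pixels, tag)
    aug$augmentation_tag <- tag
    extras[[i]] <- aug
  }
  c(patches, extras)
}

#' Resize every patch to its final square side
#'
#' Bilinear interpolation to `patch_side x patch_side`; intensities are
#' clipped to \[0,1\]. A patch already at the target size passes through
#' pixel-identical.
#'
#' @param patches List of `oomil_instance`.
#' @param patch_side Target side in pixels.
#' @return The resized patches.
#' @export
finalize_patches <- function(patches, patch_side = 224L) {
  stopifnot(length(patches) > 0)
  lapply(patches, function(p) {
    p$pixels <- resize_bilinear(p$pixels, patch_side, patch_side)
    p
  })
}

#' Build a bag of instances from a whole image
#'
#' Runs the full pipeline: [grid_patch()] -> [threshold_filter()] ->
#' [balance_bag()] -> [finalize_patches()]. When `ground_truth` is given,
#' each instance's `hidden_label` is filled from its grid cell (augmented
#' copies inherit their source patch's label); hidden labels are carried
#' for evaluation only and are never visible to training.
#'
#' @param image Grayscale matrix.
#' @param label Bag-level ordinal class in \{0, 1, 2\}.
#' @param cfg A [bag_build_config()].
#' @param ground_truth Optional `oomil_ground_truth` from
#'   [generate_image()].
#' @param bag_id Identifier string.
#' @return An object of class `oomil_bag` with fields `bag_id`,
#'   `instances` (length `cfg$target_bag_size`), `label`.
#' @export
build_bag <- function(image, label, cfg = bag_build_config(),
                      ground_truth = NULL, bag_id = "bag") {
  label <- assert_class_index(label)
  patches <- grid_patch(image, cfg$grid_rows, cfg$grid_cols)
  if (!is.null(ground_truth)) {
    patches <- lapply(patches, function(p) {
      p$hidden_label <- ground_truth$instance_labels[p$grid_row + 1L, p$grid_col + 1L]
      p
    })
  }
  patches <- threshold_filter(patches, cfg)
  patches <- balance_bag(patches, cfg)
  patches <- finalize_patches(patches, cfg$patch_side)
  structure(list(bag_id = bag_id, instances = patches, label = label),
            class = "oomil_bag")
}

#' @export
print.oomil_bag <- function(x, ...) {
  side <- nrow(x$instances[[1]]$pixels)
  n_aug <- sum(vapply(x$instances, function(p) p$augmentation_tag != "none",
                      logical(1)))
  cat(sprintf("<oomil_bag> %s: label %d, %d instances (%d augmented), %dx%d px\n",
              x$bag_id, x$label, length(x$instances), n_aug, side, side))
  invisible(x)
}

#' Build bags for a whole generated dataset
#'
#' @param dataset A list of records from [generate_dataset()].
#' @param cfg A [bag_build_config()].
#' @param use_ground_truth Attach hidden instance labels for evaluation.
#' @return A list of `oomil_bag`.
#' @export
build_bags <- function(dataset, cfg = bag_build_config(), use_ground_truth = TRUE) {
  lapply(dataset, function(rec) {
    build_bag(rec$pixels, rec$truth$bag_label, cfg,
              ground_truth = if (use_ground_truth) rec$truth,
              bag_id = rec$bag_id)
  })
}
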