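# Synthetic mammogram-like image generator with instance-level ground truth.
#
# Images are tall grayscale fields (default 448 x 224) with a textured
# background, a near-zero border band (so background patches exercise the
# foreground filter), and 0..n dense lesion blobs composited by occlusion.
# Grade-1 lesions are smooth discs; grade-2 lesions are brighter and add a
# radial spicule perturbation to the outline, mirroring the benign-smooth
# vs. malignant-spiculated convention. The maximum lesion grade in an
# image always equals the bag label, and no lesion exceeds it.

#' Configuration for the synthetic image generator
#'
#' @param image_height,image_width Image size in pixels. Defaults 448 x 224
#'   so the 14 x 7 instance grid yields integer 32 x 32 cells.
#' @param n_bags_per_class Number of images generated per ordinal class.
#' @param background_mean,background_sd Mean and standard deviation of the
#'   textured background intensity (scale \[0,1\]).
#' @param border_margin Width in pixels of the near-zero border band.
#' @param lesion_intensity Named numeric vector `c("1" = , "2" = )` giving
#'   the peak intensity of grade-1 and grade-2 lesions. Must satisfy
#'   `lesion_intensity["2"] > lesion_intensity["1"] > background_mean`.
#' @param lesion_radius Nominal lesion radius in pixels (jittered ±20%).
#' @param n_lesions_range Integer range `c(min, max)` of lesions in a
#'   non-normal image.
#' @param irregularity Relative amplitude of the spicule perturbation on
#'   grade-2 lesion outlines (0 = smooth).
#' @param grid_rows,grid_cols Instance grid used to derive ground-truth
#'   instance labels (defaults 14 x 7).
#' @param seed Integer seed; every image draws from a counter-based
#'   substream of this seed.
#' @param contrast `"default"` or `"high"`; the high-contrast preset
#'   brightens lesions and reduces background noise, giving an easier task
#'   for selection-dynamics experiments.
#' @return An object of class `oomil_synth_config`.
#' @export
synth_config <- function(image_height = 448L,
                         image_width = 224L,
                         n_bags_per_class = 10L,
                         background_mean = 0.30,
                         background_sd = 0.03,
                         border_margin = 26L,
                         lesion_intensity = c("1" = 0.55, "2" = 0.85),
                         lesion_radius = 36,
                         n_lesions_range = c(1L, 3L),
                         irregularity = 0.35,
                         grid_rows = 14L,
                         grid_cols = 7L,
                         seed = 1L,
                         contrast = c("default", "high")) {
  contrast <- match.arg(contrast)
  if (contrast == "high") {
    if (missing(lesion_intensity)) lesion_intensity <- c("1" = 0.62, "2" = 0.95)
    if (missing(background_sd)) background_sd <- 0.04
  }
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_bags_per_class = as.integer(n_bags_per_class),
    background_mean = background_mean,
    background_sd = background_sd,
    border_margin = as.integer(border_margin),
    lesion_intensity = lesion_intensity,
    lesion_radius = lesion_radius,
    n_lesions_range = as.integer(n_lesions_range),
    irregularity = irregularity,
    grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols),
    seed = as.integer(seed),
    contrast = contrast
  )
  if (cfg$image_height %% cfg$grid_rows != 0 ||
      cfg$image_width %% cfg$grid_cols != 0) {
    stop("image dimensions must be divisible by the instance grid", call. = FALSE)
  }
  li <- cfg$lesion_intensity
  if (!(li[["2"]] > li[["1"]] && li[["1"]] > cfg$background_mean)) {
    stop("lesion intensities must satisfy grade2 > grade1 > background_mean",
         call. = FALSE)
  }
  if (cfg$n_lesions_range[1] < 1 || cfg$n_lesions_range[2] < cfg$n_lesions_range[1]) {
    stop("invalid n_lesions_range", call. = FALSE)
  }
  structure(cfg, class = "oomil_synth_config")
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# One lesion blob: a dense plateau at the grade's intensity with a soft
# edge ramp, composited over tissue by occlusion (maximum), the way a
# dense mass hides the parenchyma behind it. Grade-2 outlines are
# perturbed by radial spicules. Returns the local window's linear pixel
# indices, the intensity profile, and the mask of covered pixels.
render_blob <- function(h, w, cy, cx, radius, grade, level, irregularity) {
  edge <- 4 # soft-edge width in pixels
  reach <- ceiling(radius * (1 + irregularity) + edge + 1)
  rows <- max(1L, cy - reach):min(h, cy + reach)
  cols <- max(1L, cx - reach):min(w, cx + reach)
  dy <- rows - cy
  dx <- cols - cx
  rr <- sqrt(outer(dy^2, dx^2, `+`))
  r_eff <- radius
  if (grade == 2 && irregularity > 0) {
    theta <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
    phase <- stats::runif(1, 0, 2 * pi)
    r_eff <- radius * (1 + irregularity * cos(8 * theta + phase))
  }
  inside <- rr <= r_eff
  ramp <- pmin(pmax((r_eff - rr) / edge, 0), 1) # 1 deep inside, 0 at the rim
  idx <- outer(rows, (cols - 1) * h, `+`)
  list(idx = idx, level = level * ramp, mask = inside)
}

#' Generate one synthetic image with ground truth
#'
#' @param cfg An [synth_config()] object.
#' @param bag_label Ordinal class of the image: 0 (normal), 1 (benign),
#'   2 (cancer).
#' @param seed Optional integer seed for this image; when `NULL` the
#'   current RNG stream is used.
#' @return A list with elements `pixels` (matrix in \[0,1\]), `truth`
#'   (class `oomil_ground_truth`: `bag_label`, `instance_labels` matrix
#'   `grid_rows x grid_cols`, `lesions` data frame), invisibly usable by
#'   [build_bag()].
#' @export
generate_image <- function(cfg, bag_label, seed = NULL) {
  stopifnot(inherits(cfg, "oomil_synth_config"))
  bag_label <- assert_class_index(bag_label)
  run <- function() {
    h <- cfg$image_height; w <- cfg$image_width
    x <- matrix(stats::rnorm(h * w, cfg$background_mean, cfg$background_sd), h, w)
    # mild smooth texture so the background is not pure white noise
    ph <- stats::runif(2, 0, 2 * pi)
    x <- x + 0.02 * outer(sin(2 * pi * seq_len(h) / 131 + ph[1]),
                          cos(2 * pi * seq_len(w) / 83 + ph[2]))
    label_img <- matrix(0L, h, w)
    lesions <- data.frame(cy = integer(0), cx = integer(0),
                          grade = integer(0), radius = numeric(0))
    if (bag_label > 0) {
      n_les <- if (cfg$n_lesions_range[1] == cfg$n_lesions_range[2]) {
        cfg$n_lesions_range[1]
      } else {
        sample(cfg$n_lesions_range[1]:cfg$n_lesions_range[2], 1)
      }
      grades <- c(bag_label,
                  if (n_les > 1) sample(seq_len(bag_label), n_les - 1, replace = TRUE))
      for (g in grades) {
        radius <- cfg$lesion_radius * stats::runif(1, 0.8, 1.2)
        reach <- ceiling(radius * (1 + cfg$irregularity) + 5)
        lo_y <- cfg$border_margin + reach + 1
        hi_y <- h - cfg$border_margin - reach
        lo_x <- cfg$border_margin + reach + 1
        hi_x <- w - cfg$border_margin - reach
        if (lo_y > hi_y || lo_x > hi_x) {
          stop("image too small for the configured lesion radius and border",
               call. = FALSE)
        }
        cy <- sample(lo_y:hi_y, 1)
        cx <- sample(lo_x:hi_x, 1)
        level <- cfg$lesion_intensity[[as.character(g)]]
        blob <- render_blob(h, w, cy, cx, radius, g, level, cfg$irregularity)
        # dense mass occludes the tissue behind it (with mild texture)
        lesion_px <- blob$level * (1 + stats::rnorm(length(blob$level), 0, 0.03))
        x[blob$idx] <- pmax(x[blob$idx], lesion_px)
        label_img[blob$idx[blob$mask]] <- pmax(label_img[blob$idx[blob$mask]], g)
        lesions <- rbind(lesions,
                         data.frame(cy = cy, cx = cx, grade = g, radius = radius))
      }
    }
    # near-zero border band
    bm <- cfg$border_margin
    if (bm > 0) {
      border_val <- 0.01
      x[seq_len(bm), ] <- border_val
      x[(h - bm + 1):h, ] <- border_val
      x[, seq_len(bm)] <- border_val
      x[, (w - bm + 1):w] <- border_val
    }
    x <- pmin(pmax(x, 0), 1)
    ch <- h %/% cfg$grid_rows; cw <- w %/% cfg$grid_cols
    inst <- matrix(0L, cfg$grid_rows, cfg$grid_cols)
    for (r in seq_len(cfg$grid_rows)) {
      for (cc in seq_len(cfg$grid_cols)) {
        cell <- label_img[((r - 1) * ch + 1):(r * ch), ((cc - 1) * cw + 1):(cc * cw)]
        inst[r, cc] <- max(cell)
      }
    }
    truth <- structure(
      list(bag_label = bag_label, instance_labels = inst, lesions = lesions),
      class = "oomil_ground_truth"
    )
    stopifnot(max(truth$instance_labels) == bag_label)
    list(pixels = x, truth = truth)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Generate a stratified synthetic dataset
#'
#' Produces `n_bags_per_class` images per class (0, 1, 2), each from its
#' own counter-based substream of `cfg$seed` so the dataset is
#' deterministic. When `dir` is given, images are written as 8-bit
#' grayscale PNGs and a JSON-lines ground-truth manifest
#' (`manifest.jsonl`: one record per bag with `bag_id`, `image_path`,
#' `bag_label`, `instance_labels` row-major) is written alongside.
#'
#' @param cfg An [synth_config()] object.
#' @param dir Optional output directory.
#' @return A list of records `list(bag_id, pixels, truth, image_path)`.
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "oomil_synth_config"), cfg$n_bags_per_class >= 1)
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  out <- list()
  idx <- 0L
  for (label in 0:2) {
    for (i in seq_len(cfg$n_bags_per_class)) {
      idx <- idx + 1L
      bag_id <- sprintf("bag_%04d_c%d", idx, label)
      img <- generate_image(cfg, label, seed = substream_seed(cfg$seed, idx))
      path <- NULL
      if (!is.null(dir)) {
        path <- file.path(dir, paste0(bag_id, ".png"))
        png::writePNG(img$pixels, path)
      }
      out[[idx]] <- list(bag_id = bag_id, pixels = img$pixels,
                         truth = img$truth, image_path = path)
    }
  }
  if (!is.null(dir)) {
    lines <- vapply(out, function(rec) {
      jsonlite::toJSON(list(
        bag_id = rec$bag_id,
        image_path = basename(rec$image_path),
        bag_label = rec$truth$bag_label,
        instance_labels = as.integer(t(rec$truth$instance_labels))
      ), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, file.path(dir, "manifest.jsonl"))
  }
  invisible(out)
}

#' Read a ground-truth manifest written by [generate_dataset()]
#'
#' @param path Path to a `manifest.jsonl` file.
#' @param grid_rows,grid_cols Grid shape used to refold the row-major
#'   instance labels.
#' @return A list of records with `bag_id`, `image_path`, `bag_label`,
#'   `instance_labels` (matrix).
#' @export
read_manifest <- function(path, grid_rows = 14L, grid_cols = 7L) {
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line)
    rec$instance_labels <- matrix(as.integer(rec$instance_labels),
                                  grid_rows, grid_cols, byrow = TRUE)
    rec
  })
}

#' Labeled single-patch test set for instance-level evaluation
#'
#' Emulates evaluating on physician-annotated region-of-interest crops:
#' for classes 1 and 2 a cell-sized crop is taken at the center of a
#' lesion of exactly that grade; for class 0, from lesion-free interior
#' tissue of a normal image. Crops are resized to
#' `patch_side x patch_side`.
#'
#' @param cfg An [synth_config()] object.
#' @param n_per_class Patches per class.
#' @param patch_side Output patch side in pixels (default 224).
#' @return A list of `list(pixels, label)` of length `3 * n_per_class`.
#' @export
make_instance_test_set <- function(cfg, n_per_class, patch_side = 224L) {
  stopifnot(inherits(cfg, "oomil_synth_config"), n_per_class >= 1)
  ch <- cfg$image_height %/% cfg$grid_rows
  cw <- cfg$image_width %/% cfg$grid_cols
  out <- list()
  n <- 0L
  for (label in 0:2) {
    for (i in seq_len(n_per_class)) {
      n <- n + 1L
      sd_i <- substream_seed(cfg$seed, 500000L + n)
      img <- generate_image(cfg, label, seed = sd_i)
      if (label == 0) {
        center <- with_local_seed(sd_i + 1L, {
          c(sample((cfg$border_margin + ch):(cfg$image_height - cfg$border_margin - ch), 1),
            sample((cfg$border_margin + cw):(cfg$image_width - cfg$border_margin - cw), 1))
        })
      } else {
        les <- img$truth$lesions
        les <- les[les$grade == label, , drop = FALSE]
        center <- c(les$cy[1], les$cx[1])
      }
      r0 <- min(max(center[1] - ch %/% 2, 1), cfg$image_height - ch)
      c0 <- min(max(center[2] - cw %/% 2, 1), cfg$image_width - cw)
      crop <- img$pixels[(r0 + 1):(r0 + ch), (c0 + 1):(c0 + cw)]
      out[[n]] <- list(pixels = resize_bilinear(crop, patch_side, patch_side),
                       label = label)
    }
  }
  out
}
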