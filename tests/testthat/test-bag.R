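test_that("grid patching tiles the image exactly and reassembles it", {
  cfg <- small_synth_cfg()
  img <- generate_image(cfg, 1, seed = 5)$pixels
  patches <- grid_patch(img, 14L, 7L)
  expect_length(patches, 98)
  expect_true(all(vapply(patches, function(p) all(dim(p$pixels) == c(32, 32)),
                         logical(1))))
  rows <- vapply(patches, function(p) p$grid_row, integer(1))
  cols <- vapply(patches, function(p) p$grid_col, integer(1))
  expect_equal(rows[1:8], c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L)) # row-major order
  expect_equal(cols[1:8], c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 0L))

  rebuilt <- matrix(0, 448, 224)
  for (p in patches) {
    rebuilt[p$grid_row * 32 + 1:32, p$grid_col * 32 + 1:32] <- p$pixels
  }
  expect_identical(rebuilt, img)
})

test_that("a 1x1 grid returns the image itself", {
  m <- matrix(runif(35), 5, 7)
  patches <- grid_patch(m, 1L, 1L)
  expect_length(patches, 1)
  expect_identical(patches[[1]]$pixels, m)
})

test_that("non-divisible images are center-cropped before tiling", {
  m <- matrix(runif(450 * 230), 450, 230)
  patches <- grid_patch(m, 14L, 7L)
  expect_length(patches, 98)
  rebuilt <- matrix(0, 448, 224)
  for (p in patches) {
    rebuilt[p$grid_row * 32 + 1:32, p$grid_col * 32 + 1:32] <- p$pixels
  }
  expect_identical(rebuilt, m[2:449, 4:227])
})

test_that("threshold filtering keeps exactly the sufficiently-bright patches", {
  cfg <- bag_build_config(foreground_threshold = 0.08,
                          min_foreground_fraction = 0.25)
  zeros <- constant_patches(0)[[1]]
  ones <- constant_patches(1)[[1]]
  mixed <- zeros
  mixed$pixels <- matrix(0, 10, 10)
  mixed$pixels[1:30] <- 0.5 # 30% of pixels above threshold
  kept <- threshold_filter(list(zeros, ones, mixed), cfg)
  expect_length(kept, 2)
  expect_identical(kept[[1]]$pixels, ones$pixels)

  cfg35 <- bag_build_config(min_foreground_fraction = 0.35)
  expect_length(threshold_filter(list(ones, mixed), cfg35), 1)
  expect_error(threshold_filter(list(zeros), cfg), "empty bag")
})

test_that("raising the foreground requirement never keeps more patches", {
  set.seed(7)
  patches <- lapply(1:40, function(i) {
    p <- constant_patches(0)[[1]]
    p$pixels <- matrix(runif(64) * runif(1), 8, 8)
    p
  })
  prev <- Inf
  for (frac in c(0, 0.2, 0.4, 0.6, 0.8)) {
    cfg <- bag_build_config(min_foreground_fraction = frac)
    n <- tryCatch(length(threshold_filter(patches, cfg)), error = function(e) 0L)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("balancing trims surpluses toward the brightest patches", {
  cfg <- small_bag_cfg(target_bag_size = 70L)
  patches <- lapply(1:98, function(i) {
    p <- constant_patches(0, side = 10L)[[1]]
    p$pixels[seq_len(i)] <- 1 # foreground fraction i / 100
    p$grid_row <- as.integer((i - 1) %/% 7)
    p$grid_col <- as.integer((i - 1) %% 7)
    p
  })
  out <- balance_bag(patches, cfg)
  expect_length(out, 70)
  expect_true(all(vapply(out, function(p) p$augmentation_tag == "none",
                         logical(1))))
  # the 70 highest-foreground patches survive, in their original order
  expect_equal(vapply(out, function(p) sum(p$pixels), numeric(1)),
               as.numeric(29:98))
})

test_that("balancing a full-size or short bag behaves as specified", {
  cfg <- small_bag_cfg(target_bag_size = 70L)
  exact <- constant_patches(rep(0.5, 70))
  expect_identical(balance_bag(exact, cfg), exact)

  short <- constant_patches(seq(0.2, 0.9, length.out = 60))
  out <- balance_bag(short, cfg)
  expect_length(out, 70)
  tags <- vapply(out, function(p) p$augmentation_tag, character(1))
  expect_equal(sum(tags != "none"), 10)
  expect_equal(unique(tags[tags != "none"]), "hflip") # first transform round
  # copies come round-robin from the first ten survivors
  expect_equal(vapply(out[61:70], function(p) p$pixels[1, 1], numeric(1)),
               vapply(short[1:10], function(p) p$pixels[1, 1], numeric(1)))
})

test_that("augmented copies are true transforms of their sources", {
  p <- constant_patches(0)[[1]]
  p$pixels <- matrix(runif(36), 6, 6)
  cfg <- bag_build_config(target_bag_size = 9L)
  out <- balance_bag(list(p), cfg)
  expect_length(out, 9)
  tags <- vapply(out, function(q) q$augmentation_tag, character(1))
  expect_equal(tags[1], "none")
  expect_equal(tags[2:9][1:5], c("hflip", "vflip", "rot90", "rot180", "rot270"))
  expect_identical(out[[2]]$pixels, p$pixels[, 6:1])
  expect_identical(out[[3]]$pixels, p$pixels[6:1, ])
  expect_identical(out[[5]]$pixels, p$pixels[6:1, 6:1])
})

test_that("finalize resizes with bilinear interpolation", {
  p <- constant_patches(0.37, side = 32L)
  out <- finalize_patches(p, 224L)
  expect_equal(dim(out[[1]]$pixels), c(224, 224))
  expect_true(all(abs(out[[1]]$pixels - 0.37) < 1e-12)) # constant stays constant

  q <- constant_patches(0)[[1]]
  q$pixels <- matrix(runif(224 * 224), 224, 224)
  expect_identical(finalize_patches(list(q), 224L)[[1]]$pixels, q$pixels)

  # linear ramps are reproduced exactly by bilinear interpolation
  ramp <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16)
  up <- resize_bilinear(ramp, 16, 48)
  expect_equal(dim(up), c(16, 48))
  expect_true(all(diff(up[1, ]) >= -1e-12))
})

test_that("build_bag produces the contracted bag and carries hidden labels", {
  cfg <- small_synth_cfg()
  bcfg <- small_bag_cfg()
  ds <- generate_dataset(cfg)
  bags <- build_bags(ds, bcfg)
  for (i in seq_along(bags)) {
    bag <- bags[[i]]
    expect_length(bag$instances, 70)
    expect_true(all(vapply(bag$instances,
                           function(p) all(dim(p$pixels) == c(32, 32)),
                           logical(1))))
    hidden <- vapply(bag$instances, function(p) p$hidden_label, integer(1))
    expect_false(anyNA(hidden))
    expect_true(all(hidden <= bag$label))
    if (bag$label > 0) expect_true(any(hidden == bag$label))
  }
  normal <- bags[[1]]
  expect_true(all(vapply(normal$instances, function(p) p$hidden_label,
                         integer(1)) == 0))
})

test_that("augmentation-filled bags inherit hidden labels from sources", {
  cfg <- small_synth_cfg()
  img <- generate_image(cfg, 2, seed = 8)
  # a stricter filter drops edge cells, forcing augmentation to reach 70
  bcfg <- small_bag_cfg(min_foreground_fraction = 0.5)
  bag <- build_bag(img$pixels, 2, bcfg, img$truth)
  expect_length(bag$instances, 70)
  tags <- vapply(bag$instances, function(p) p$augmentation_tag, character(1))
  expect_equal(sum(tags != "none"), 10) # 60 interior cells survive
  hidden <- vapply(bag$instances, function(p) p$hidden_label, integer(1))
  expect_true(all(hidden <= 2))
})
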