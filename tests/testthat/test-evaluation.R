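test_that("ordinal score thresholds map to classes monotonically", {
  cuts <- ordinal_cutpoints(b1 = 0.5, b2 = 1.5)
  expect_equal(predict_class(-2, cuts), 0L)
  expect_equal(predict_class(1.0, cuts), 1L)
  expect_equal(predict_class(7, cuts), 2L)
  expect_equal(predict_class(c(0.2, 0.3, 0.5)), 2L)
  expect_equal(predict_class(c(0.4, 0.4, 0.2)), 0L) # argmax tie -> lower class
  preds <- vapply(seq(-3, 4, by = 0.05), predict_class, integer(1), cuts = cuts)
  expect_true(all(diff(preds) >= 0))
})

test_that("perfect predictions yield unit metrics", {
  cm <- diag(c(2, 2, 2))
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class_accuracy, rep(1, 3))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$f1, 1)
})

test_that("metrics match an independently hand-computed contingency oracle", {
  cm <- matrix(c(5, 3, 2,
                 1, 6, 3,
                 0, 2, 8), nrow = 3, byrow = TRUE)
  m <- metrics_from_confusion(cm, "macro_ovr")
  expect_equal(sum(m$confusion), 30)
  expect_equal(m$accuracy, 19 / 30, tolerance = 1e-12)
  expect_equal(m$per_class_accuracy, c(5 / 10, 6 / 10, 8 / 10),
               tolerance = 1e-12)
  sens <- (5 / 10 + 6 / 10 + 8 / 10) / 3
  spec <- (19 / 20 + 15 / 20 + 15 / 20) / 3
  prec <- (5 / 6 + 6 / 11 + 8 / 13) / 3
  expect_equal(m$sensitivity, sens, tolerance = 1e-12)
  expect_equal(m$specificity, spec, tolerance = 1e-12)
  expect_equal(m$precision, prec, tolerance = 1e-12)
  expect_equal(m$f1, 2 * prec * sens / (prec + sens), tolerance = 1e-12)

  b <- metrics_from_confusion(cm, "disease_binary")
  expect_equal(b$sensitivity, 19 / 20, tolerance = 1e-12)
  expect_equal(b$specificity, 5 / 10, tolerance = 1e-12)
  expect_equal(b$precision, 19 / 24, tolerance = 1e-12)
  expect_equal(b$f1, 2 * (19 / 24) * (19 / 20) / (19 / 24 + 19 / 20),
               tolerance = 1e-12)
})

test_that("macro metrics are invariant to class relabeling", {
  cm <- matrix(c(5, 3, 2, 1, 6, 3, 0, 2, 8), nrow = 3, byrow = TRUE)
  m <- metrics_from_confusion(cm)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(3, 2, 1))) {
    mp <- metrics_from_confusion(cm[perm, perm])
    expect_equal(mp$accuracy, m$accuracy, tolerance = 1e-12)
    expect_equal(mp$sensitivity, m$sensitivity, tolerance = 1e-12)
    expect_equal(mp$specificity, m$specificity, tolerance = 1e-12)
    expect_equal(mp$precision, m$precision, tolerance = 1e-12)
    expect_equal(sort(mp$per_class_accuracy), sort(m$per_class_accuracy),
                 tolerance = 1e-12)
  }
})

test_that("empty true classes are excluded from macro averages", {
  cm <- matrix(c(4, 1, 0,
                 2, 3, 0,
                 0, 0, 0), nrow = 3, byrow = TRUE)
  m <- metrics_from_confusion(cm)
  expect_true(is.na(m$per_class_accuracy[3]))
  expect_equal(m$sensitivity, (4 / 5 + 3 / 5) / 2, tolerance = 1e-12)
})

test_that("evaluate fills the confusion matrix consistently with predictions", {
  cfg <- small_synth_cfg()
  ts <- make_instance_test_set(cfg, 4L, patch_side = 32L)
  net <- build_network(small_net_spec(), seed = 3)
  cuts <- ordinal_cutpoints()
  m <- evaluate(net, cuts, ts)
  expect_equal(sum(m$confusion), length(ts))
  preds <- vapply(unlist(forward_bag(net, ts)), predict_class, integer(1),
                  cuts = cuts)
  truth <- vapply(ts, function(p) p$label, integer(1))
  expect_equal(m$accuracy, mean(preds == truth), tolerance = 1e-12)

  net3 <- build_network(small_net_spec(head = "softmax3"), seed = 3)
  m3 <- evaluate(net3, cuts, ts)
  expect_equal(sum(m3$confusion), length(ts))
})

test_that("kid statistics summarize selection quality per epoch", {
  bags <- list(
    structure(list(bag_id = "n", instances = list(), label = 0L),
              class = "oomil_bag"),
    structure(list(bag_id = "p", instances = list(), label = 2L),
              class = "oomil_bag")
  )
  history <- list(
    list(epoch = 1L, bag_id = "p", selected_indices = 1:4,
         selected_losses = rep(0, 4), n_true_positive = 4L, mean_loss = 0),
    list(epoch = 1L, bag_id = "n", selected_indices = 1:4,
         selected_losses = rep(0, 4), n_true_positive = 4L, mean_loss = 0),
    list(epoch = 2L, bag_id = "p", selected_indices = 1:4,
         selected_losses = rep(0, 4), n_true_positive = 2L, mean_loss = 0)
  )
  ks <- kid_stats(history, bags, 4L)
  expect_equal(ks$epoch, c(1L, 2L))
  expect_equal(ks$mean_s, c(4, 2)) # normal bag excluded
  expect_equal(ks$precision, c(1, 0.5))

  hist_na <- list(list(epoch = 1L, bag_id = "p", selected_indices = 1:4,
                       selected_losses = rep(0, 4),
                       n_true_positive = NA_integer_, mean_loss = 0))
  expect_error(kid_stats(hist_na, bags, 4L), "hidden")
})

test_that("random selection precision approaches the positive fraction", {
  # bag with 10% positive instances; seeded Monte-Carlo over selections
  n <- 70L
  positives <- 7L
  hidden <- c(rep(2L, positives), rep(0L, n - positives))
  set.seed(123)
  prec <- replicate(4000, {
    sel <- sample.int(n, 4)
    mean(hidden[sel] == 2L)
  })
  expect_equal(mean(prec), 0.1, tolerance = 0.05)
})

test_that("selection rendering outlines exactly the selected patches", {
  bags <- make_small_bags(n_per_class = 1L)
  bag <- bags[[3]]
  hidden <- vapply(bag$instances, function(p) p$hidden_label, integer(1))
  pos <- which(hidden == bag$label)[1:2]
  neg <- which(hidden != bag$label)[1:2]
  record <- list(epoch = 1L, bag_id = bag$bag_id,
                 selected_indices = c(pos, neg),
                 selected_losses = rep(0, 4), n_true_positive = 2L)
  img <- render_selection(bag, record, border = 2L)
  expect_equal(dim(img), c(10 * 32, 7 * 32, 3))
  is_red <- img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0
  is_blue <- img[, , 1] == 0 & img[, , 2] == 0 & img[, , 3] == 1
  # 2 red and 2 blue outlines, each a 32x32 frame of thickness 2
  frame_px <- 2 * (2 * 32 + 2 * 32) - 4 * 4
  expect_equal(sum(is_red), 2 * frame_px)
  expect_equal(sum(is_blue), 2 * frame_px)

  all_correct <- record
  all_correct$selected_indices <- which(hidden == bag$label)[1:4]
  all_correct$n_true_positive <- 4L
  img2 <- render_selection(bag, all_correct, border = 2L)
  expect_equal(sum(img2[, , 1] == 1 & img2[, , 2] == 0 & img2[, , 3] == 0),
               4 * frame_px)
  expect_equal(sum(img2[, , 1] == 0 & img2[, , 2] == 0 & img2[, , 3] == 1), 0)

  # unknown truth: neutral outline color
  bag_na <- bag
  bag_na$instances <- lapply(bag$instances, function(p) {
    p$hidden_label <- NA_integer_
    p
  })
  img3 <- render_selection(bag_na, record, border = 2L)
  expect_equal(sum(img3[, , 1] == 1 & img3[, , 2] == 1 & img3[, , 3] == 0),
               4 * frame_px)

  bad <- record
  bad$selected_indices <- c(1L, 500L)
  expect_error(render_selection(bag, bad), "out of range")
  bad2 <- record
  bad2$bag_id <- "other"
  expect_error(render_selection(bag, bad2), "does not refer")

  path <- withr::local_tempfile(fileext = ".png")
  render_selection(bag, record, path = path)
  expect_true(file.exists(path))
})
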