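# Instance-level prediction, metric suite, and key-instance-detection
# diagnostics.

#' Ordinal class from a scalar score or probability vector
#'
#' Scalar (ordinal head): 0 below `b1`, 1 in \[`b1`, `b2`), 2 at or above
#' `b2` — monotone non-decreasing in the score. Probability vector
#' (softmax head): argmax, ties toward the lower class.
#'
#' @param score Numeric scalar or length-3 probability vector.
#' @param cuts An [ordinal_cutpoints()] (scalar scores only).
#' @return Integer class in \{0, 1, 2\}.
#' @export
predict_class <- function(score, cuts = ordinal_cutpoints()) {
  if (length(score) == 3) {
    return(as.integer(which.max(score) - 1L)) # which.max ties -> lower class
  }
  b2 <- cutpoint_b2(cuts)
  if (score < cuts$b1) 0L else if (score < b2) 1L else 2L
}

#' Metrics from a 3x3 confusion matrix
#'
#' Rows are true classes, columns predicted. `accuracy` is the trace over
#' the total; `per_class_accuracy` is per-true-class recall (an empty row
#' yields `NA` and is excluded from macro means). Under `macro_ovr`,
#' sensitivity/specificity/precision are unweighted means of the
#' one-vs-rest values over the three classes; under `disease_binary`,
#' classes \{1, 2\} are collapsed to "diseased" (positive) versus normal
#' and the plain binary definitions apply. `f1` is the harmonic mean of
#' the report's precision and sensitivity.
#'
#' @param cm 3x3 numeric matrix of counts.
#' @param mode `"macro_ovr"` (default) or `"disease_binary"`.
#' @return An object of class `oomil_metrics` (a list): `accuracy`,
#'   `per_class_accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `f1`, `averaging_mode`, `confusion`.
#' @export
metrics_from_confusion <- function(cm, mode = c("macro_ovr", "disease_binary")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(cm), all(dim(cm) == 3), all(cm >= 0))
  total <- sum(cm)
  stopifnot(total > 0)
  acc <- sum(diag(cm)) / total
  row_sums <- rowSums(cm)
  per_class <- ifelse(row_sums > 0, diag(cm) / row_sums, NA_real_)
  if (mode == "macro_ovr") {
    sens <- spec <- prec <- numeric(3)
    for (c in 1:3) {
      tp <- cm[c, c]
      fn <- row_sums[c] - tp
      fp <- sum(cm[, c]) - tp
      tn <- total - tp - fn - fp
      sens[c] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      spec[c] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
      prec[c] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    }
    sensitivity <- mean(sens, na.rm = TRUE)
    specificity <- mean(spec, na.rm = TRUE)
    precision <- mean(prec, na.rm = TRUE)
  } else {
    tp <- sum(cm[2:3, 2:3])
    fn <- sum(cm[2:3, 1])
    fp <- sum(cm[1, 2:3])
    tn <- cm[1, 1]
    sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  structure(list(accuracy = acc,
                 per_class_accuracy = unname(per_class),
                 sensitivity = sensitivity, specificity = specificity,
                 precision = precision, f1 = f1,
                 averaging_mode = mode, confusion = cm),
            class = "oomil_metrics")
}

#' @export
print.oomil_metrics <- function(x, ...) {
  cat(sprintf("<oomil_metrics> (%s)\n", x$averaging_mode))
  cat(sprintf("  accuracy    %.4f\n", x$accuracy))
  cat(sprintf("  per-class   %s\n",
              paste(sprintf("%.4f", x$per_class_accuracy), collapse = " / ")))
  cat(sprintf("  sensitivity %.4f  specificity %.4f\n", x$sensitivity, x$specificity))
  cat(sprintf("  precision   %.4f  F1 %.4f\n", x$precision, x$f1))
  invisible(x)
}

#' Evaluate a model on a labeled instance test set
#'
#' Predicts a class for every patch (ordinal head thresholded by `cuts`,
#' softmax head by argmax), fills the 3x3 confusion matrix, and computes
#' the metric suite under the requested averaging mode.
#'
#' @param net An `oomil_network`.
#' @param cuts An [ordinal_cutpoints()].
#' @param test_set List of `list(pixels, label)` from
#'   [make_instance_test_set()].
#' @param mode Averaging mode, see [metrics_from_confusion()].
#' @return An `oomil_metrics` object (confusion matrix in `$confusion`).
#' @export
evaluate <- function(net, cuts, test_set, mode = "macro_ovr") {
  stopifnot(length(test_set) > 0)
  S <- score_instances(net, test_set)
  pred <- if (net$spec$head == "softmax3") {
    apply(S, 1, which.max) - 1L
  } else {
    vapply(S[, 1], predict_class, integer(1), cuts = cuts)
  }
  truth <- vapply(test_set, function(p) as.integer(p$label), integer(1))
  cm <- matrix(0, 3, 3, dimnames = list(true = 0:2, pred = 0:2))
  for (i in seq_along(pred)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1
  }
  metrics_from_confusion(cm, mode)
}

#' Key-instance-detection statistics per epoch
#'
#' Restricted to bags with label > 0 (only those have true positive
#' instances to find): per epoch, the mean number of correctly selected
#' key instances (the "S" diagnostic) and the selection precision
#' `sum(S) / (k * n_bags)`.
#'
#' @param history Selection-record list from [train()] (`fit$history`).
#' @param bags The training bags (for their labels and hidden labels).
#' @param k Number of key instances per selection.
#' @return A data frame with columns `epoch`, `mean_s`, `precision`.
#' @export
kid_stats <- function(history, bags, k) {
  labels <- vapply(bags, function(b) b$label, integer(1))
  names(labels) <- vapply(bags, function(b) b$bag_id, character(1))
  recs <- Filter(function(r) labels[[r$bag_id]] > 0, history)
  if (length(recs) == 0) stop("no positive-bag records in history", call. = FALSE)
  s_vals <- vapply(recs, function(r) as.numeric(r$n_true_positive), numeric(1))
  if (anyNA(s_vals)) stop("hidden instance labels are required", call. = FALSE)
  epochs <- vapply(recs, function(r) r$epoch, integer(1))
  out <- do.call(rbind, lapply(sort(unique(epochs)), function(e) {
    s <- s_vals[epochs == e]
    data.frame(epoch = e, mean_s = mean(s),
               precision = sum(s) / (k * length(s)))
  }))
  rownames(out) <- NULL
  out
}

#' Render a bag with its selected key instances outlined
#'
#' Lays the bag's patches out as a montage in instance order (row-major,
#' `ncol` per row). Selected instances whose hidden label equals the bag
#' label are outlined in red, incorrect selections in blue; without
#' hidden labels every selection is outlined in yellow.
#'
#' @param bag An `oomil_bag`.
#' @param record A selection record referring to this bag.
#' @param path Optional PNG output path.
#' @param ncol Montage columns (default 7).
#' @param border Outline thickness in pixels.
#' @return Invisibly, the RGB montage array (`h x w x 3`).
#' @export
render_selection <- function(bag, record, path = NULL, ncol = 7L, border = 3L) {
  if (!identical(record$bag_id, bag$bag_id)) {
    stop("record does not refer to this bag", call. = FALSE)
  }
  n <- length(bag$instances)
  if (any(record$selected_indices < 1 | record$selected_indices > n)) {
    stop("selected index out of range", call. = FALSE)
  }
  side <- nrow(bag$instances[[1]]$pixels)
  nrow_m <- ceiling(n / ncol)
  img <- array(0, dim = c(nrow_m * side, ncol * side, 3))
  for (i in seq_len(n)) {
    r0 <- ((i - 1) %/% ncol) * side
    c0 <- ((i - 1) %% ncol) * side
    g <- bag$instances[[i]]$pixels
    for (ch in 1:3) img[r0 + seq_len(side), c0 + seq_len(side), ch] <- g
  }
  for (i in record$selected_indices) {
    hl <- bag$instances[[i]]$hidden_label
    col <- if (is.na(hl)) c(1, 1, 0) # yellow: truth unknown
           else if (hl == bag$label) c(1, 0, 0) # red: correct selection
           else c(0, 0, 1) # blue: incorrect selection
    r0 <- ((i - 1) %/% ncol) * side
    c0 <- ((i - 1) %% ncol) * side
    rows <- r0 + seq_len(side); cols <- c0 + seq_len(side)
    b <- seq_len(border)
    for (ch in 1:3) {
      img[r0 + b, cols, ch] <- col[ch]
      img[r0 + side - b + 1, cols, ch] <- col[ch]
      img[rows, c0 + b, ch] <- col[ch]
      img[rows, c0 + side - b + 1, ch] <- col[ch]
    }
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Ablation report comparing losses and decomposition strategies
#'
#' Trains the direct ordinal model, the cross-entropy (softmax head)
#' variant, and the ordered binary-decomposition baseline on the same
#' bags for each requested k, and evaluates instance-level accuracy on a
#' labeled test set. Produces the loss-by-k accuracy layout used for
#' ablation comparisons.
#'
#' @param bags Training bags.
#' @param test_set Labeled instance test set.
#' @param spec Network spec (scalar head; the softmax variant is derived
#'   from it).
#' @param cfg Base [train_config()]; its `k` is replaced by each value in
#'   `k_values`.
#' @param k_values Integer vector of k values to compare.
#' @return A data frame with columns `method`, `k`, `accuracy`.
#' @export
ablation_report <- function(bags, test_set, spec, cfg, k_values = 4L) {
  spec3 <- spec; spec3$head <- "softmax3"; spec3$out_units <- 3L
  rows <- list()
  for (k in k_values) {
    run_cfg <- cfg; run_cfg$k <- as.integer(k)
    ord_cfg <- run_cfg; ord_cfg$loss <- "min_uncertainty_ordinal"
    fit_ord <- train(build_network(spec, seed = run_cfg$seed),
                     ordinal_cutpoints(), bags, ord_cfg)
    acc_ord <- evaluate(fit_ord$net, fit_ord$cuts, test_set)$accuracy

    ce_cfg <- run_cfg; ce_cfg$loss <- "cross_entropy"
    fit_ce <- train(build_network(spec3, seed = run_cfg$seed),
                    ordinal_cutpoints(), bags, ce_cfg)
    acc_ce <- evaluate(fit_ce$net, fit_ce$cuts, test_set)$accuracy

    baseline <- train_omil_baseline(bags, run_cfg, spec)
    pred <- predict_omil(baseline, test_set)
    truth <- vapply(test_set, function(p) as.integer(p$label), integer(1))
    acc_omil <- mean(pred == truth)

    rows[[length(rows) + 1L]] <- data.frame(
      method = c("min_uncertainty_ordinal (direct)",
                 "cross_entropy (direct)",
                 "binary_decomposition (baseline)"),
      k = k,
      accuracy = c(acc_ord, acc_ce, acc_omil))
  }
  do.call(rbind, rows)
}
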