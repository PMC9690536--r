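# Per-instance losses against the bag label.
#
# The default loss for the scalar (ordinal) head is an all-threshold
# cumulative-logistic penalty with two trainable cutpoints b1 < b2
# partitioning the score axis into the three ordered class regions:
#
#   L(s, y) = sum_{c in {0,1}} softplus( z_c * (s - b_{c+1}) ),
#   z_c = +1 if y <= c else -1.
#
# Each term penalizes a violated ordering of the score against one class
# boundary, so adjacent-class confusions are always penalized no more
# than distant-class ones. The cutpoints are parameterized as b1 and
# b2 = b1 + softplus(delta), which keeps b2 > b1 for any real delta.

#' Trainable ordinal cutpoints
#'
#' @param b1 First cutpoint (default 0.5).
#' @param b2 Second cutpoint used to initialize `delta` via the inverse
#'   softplus (default 1.5, i.e. midpoints between consecutive class
#'   indices 0, 1, 2).
#' @return An object of class `oomil_cutpoints` with fields `b1`, `delta`.
#' @export
ordinal_cutpoints <- function(b1 = 0.5, b2 = 1.5) {
  stopifnot(b2 > b1)
  structure(list(b1 = b1, delta = softplus_inv(b2 - b1)),
            class = "oomil_cutpoints")
}

#' @export
print.oomil_cutpoints <- function(x, ...) {
  cat(sprintf("<oomil_cutpoints> b1 = %.4f, b2 = %.4f\n", x$b1, cutpoint_b2(x)))
  invisible(x)
}

#' Second cutpoint implied by the parameterization
#' @param cuts An `oomil_cutpoints`.
#' @return `b1 + softplus(delta)`.
#' @export
cutpoint_b2 <- function(cuts) cuts$b1 + softplus(cuts$delta)

LOSS_CHOICES <- c("min_uncertainty_ordinal", "squared_error_ordinal", "cross_entropy")

#' All-threshold ordinal uncertainty loss
#'
#' @param score Real scalar score (or vector of scores) from the ordinal
#'   head.
#' @param label Ordinal class in \{0, 1, 2\}.
#' @param cuts An [ordinal_cutpoints()].
#' @return Non-negative loss, one per score.
#' @export
ordinal_uncertainty_loss <- function(score, label, cuts) {
  label <- assert_class_index(label)
  if (any(!is.finite(score))) stop("non-finite score", call. = FALSE)
  b <- c(cuts$b1, cutpoint_b2(cuts))
  z0 <- if (label <= 0) 1 else -1
  z1 <- if (label <= 1) 1 else -1
  softplus(z0 * (score - b[1])) + softplus(z1 * (score - b[2]))
}

# Loss and analytic gradients w.r.t. score, b1 and delta (vectorized over
# scores). Used by the trainer; the finite-difference tests check it.
ordinal_loss_grad <- function(score, label, cuts) {
  b2 <- cutpoint_b2(cuts)
  z0 <- if (label <= 0) 1 else -1
  z1 <- if (label <= 1) 1 else -1
  s0 <- sigmoid(z0 * (score - cuts$b1))
  s1 <- sigmoid(z1 * (score - b2))
  list(loss = softplus(z0 * (score - cuts$b1)) + softplus(z1 * (score - b2)),
       dscore = z0 * s0 + z1 * s1,
       db1 = -z0 * s0 - z1 * s1, # b2 moves with b1
       ddelta = -z1 * s1 * sigmoid(cuts$delta))
}

#' Squared-error ordinal loss
#'
#' The simplest alternative reading: the scalar score regresses the class
#' index, `L = (s - y)^2`.
#' @inheritParams ordinal_uncertainty_loss
#' @return Non-negative loss, one per score.
#' @export
squared_error_loss <- function(score, label, cuts = NULL) {
  label <- assert_class_index(label)
  if (any(!is.finite(score))) stop("non-finite score", call. = FALSE)
  (score - label)^2
}

#' Cross-entropy loss for the softmax head
#'
#' `-log(probs[label + 1])`, with the picked probability floored at 1e-12
#' so the loss stays finite.
#'
#' @param probs Probability vector of length 3 (sums to 1).
#' @param label Ordinal class in \{0, 1, 2\}.
#' @return Non-negative loss.
#' @export
cross_entropy_loss <- function(probs, label) {
  label <- assert_class_index(label)
  stopifnot(length(probs) == 3, abs(sum(probs) - 1) < 1e-6)
  -log(max(probs[label + 1L], 1e-12))
}

loss_requires_head <- function(loss) {
  if (loss == "cross_entropy") "softmax3" else "ordinal_scalar"
}

#' Per-instance loss vector of a bag
#'
#' Scores every instance with the network and evaluates the chosen loss
#' against the bag label, preserving instance order. The loss choice must
#' match the network head (`cross_entropy` needs `softmax3`; the ordinal
#' losses need the scalar head).
#'
#' @param net An `oomil_network`.
#' @param bag An `oomil_bag`.
#' @param loss One of `"min_uncertainty_ordinal"`,
#'   `"squared_error_ordinal"`, `"cross_entropy"`.
#' @param cuts An [ordinal_cutpoints()] (ordinal losses only).
#' @return Numeric vector of non-negative losses, one per instance.
#' @export
bag_loss_vector <- function(net, bag, loss = "min_uncertainty_ordinal",
                            cuts = ordinal_cutpoints()) {
  loss <- match.arg(loss, LOSS_CHOICES)
  if (net$spec$head != loss_requires_head(loss)) {
    stop(sprintf("loss '%s' requires the %s head", loss, loss_requires_head(loss)),
         call. = FALSE)
  }
  S <- score_instances(net, bag$instances)
  if (loss == "cross_entropy") {
    vapply(seq_len(nrow(S)), function(i) cross_entropy_loss(S[i, ], bag$label),
           numeric(1))
  } else if (loss == "min_uncertainty_ordinal") {
    ordinal_uncertainty_loss(S[, 1], bag$label, cuts)
  } else {
    squared_error_loss(S[, 1], bag$label)
  }
}
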