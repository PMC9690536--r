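# Shared numeric helpers and small image operations.

#' Numerically stable softplus
#'
#' Computes `log(1 + exp(x))` without overflow for large `x`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @keywords internal
softplus <- function(x) {
  # log(1+exp(x)) = max(x,0) + log1p(exp(-|x|))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Inverse softplus: y such that softplus(y) == x (x > 0)
#' @keywords internal
softplus_inv <- function(x) {
  stopifnot(all(x > 0))
  x + log(-expm1(-x))
}

#' Bilinear resize of a grayscale matrix
#'
#' Resizes `m` (rows = y, cols = x, intensities in \[0,1\]) to
#' `out_h` x `out_w` using bilinear interpolation on pixel centers:
#' output center `i` maps to input coordinate `(i - 0.5) * in/out + 0.5`,
#' so resizing to the same size is an exact identity. Values are clipped
#' to \[0,1\].
#'
#' @param m Numeric matrix.
#' @param out_h,out_w Target dimensions in pixels.
#' @return A numeric `out_h` x `out_w` matrix.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m), out_h >= 1, out_w >= 1)
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  map_axis <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - ifelse(n_in > 1, 1, 0))
    lo <- pmax(lo, 1)
    hi <- pmin(lo + 1, n_in)
    w <- src - lo
    list(lo = lo, hi = hi, w = w)
  }
  ry <- map_axis(out_h, in_h)
  rx <- map_axis(out_w, in_w)
  # interpolate rows then columns, all vectorized
  top <- m[ry$lo, , drop = FALSE]
  bot <- m[ry$hi, , drop = FALSE]
  rows <- top * (1 - ry$w) + bot * ry$w
  left  <- rows[, rx$lo, drop = FALSE]
  right <- rows[, rx$hi, drop = FALSE]
  out <- sweep(left, 2, 1 - rx$w, `*`) + sweep(right, 2, rx$w, `*`)
  pmin(pmax(out, 0), 1)
}

# Dihedral patch transforms. Orientation conventions are internal but fixed:
# hflip mirrors left-right, vflip top-bottom, rot90 is clockwise.
flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
rot_90 <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

#' Apply a named augmentation transform to a patch
#'
#' Supported tags: `none`, `hflip`, `vflip`, `rot90`, `rot180`, `rot270`
#' and compositions written `hflip+rot90` (flip applied first).
#'
#' @param m Numeric matrix (patch pixels).
#' @param tag Transform name.
#' @return Transformed matrix.
#' @export
apply_transform <- function(m, tag) {
  for (part in strsplit(tag, "+", fixed = TRUE)[[1]]) {
    m <- switch(part,
      none   = m,
      hflip  = flip_h(m),
      vflip  = flip_v(m),
      rot90  = rot_90(m),
      rot180 = rot_90(rot_90(m)),
      rot270 = rot_90(rot_90(rot_90(m))),
      stop("unknown transform tag: ", part)
    )
  }
  m
}

# Ordered transform list used when topping a bag up to its target size.
AUG_TRANSFORMS <- c("hflip", "vflip", "rot90", "rot180", "rot270",
                    "hflip+rot90", "hflip+rot180", "hflip+rot270")

#' Derive a per-unit substream seed from a global seed
#'
#' Counter-based derivation keeping results within 32-bit integer range,
#' so each bag/image gets an independent reproducible stream.
#' @keywords internal
substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 7919) %% 2147483647)
}

#' @keywords internal
assert_class_index <- function(label) {
  if (!is.numeric(label) || length(label) != 1 || is.na(label) ||
      !(label %in% 0:2)) {
    stop("class label must be a single integer in {0, 1, 2}", call. = FALSE)
  }
  as.integer(label)
}
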