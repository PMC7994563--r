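#' Fit an equal-width quantizer on a feature table
#'
#' Learns per-feature ranges (observed minimum and maximum over non-missing
#' entries) and fixes the bit depth `m_bits`, so each real feature maps onto
#' one of `2^m_bits` equal-width levels. Ranges are meant to be fitted on the
#' training split and then frozen for registration and test.
#'
#' @param x numeric matrix or data frame, one row per instance, one column
#'   per feature; `NA` marks a missing value.
#' @param m_bits non-negative integer bit depth; the bus carries levels
#'   `0 .. 2^m_bits - 1`.
#' @return An object of class `quantizer_model` with fields `n_features`,
#'   `m_bits`, `n_levels`, `lo`, `hi`.
#' @examples
#' q <- fit_quantizer(rbind(c(0, 2), c(1, 4)), m_bits = 5)
#' quantize(c(0.5, 3), q)
#' @export
fit_quantizer <- function(x, m_bits) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty feature table")
  storage.mode(x) <- "double"
  m_bits <- as.integer(m_bits)
  stopifnot(length(m_bits) == 1L, m_bits >= 0L)
  observed <- colSums(!is.na(x))
  if (any(observed == 0L)) {
    stop(sprintf("feature %d has no observed value", which(observed == 0L)[1L]))
  }
  structure(list(
    n_features = ncol(x),
    m_bits = m_bits,
    n_levels = 2L^m_bits,
    lo = apply(x, 2L, min, na.rm = TRUE),
    hi = apply(x, 2L, max, na.rm = TRUE)
  ), class = "quantizer_model")
}

#' @export
print.quantizer_model <- function(x, ...) {
  cat(sprintf("<quantizer_model> %d features, m = %d (%d levels)\n",
              x$n_features, x$m_bits, x$n_levels))
  invisible(x)
}

#' Quantize a real feature vector onto the bus
#'
#' Maps each non-missing feature to `floor((v - lo) / (hi - lo) * 2^m)`,
#' clipped into `[0, 2^m - 1]`; a degenerate range (`hi == lo`) maps to level
#' 0. Out-of-range values are clipped rather than rejected so that corrupted
#' or occluded cues still quantize. Missing features stay unassigned.
#'
#' @param v numeric feature vector (`NA` = missing).
#' @param q a [fit_quantizer()] model.
#' @return A [discrete_fn()] over `2^m` levels.
#' @export
quantize <- function(v, q) {
  stopifnot(inherits(q, "quantizer_model"))
  if (length(v) != q$n_features) {
    stop_mismatch(sprintf("vector length %d, quantizer expects %d",
                          length(v), q$n_features))
  }
  discrete_fn(quantize_levels(matrix(as.numeric(v), nrow = 1L), q)[1L, ],
              q$n_levels)
}

# Vectorized core: instances x features real matrix -> integer level matrix.
quantize_levels <- function(x, q) {
  width <- q$hi - q$lo
  scaled <- sweep(x, 2L, q$lo, "-")
  scaled <- sweep(scaled, 2L, ifelse(width > 0, width, 1), "/")
  lv <- floor(scaled * q$n_levels)
  lv[, width == 0] <- 0
  lv <- pmin(pmax(lv, 0), q$n_levels - 1L)
  lv[is.na(x)] <- NA
  storage.mode(lv) <- "integer"
  lv
}

#' Convert bus levels back to real feature values
#'
#' Digital-to-real conversion: an assigned level maps to the midpoint of its
#' quantization bin, `lo + (level + 0.5) * (hi - lo) / 2^m`; unassigned
#' arguments come back missing (`NA`).
#'
#' @param f a [discrete_fn()] with the quantizer's geometry.
#' @param q a [fit_quantizer()] model.
#' @return Numeric vector of length `n_features`.
#' @export
dequantize <- function(f, q) {
  stopifnot(inherits(f, "discrete_fn"), inherits(q, "quantizer_model"))
  if (n_args(f) != q$n_features || n_levels(f) != q$n_levels) {
    stop_mismatch("function and quantizer differ")
  }
  lv <- unclass(f)
  attributes(lv) <- NULL
  q$lo + (lv + 0.5) * (q$hi - q$lo) / q$n_levels
}
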