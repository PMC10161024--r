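#' Binarize a fluorescence channel
#'
#' Thresholds an intensity image into a positive-pixel mask. The default is
#' Otsu's method on a 256-bin histogram; a fixed intensity threshold and a
#' quantile threshold are also available. The threshold actually applied is
#' recorded in the `"threshold"` attribute for reproducibility, since
#' colocalized-pixel fractions depend on it.
#'
#' @param channel 2-d non-negative intensity matrix.
#' @param method `"otsu"`, `"fixed"` or `"quantile"`.
#' @param threshold fixed intensity cutoff (required for `method = "fixed"`).
#' @param quantile probability in (0, 1) for `method = "quantile"`.
#' @return A logical matrix (`TRUE` = positive) with attribute `"threshold"`.
#' @examples
#' img <- matrix(c(10, 10, 200, 200), 2)
#' binarize(img)
#' @export
binarize <- function(channel, method = c("otsu", "fixed", "quantile"),
                     threshold = NULL, quantile = 0.75) {
  method <- match.arg(method)
  if (!is.matrix(channel) || !is.numeric(channel))
    stop("'channel' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(channel)) || any(channel < 0))
    stop("'channel' must be finite and non-negative", call. = FALSE)
  thr <- switch(method,
    otsu = otsu_threshold(channel),
    fixed = {
      if (is.null(threshold)) stop("'threshold' required for method = 'fixed'",
                                   call. = FALSE)
      threshold
    },
    quantile = {
      if (quantile <= 0 || quantile >= 1)
        stop("'quantile' must lie in (0, 1)", call. = FALSE)
      stats::quantile(channel, quantile, names = FALSE)
    })
  structure(channel > thr, threshold = thr, method = method)
}

#' Colocalized-pixel fraction of two binary masks
#'
#' The fraction of channel-A-positive pixels that are also channel-B
#' positive: `|A intersect B| / |A|`. The denominator is always the first
#' argument — A is the protein of interest (e.g. F-actin, or YAP for nuclear
#' localization) and B the reference compartment (e.g. VE-cadherin, DAPI).
#'
#' @param mask_a,mask_b logical matrices of identical dimensions.
#' @return An object of class `coloc_result`: `fraction` in \[0, 1\],
#'   pixel counts `n_a` and `n_overlap`, and the thresholds recorded on the
#'   masks (if any).
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
#' coloc_fraction(a, b)$fraction   # 0.5
#' @export
coloc_fraction <- function(mask_a, mask_b) {
  if (!is.logical(mask_a) || !is.logical(mask_b))
    stop("masks must be logical matrices", call. = FALSE)
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("masks must have identical dimensions", call. = FALSE)
  n_a <- sum(mask_a)
  if (n_a == 0)
    stop("undefined fraction: mask A is empty", call. = FALSE)
  n_overlap <- sum(mask_a & mask_b)
  structure(list(fraction = n_overlap / n_a, n_a = n_a, n_overlap = n_overlap,
                 threshold_a = attr(mask_a, "threshold"),
                 threshold_b = attr(mask_b, "threshold")),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalized-pixel fraction: %.4f (%d of %d A-positive px)\n",
              x$fraction, x$n_overlap, x$n_a))
  invisible(x)
}

#' Nuclear localization fraction of a signal channel
#'
#' Binarizes a signal channel (e.g. YAP) and a nuclear counterstain (e.g.
#' DAPI) and reports the fraction of signal-positive pixels inside nuclei —
#' the composition `binarize` then [coloc_fraction()] with the signal as A.
#'
#' @param signal,nucleus intensity matrices of identical dimensions.
#' @param method,threshold,quantile thresholding controls passed to
#'   [binarize()] (applied to both channels).
#' @return A `coloc_result`.
#' @export
nuclear_fraction <- function(signal, nucleus, method = "otsu",
                             threshold = NULL, quantile = 0.75) {
  coloc_fraction(binarize(signal, method, threshold, quantile),
                 binarize(nucleus, method, threshold, quantile))
}
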