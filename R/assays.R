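#' Transwell permeation percentage
#'
#' Fraction of tracer crossing a cell monolayer on a transwell insert,
#' expressed relative to cell-free controls:
#' `100 * (FI_sample - background) / mean(FI_controls - background)`.
#' Cell-free wells define 100% permeation; the background is a well without
#' tracer. The result is invariant to any common positive gain applied to
#' all readings.
#'
#' @param samples fluorescence intensities of the sample wells (a.u.).
#' @param controls fluorescence intensities of cell-free control wells.
#' @param background reading without tracer (default 0).
#' @return Percent permeation, one value per sample.
#' @examples
#' transwell_percent(25, c(45, 35), background = 5)  # 57.14286
#' @export
transwell_percent <- function(samples, controls, background = 0) {
  percent_of_controls(samples, controls, background, "fluorescence")
}

#' Cell-viability percentage from a WST-1 absorbance assay
#'
#' `100 * (A_sample - background) / mean(A_controls - background)`, where the
#' background is a well without the WST-1 reagent and controls are untreated
#' cells defining 100% viability.
#'
#' @param samples absorbance readings of treated wells (a.u.).
#' @param controls absorbance readings of untreated control wells.
#' @param background absorbance without the reagent (default 0).
#' @return Percent viability, one value per sample.
#' @examples
#' viability_percent(0.6, c(0.5, 0.7))   # 100
#' @export
viability_percent <- function(samples, controls, background = 0) {
  percent_of_controls(samples, controls, background, "absorbance")
}

percent_of_controls <- function(samples, controls, background, what) {
  if (length(controls) == 0) stop("'controls' must be non-empty", call. = FALSE)
  if (!all(is.finite(samples)) || !all(is.finite(controls)) ||
      !is.finite(background))
    stop("readings must be finite", call. = FALSE)
  if (background > min(c(samples, controls)))
    warning("background exceeds the smallest ", what,
            " reading; check plate layout")
  ctrl <- mean(controls - background)
  if (ctrl <= 0)
    stop("non-positive control mean after background subtraction", call. = FALSE)
  100 * (samples - background) / ctrl
}

#' Row-wise z-scores of an expression matrix
#'
#' Standardizes every gene (row) to mean 0 and sample standard deviation 1
#' (`n - 1` denominator): `z = (value - rowMean) / rowSD`. Used to put genes
#' on a common scale for heatmap visualization. Idempotent: z-scoring a
#' z-scored matrix returns it unchanged (to numerical precision).
#'
#' @param mat numeric matrix, genes in rows, conditions in columns; no
#'   missing values, and every row needs at least two distinct values.
#' @return A matrix of the same shape and dimnames.
#' @examples
#' zscore_rows(rbind(g1 = c(1, 2, 3)))   # -1 0 1
#' @export
zscore_rows <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("'mat' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(mat))) stop("'mat' contains missing or non-finite values",
                                 call. = FALSE)
  if (ncol(mat) < 2) stop("need at least two columns to z-score", call. = FALSE)
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    nm <- if (!is.null(rownames(mat))) rownames(mat)[bad] else bad
    stop("constant row cannot be z-scored: ", nm, call. = FALSE)
  }
  out <- (mat - rowMeans(mat)) / sds
  dimnames(out) <- dimnames(mat)
  out
}

#' Western-blot band fold change relative to a reference lane
#'
#' Band signals are first normalized to their loading control, then expressed
#' as a fold change relative to the (iso-osmotic) reference lane:
#' `(target / loading) / (ref_target / ref_loading)`.
#'
#' @param target,loading band and loading-control signals of the sample lane.
#' @param ref_target,ref_loading the same for the reference lane.
#' @return Fold change (1 means no change).
#' @examples
#' band_fold_change(6, 2, 3, 2)   # 2
#' @export
band_fold_change <- function(target, loading, ref_target, ref_loading) {
  vals <- c(target, loading, ref_target, ref_loading)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all band signals must be positive", call. = FALSE)
  (target / loading) / (ref_target / ref_loading)
}
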