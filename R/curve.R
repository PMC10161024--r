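#' Integrated extraluminal leakage curve
#'
#' Integrates the extraluminal fluorescence at every frame and converts it to
#' the calibrated ordinate whose slope against time is the permeability
#' coefficient. Because the lumen is an infinite source its projected signal
#' is constant in time, so the whole-frame intensity sum minus its t = 0
#' baseline isolates exactly the barrier-crossed tracer — including the part
#' that projects over the lumen footprint (tracer above and below the
#' cylinder), which at early times holds most of the leaked mass and which an
#' outside-region-only sum would miss. The baseline subtraction also removes
#' autofluorescence, static offsets and static PSF bleed, so
#' `F_out(t_0) = 0`.
#'
#' Under the projection imaging model the calibration is exact:
#' `y_k = s^2 F_out(t_k) / (4 L I_lumen0)`, where `s` is the pixel pitch, `L`
#' the imaged axial length and `I_lumen0` the mean t = 0 intensity over the
#' lumen disk, equal to `gain * c0 * (pi/2) * r0` (the mean chord of a disk
#' is `(pi/2) r0`). All optical gains cancel and `slope(y ~ t) = P` in m/s.
#' `I_lumen0` is reconstructed from the transverse profile as
#' `(pi/4) * peak`, the disk mean implied by the projection model, rather
#' than averaged over the thresholded mask (which under-covers the dim lumen
#' edge and would bias the mean high).
#'
#' @param stack an [image_stack()].
#' @param geom a [segment_lumen()] geometry derived from this stack's first
#'   frame.
#' @param saturation_level intensity treated as detector full scale when
#'   flagging saturation.
#' @return An object of class `leakage_curve`: data.frame `data` with columns
#'   `t` (s), `F_out` (counts) and `y` (m); scalars `I_lumen0`, `pixel_pitch`,
#'   `L_hat`; and `flags` (currently `saturation_suspected`).
#' @export
leakage_curve <- function(stack, geom, saturation_level = 65535) {
  stopifnot(inherits(stack, "image_stack"), inherits(geom, "lumen_geometry"))
  if (!all(dim(stack$frames)[1:2] == dim(geom$lumen_mask)))
    stop("geometry does not match the stack dimensions", call. = FALSE)
  n_t <- dim(stack$frames)[3]
  tot_sum <- vapply(seq_len(n_t), function(k) sum(stack$frames[, , k]),
                    numeric(1))
  F_out <- tot_sum - tot_sum[1]

  I_lumen0 <- (pi / 4) * geom$peak_intensity
  if (!is.finite(I_lumen0) || I_lumen0 <= 0)
    stop("non-positive lumen reference intensity", call. = FALSE)

  sat <- vapply(seq_len(n_t),
                function(k) mean(stack$frames[, , k] >= saturation_level),
                numeric(1))
  y <- stack$pixel_pitch^2 * F_out / (4 * geom$L_hat * I_lumen0)
  structure(list(
    data = data.frame(t = stack$frame_times, F_out = F_out, y = y),
    I_lumen0 = I_lumen0, pixel_pitch = stack$pixel_pitch, L_hat = geom$L_hat,
    flags = list(saturation_suspected = any(sat > 0.05))),
    class = "leakage_curve")
}

#' Build a leakage curve from precomputed calibrated ordinates
#'
#' For fitting externally derived (or analytically constructed) curves with
#' [fit_permeability()] without going through image processing.
#'
#' @param t frame times (s).
#' @param y calibrated ordinates (m); `slope(y ~ t)` has units m/s.
#' @param flags optional named list of quality flags.
#' @return A `leakage_curve` object.
#' @examples
#' fit_permeability(as_leakage_curve(seq(0, 300, 30), 5e-8 * seq(0, 300, 30)))
#' @export
as_leakage_curve <- function(t, y, flags = list(saturation_suspected = FALSE)) {
  stopifnot(length(t) == length(y), length(t) >= 2, all(diff(t) > 0))
  structure(list(data = data.frame(t = t, F_out = NA_real_, y = y),
                 I_lumen0 = NA_real_, pixel_pitch = NA_real_, L_hat = NA_real_,
                 flags = flags),
            class = "leakage_curve")
}

#' @export
print.leakage_curve <- function(x, ...) {
  cat(sprintf("Leakage curve: %d frames, t = %g..%g s\n", nrow(x$data),
              min(x$data$t), max(x$data$t)))
  if (is.finite(x$I_lumen0))
    cat(sprintf("  I_lumen0 = %.0f counts, L = %.0f um\n", x$I_lumen0,
                x$L_hat * 1e6))
  if (isTRUE(x$flags$saturation_suspected)) cat("  flag: saturation suspected\n")
  invisible(x)
}
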