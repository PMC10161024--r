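#' Imaging (optics and detector) parameters for the projection renderer
#'
#' Describes how a widefield projection image of the vessel is formed: pixel
#' pitch, field of view, intensity gain, point-spread blur, background offset,
#' shot/read noise and quantization. The vessel axis runs along image rows
#' (the first array dimension); columns are the transverse direction.
#'
#' @param pixel_pitch pixel size in the sample plane (m).
#' @param n_rows,n_cols frame dimensions; the imaged axial length is
#'   `n_rows * pixel_pitch`. The default transverse field of view (1.6 mm at
#'   2.5 um/px) holds the vessel plus three diffusion lengths of leaked
#'   tracer on either side over a 5 min record at the default diffusivity,
#'   so the integrated signal does not leak off-frame.
#' @param gain intensity counts per unit (concentration x path length).
#' @param psf_sigma Gaussian point-spread-function sigma (m); `0` disables blur.
#' @param background constant intensity offset (counts): autofluorescence
#'   plus the detector bias offset. Kept above 3x the read-noise sd so the
#'   zero clamp of the detector does not censor the noise distribution
#'   (censoring would systematically under-record small intensity
#'   increments).
#' @param poisson_noise apply Poisson shot noise to the expected counts?
#' @param gaussian_sd Gaussian read-noise standard deviation (counts). The
#'   default is about 1% of the lumen-center intensity under the default gain.
#' @param bit_depth detector bit depth; values are clamped to
#'   `[0, 2^bit_depth - 1]`.
#' @param frame_interval time between frames (s).
#' @param n_frames number of frames (the default covers 5 min at 30 s steps).
#' @param seed integer RNG seed making the rendered stack reproducible.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(pixel_pitch = 2.5e-6, n_rows = 128L, n_cols = 640L,
                          gain = 1.28e8, psf_sigma = 1e-6, background = 1000,
                          poisson_noise = TRUE, gaussian_sd = 300,
                          bit_depth = 16L, frame_interval = 30,
                          n_frames = 11L, seed = 1L) {
  stop_if_not_scalar_pos(pixel_pitch, "pixel_pitch")
  stop_if_not_scalar_pos(gain, "gain")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  stop_if_not_scalar_pos(psf_sigma, "psf_sigma", allow_zero = TRUE)
  stop_if_not_scalar_pos(background, "background", allow_zero = TRUE)
  stop_if_not_scalar_pos(gaussian_sd, "gaussian_sd", allow_zero = TRUE)
  if (n_rows < 4 || n_cols < 16) stop("frame dimensions too small", call. = FALSE)
  structure(list(pixel_pitch = pixel_pitch, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), gain = gain,
                 psf_sigma = psf_sigma, background = background,
                 poisson_noise = isTRUE(poisson_noise),
                 gaussian_sd = gaussian_sd, bit_depth = as.integer(bit_depth),
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "optics_params")
}

#' Time-lapse image stack
#'
#' Container for a single-channel time-lapse recording: an `n_rows x n_cols x
#' n_frames` intensity array with its pixel pitch and frame times.
#'
#' @param frames numeric array `H x W x T`, non-negative intensities.
#' @param pixel_pitch pixel size (m).
#' @param frame_times strictly increasing frame times (s), length `T`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_pitch, frame_times) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3-d array (rows x cols x time)", call. = FALSE)
  if (dim(frames)[3] < 2L) stop("need at least 2 frames", call. = FALSE)
  if (length(frame_times) != dim(frames)[3])
    stop("'frame_times' length must match the number of frames", call. = FALSE)
  if (any(diff(frame_times) <= 0))
    stop("'frame_times' must be strictly increasing", call. = FALSE)
  if (any(frames < 0)) stop("intensities must be non-negative", call. = FALSE)
  stop_if_not_scalar_pos(pixel_pitch, "pixel_pitch")
  structure(list(frames = frames, pixel_pitch = pixel_pitch,
                 frame_times = as.numeric(frame_times)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d frames of %d x %d px (%.2f um/px), t = %g..%g s\n",
              d[3], d[1], d[2], x$pixel_pitch * 1e6,
              x$frame_times[1], x$frame_times[d[3]]))
  invisible(x)
}

# Quadrature weights mapping radial concentration nodes to the per-column
# z-projected extraluminal line integral. Returns a sparse n_cols x
# (n_r + 2) matrix; node order is (surface r0, cell centers, R_max).
projection_weights <- function(field, optics) {
  p <- field$params
  s <- optics$pixel_pitch
  x <- (seq_len(optics$n_cols) - (optics$n_cols + 1) / 2) * s
  r_nodes <- c(p$r0, field$radii, p$R_max)
  dr <- field$radii[2] - field$radii[1]
  dz <- min(s, dr) / 2
  z_edges <- seq(0, p$R_max + dz, by = dz)
  zc <- z_edges[-1] - dz / 2
  nz <- length(zc)

  xm <- matrix(x, length(x), nz)
  zm <- matrix(zc, length(x), nz, byrow = TRUE)
  z_lo <- ifelse(abs(x) < p$r0, sqrt(pmax(p$r0^2 - x^2, 0)), 0)
  z_hi <- sqrt(pmax(p$R_max^2 - x^2, 0))
  lo <- pmax(matrix(z_lo, length(x), nz), zm - dz / 2)
  hi <- pmin(matrix(z_hi, length(x), nz), zm + dz / 2)
  w <- pmax(hi - lo, 0) * 2                     # both z half-spaces
  zeff <- (lo + hi) / 2
  sel <- which(w > 0)
  r <- sqrt(xm[sel]^2 + zeff[sel]^2)
  r <- pmin(pmax(r, r_nodes[1]), r_nodes[length(r_nodes)])

  iv <- findInterval(r, r_nodes, rightmost.closed = TRUE)
  frac <- (r - r_nodes[iv]) / (r_nodes[iv + 1] - r_nodes[iv])
  cols <- row(xm)[sel]
  Matrix::sparseMatrix(
    i = c(cols, cols), j = c(iv, iv + 1L),
    x = c(w[sel] * (1 - frac), w[sel] * frac),
    dims = c(length(x), length(r_nodes)))
}

# Noiseless expected-intensity transverse profile at one stored field time.
noiseless_profile <- function(field, optics, time_index, weights = NULL) {
  p <- field$params
  s <- optics$pixel_pitch
  x <- (seq_len(optics$n_cols) - (optics$n_cols + 1) / 2) * s
  chord <- ifelse(abs(x) < p$r0, 2 * sqrt(pmax(p$r0^2 - x^2, 0)), 0)
  if (is.null(weights)) weights <- projection_weights(field, optics)
  v <- c(field$c_surface[time_index], field$conc[time_index, ], 0)
  prof <- optics$gain * (chord * p$c0 + as.numeric(weights %*% v)) +
    optics$background
  if (optics$psf_sigma / s > 0.01) {
    sig <- optics$psf_sigma / s
    half <- max(1L, ceiling(4 * sig))
    k <- dnorm(seq(-half, half), sd = sig)
    k <- k / sum(k)
    padded <- c(rep(prof[1], half), prof, rep(prof[length(prof)], half))
    prof <- as.numeric(stats::filter(padded, k, sides = 2))[half + seq_along(x)]
  }
  prof
}

#' Render a time-lapse projection stack from a solved radial field
#'
#' Forms widefield (z-projection) frames of the leaking vessel. A pixel at
#' transverse offset `x` receives `gain * (chord(x) * c0 + integral of
#' c(sqrt(x^2 + z^2)) dz) + background`, where `chord(x) = 2 sqrt(r0^2 - x^2)`
#' is the intraluminal path length; the profile is blurred by a Gaussian PSF,
#' then Poisson shot noise, Gaussian read noise and quantization to
#' `bit_depth` are applied. Deterministic for a fixed `optics$seed`.
#'
#' @param field a [solve_radial_diffusion()] result whose stored times include
#'   all requested frame times.
#' @param optics an [optics_params()] object.
#' @param weights optional precomputed [projection_weights()] matrix (an
#'   optimization when rendering many stacks from the same geometry).
#' @return A list with components `stack` (an [image_stack()]) and `manifest`
#'   (a ground-truth record: all parameters, the seed and quality flags;
#'   serializable with [write_manifest()] and sufficient to regenerate the
#'   stack bit-identically).
#' @export
render_projection_stack <- function(field, optics, weights = NULL) {
  stopifnot(inherits(field, "radial_field"), inherits(optics, "optics_params"))
  ft <- (seq_len(optics$n_frames) - 1L) * optics$frame_interval
  if (max(ft) > field$params$duration + 1e-9)
    stop("field duration is shorter than the requested stack duration",
         call. = FALSE)
  idx <- vapply(ft, function(t) {
    i <- which.min(abs(field$times - t))
    if (abs(field$times[i] - t) > 1e-6)
      stop("frame time ", t, " s not stored in the field solution", call. = FALSE)
    i
  }, integer(1))
  if (is.null(weights)) weights <- projection_weights(field, optics)

  H <- optics$n_rows; W <- optics$n_cols
  vmax <- 2^optics$bit_depth - 1
  frames <- array(0, dim = c(H, W, optics$n_frames))
  with_local_seed(optics$seed, {
    for (k in seq_along(idx)) {
      prof <- noiseless_profile(field, optics, idx[k], weights)
      lam <- matrix(prof, H, W, byrow = TRUE)
      v <- if (optics$poisson_noise) {
        matrix(rpois(H * W, pmax(lam, 0)), H, W)
      } else lam
      if (optics$gaussian_sd > 0) v <- v + matrix(rnorm(H * W, 0, optics$gaussian_sd), H, W)
      frames[, , k] <- pmin(pmax(round(v), 0), vmax)
    }
  })

  # saturation: fraction of intraluminal pixels pinned at full scale
  x <- (seq_len(W) - (W + 1) / 2) * optics$pixel_pitch
  lum_cols <- abs(x) < field$params$r0
  sat_frac <- if (any(lum_cols)) {
    max(apply(frames[, lum_cols, , drop = FALSE] >= vmax, 3, mean))
  } else 0
  manifest <- list(
    generator = "vesselperm", version = as.character(utils::packageVersion("vesselperm")),
    P_true = field$params$P,
    transport = unclass(field$params),
    optics = unclass(optics),
    frame_times = ft,
    flags = list(saturation_warning = sat_frac > 0.01, saturated_fraction = sat_frac),
    seed = optics$seed)
  if (sat_frac > 0.01)
    warning(sprintf("%.1f%% of lumen pixels saturated", 100 * sat_frac))
  list(stack = image_stack(frames, optics$pixel_pitch, ft), manifest = manifest)
}

#' Simulate a leakage image stack with known ground truth
#'
#' Convenience wrapper: solves the forward transport model for `P_true` and
#' renders a noisy projection stack, returning the stack and its ground-truth
#' manifest.
#'
#' @param P_true true membrane permeability (m/s).
#' @param seed RNG seed for the imaging noise (overrides `optics$seed`).
#' @param transport optional [transport_params()]; default uses `P = P_true`.
#' @param optics optional [optics_params()].
#' @param field optional precomputed [solve_radial_diffusion()] result for
#'   these transport parameters (an optimization when simulating many noise
#'   realizations of the same vessel).
#' @param weights optional precomputed [projection_weights()].
#' @return As [render_projection_stack()].
#' @examples
#' \donttest{
#' sim <- simulate_leakage_stack(1e-7, seed = 1)
#' sim$stack
#' }
#' @export
simulate_leakage_stack <- function(P_true, seed = 1L, transport = NULL,
                                   optics = NULL, field = NULL, weights = NULL) {
  if (is.null(transport)) transport <- transport_params(P = P_true)
  if (transport$P != P_true) stop("'transport$P' disagrees with 'P_true'", call. = FALSE)
  if (is.null(optics)) optics <- optics_params()
  optics$seed <- as.integer(seed)
  if (is.null(field)) {
    ft <- (seq_len(optics$n_frames) - 1L) * optics$frame_interval
    field <- solve_radial_diffusion(transport, save_times = ft)
  }
  render_projection_stack(field, optics, weights = weights)
}
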