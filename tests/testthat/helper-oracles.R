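# Independent explicit-Euler (FTCS) solver for the radial membrane-diffusion
# problem, written as a brute-force oracle: finite-volume flux form on a
# uniform grid, forward time stepping at a stability-limited step. Kept
# deliberately independent of the package's Crank-Nicolson implementation.
oracle_euler_radial <- function(P, D = 1.5e-10, r0 = 117.5e-6, c0 = 1,
                                R_max = NULL, duration = 60, n_r = 600L) {
  if (is.null(R_max)) R_max <- r0 + 8 * sqrt(D * duration)
  dr <- (R_max - r0) / n_r
  rc <- r0 + (seq_len(n_r) - 0.5) * dr
  rf <- r0 + (0:n_r) * dr
  dt <- 0.8 * dr^2 / (2 * D)
  n_steps <- ceiling(duration / dt)
  dt <- duration / n_steps
  beta <- P * dr / (2 * D)
  p_eff <- P / (1 + beta)
  cvec <- numeric(n_r)
  cum <- 0
  g <- D * rf / dr
  for (k in seq_len(n_steps)) {
    j_in <- p_eff * (c0 - cvec[1])                       # per membrane area
    q <- g[2:n_r] * diff(cvec)        # inflow through each interior face,
                                      # signed toward the inner cell
    inflow_inner <- c(rf[1] * j_in, -q)
    inflow_outer <- c(q, -D * rf[n_r + 1] * cvec[n_r] / (dr / 2))
    cum <- cum + dt * j_in
    cvec <- cvec + dt * (inflow_inner + inflow_outer) / (rc * dr)
  }
  list(radii = rc, conc = cvec, cum_influx = cum,
       mass_per_length = 2 * pi * sum(cvec * rc * dr),
       influx_per_length = 2 * pi * r0 * cum)
}

# Shared simulation cache so expensive transport solves and projection
# weights are reused across test files (imaging seeds still vary per call).
.sim_cache <- new.env(parent = emptyenv())

cached_field <- function(P, frame_times = seq(0, 300, 30)) {
  key <- paste0("field_", P, "_", paste(range(frame_times), collapse = "_"))
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- solve_radial_diffusion(
      transport_params(P = P), save_times = frame_times)
  .sim_cache[[key]]
}

cached_weights <- function(field, optics) {
  key <- paste0("w_", field$params$P, "_", optics$n_cols, "_",
                optics$pixel_pitch)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- vesselperm:::projection_weights(field, optics)
  .sim_cache[[key]]
}

# One simulated leakage stack under the default study conditions.
leakage_sim <- function(P, seed, optics = optics_params()) {
  field <- cached_field(P)
  render_projection_stack(
    field,
    within_optics_seed(optics, seed),
    weights = cached_weights(field, optics))
}

within_optics_seed <- function(optics, seed) {
  optics$seed <- as.integer(seed)
  optics
}

# Noiseless, unblurred optics for deterministic imaging checks.
noiseless_optics <- function(...) {
  optics_params(psf_sigma = 0, background = 0, poisson_noise = FALSE,
                gaussian_sd = 0, ...)
}
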