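test_that("a zero field with zero background and noise renders all-zero frames", {
  fld <- solve_radial_diffusion(transport_params(P = 0, duration = 60,
                                                 n_r = 80L))
  op <- noiseless_optics(n_frames = 3L, n_rows = 8L, n_cols = 64L,
                         gain = 1)  # gain on a zero field is irrelevant
  op$gain <- 1e-30                  # suppress the lumen chord term too
  sim <- render_projection_stack(fld, op)
  expect_true(all(round(sim$stack$frames) == 0))
})

test_that("the noiseless unblurred lumen-center pixel equals gain*c0*2*r0 within 1%", {
  fld <- cached_field(1e-7)
  op <- noiseless_optics(n_cols = 641L)  # odd width: a pixel sits exactly on axis
  sim <- render_projection_stack(fld, op)
  center <- sim$stack$frames[1, 321, 1]
  expect_equal(center, op$gain * 1 * 2 * 117.5e-6, tolerance = 0.01)
})

test_that("rendering is bit-identical for a fixed seed, through TIFF serialization", {
  a <- leakage_sim(1e-7, seed = 42)
  b <- leakage_sim(1e-7, seed = 42)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$manifest[names(a$manifest) != "version"],
                   b$manifest[names(b$manifest) != "version"])
  fa <- tempfile(fileext = ".tif"); fb <- tempfile(fileext = ".tif")
  write_stack_tiff(a$stack, fa); write_stack_tiff(b$stack, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  c <- leakage_sim(1e-7, seed = 43)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("noiseless rendering conserves the leaked mass within 2%", {
  fld <- cached_field(1e-7)
  op <- noiseless_optics()
  sim <- render_projection_stack(fld, op)
  L <- op$n_rows * op$pixel_pitch
  for (k in c(5, 11)) {
    measured <- sum(sim$stack$frames[, , k] - sim$stack$frames[, , 1]) *
      op$pixel_pitch^2 / (op$gain * L)
    truth <- fld$mass_per_length[match(sim$stack$frame_times[k], fld$times)]
    expect_equal(measured, truth, tolerance = 0.02)
  }
})

test_that("lumen saturation raises a warning and is flagged in the manifest", {
  fld <- cached_field(1e-7)
  op <- noiseless_optics(gain = 1e10, n_rows = 8L)
  expect_warning(sim <- render_projection_stack(fld, op), "saturated")
  expect_true(sim$manifest$flags$saturation_warning)
})

test_that("stacks round-trip through multi-page 16-bit TIFF exactly", {
  sim <- leakage_sim(1e-7, seed = 7)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(sim$stack, path)
  back <- read_stack_tiff(path, sim$stack$pixel_pitch,
                          frame_times = sim$stack$frame_times)
  expect_identical(dim(back$frames), dim(sim$stack$frames))
  expect_equal(back$frames, sim$stack$frames)

  mpath <- tempfile(fileext = ".json")
  write_manifest(sim$manifest, mpath)
  m <- read_manifest(mpath)
  expect_equal(m$P_true, sim$manifest$P_true)
  expect_equal(m$seed, sim$manifest$seed)
  expect_equal(m$transport$D, sim$manifest$transport$D)
})

test_that("a stack longer than the solved field is rejected", {
  fld <- solve_radial_diffusion(transport_params(P = 1e-7, duration = 60),
                                save_times = c(0, 30, 60))
  expect_error(render_projection_stack(fld, optics_params(n_frames = 11L)),
               "duration")
})
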