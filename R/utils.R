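#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom graphics abline legend plot points
#' @importFrom grDevices dev.flush dev.hold
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (allow_zero) {
    if (x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  } else if (strict && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Otsu threshold on an arbitrary-range intensity matrix.
otsu_threshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("Otsu thresholding requires a non-constant image", call. = FALSE)
  EBImage::otsu(x, range = rng, levels = 256L)
}
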