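#' Two-channel colocalization fixture with exact ground-truth overlap
#'
#' Builds a pair of single-channel images whose binary positive sets overlap
#' by exactly the requested pixel fraction (relative to channel A) before
#' noise is added, for validating colocalized-pixel-fraction analyses.
#' Channel A is a compact block of `n_a` pixels; the first
#' `round(target_fraction * n_a)` of them (in raster order) are also positive
#' in channel B, which additionally contains a disjoint block away from A.
#'
#' @param target_fraction requested overlap fraction in `[0, 1]`.
#' @param n_a number of channel-A-positive pixels.
#' @param dim image dimensions `c(rows, cols)`.
#' @param fg,bg foreground and background intensities.
#' @param noise_sd Gaussian noise standard deviation added to both channels.
#' @param seed RNG seed.
#' @return A list with intensity images `channel_a`, `channel_b`, the
#'   noise-free masks `mask_a`, `mask_b`, the exact `fraction_true`, and the
#'   overlap pixel count `n_overlap`.
#' @examples
#' fx <- make_coloc_fixture(0.3, n_a = 10000)
#' fx$n_overlap  # exactly 3000
#' @export
make_coloc_fixture <- function(target_fraction, n_a = 10000L,
                               dim = c(160L, 160L), fg = 200, bg = 10,
                               noise_sd = 5, seed = 1L) {
  if (!is.numeric(target_fraction) || target_fraction < 0 || target_fraction > 1)
    stop("'target_fraction' must lie in [0, 1]", call. = FALSE)
  H <- dim[1]; W <- dim[2]
  half <- floor(W / 2) - 2L
  if (n_a > H * half) stop("'n_a' too large for the canvas", call. = FALSE)
  n_overlap <- as.integer(round(target_fraction * n_a))
  if (n_overlap > n_a) stop("overlap cannot exceed the size of A", call. = FALSE)

  mask_a <- matrix(FALSE, H, W)
  # fill A row-wise in the left half of the canvas
  a_idx <- as.matrix(expand.grid(row = seq_len(H), col = seq_len(half)))
  a_idx <- a_idx[order(a_idx[, "row"], a_idx[, "col"]), , drop = FALSE][seq_len(n_a), ]
  mask_a[a_idx] <- TRUE

  mask_b <- matrix(FALSE, H, W)
  if (n_overlap > 0) mask_b[a_idx[seq_len(n_overlap), , drop = FALSE]] <- TRUE
  # disjoint B-only block in the right half
  n_b_extra <- max(as.integer(n_a / 2), 64L)
  b_idx <- as.matrix(expand.grid(row = seq_len(H), col = (half + 3L):W))
  b_idx <- b_idx[order(b_idx[, "row"], b_idx[, "col"]), , drop = FALSE]
  mask_b[b_idx[seq_len(min(n_b_extra, nrow(b_idx))), , drop = FALSE]] <- TRUE

  with_local_seed(seed, {
    channel_a <- bg + (fg - bg) * mask_a + matrix(rnorm(H * W, 0, noise_sd), H, W)
    channel_b <- bg + (fg - bg) * mask_b + matrix(rnorm(H * W, 0, noise_sd), H, W)
  })
  list(channel_a = pmax(channel_a, 0), channel_b = pmax(channel_b, 0),
       mask_a = mask_a, mask_b = mask_b,
       fraction_true = n_overlap / n_a, n_overlap = n_overlap, n_a = n_a)
}

#' Label-mask fixture with analytic shape-metric ground truth
#'
#' Paints non-overlapping axis-aligned shapes (disks, rectangles, ellipses)
#' into an integer label mask and records their closed-form area, perimeter,
#' aspect ratio and circularity (Ramanujan's approximation for the ellipse
#' perimeter), for validating morphometry estimators.
#'
#' @param shapes a data.frame with columns `type` ("disk", "rect" or
#'   "ellipse"), `cx`, `cy` (centers, px), `a`, `b` (px): radius for disks
#'   (`b` ignored), full side lengths along x/y for rectangles, semi-axes
#'   along x/y for ellipses.
#' @param dim canvas dimensions `c(rows, cols)`; by default sized to fit.
#' @param pixel_pitch physical pixel size (m) recorded with the truth table.
#' @return A list with the integer `labels` matrix and a `truth` data.frame
#'   (label, type, area_px, perimeter_px, aspect_ratio, circularity).
#' @examples
#' fx <- make_label_fixture(data.frame(type = "disk", cx = 60, cy = 60,
#'                                     a = 50, b = NA))
#' fx$truth
#' @export
make_label_fixture <- function(shapes, dim = NULL, pixel_pitch = 1e-6) {
  stopifnot(is.data.frame(shapes), nrow(shapes) >= 1)
  ext <- function(s) switch(s$type, disk = c(s$a, s$a),
                            rect = c(s$a / 2, s$b / 2),
                            ellipse = c(s$a, s$b),
                            stop("unknown shape type: ", s$type, call. = FALSE))
  if (is.null(dim)) {
    xs <- ys <- 0
    for (i in seq_len(nrow(shapes))) {
      e <- ext(shapes[i, ])
      xs <- max(xs, shapes$cx[i] + e[1]); ys <- max(ys, shapes$cy[i] + e[2])
    }
    dim <- c(ceiling(ys) + 3L, ceiling(xs) + 3L)
  }
  H <- dim[1]; W <- dim[2]
  xc <- matrix(seq_len(W), H, W, byrow = TRUE)
  yc <- matrix(seq_len(H), H, W)
  labels <- matrix(0L, H, W)
  truth <- vector("list", nrow(shapes))
  for (i in seq_len(nrow(shapes))) {
    s <- shapes[i, ]
    inside <- switch(s$type,
      disk    = (xc - s$cx)^2 + (yc - s$cy)^2 <= s$a^2,
      # half-open interval so an a x b rectangle covers exactly a*b pixels
      rect    = xc > s$cx - s$a / 2 & xc <= s$cx + s$a / 2 &
                yc > s$cy - s$b / 2 & yc <= s$cy + s$b / 2,
      ellipse = ((xc - s$cx) / s$a)^2 + ((yc - s$cy) / s$b)^2 <= 1)
    if (any(labels[inside] != 0L))
      stop("overlapping shapes in the fixture specification", call. = FALSE)
    labels[inside] <- i
    tm <- switch(s$type,
      disk = {
        p <- 2 * pi * s$a
        data.frame(area_px = pi * s$a^2, perimeter_px = p, aspect_ratio = 1,
                   circularity = 1)
      },
      rect = {
        area <- s$a * s$b; p <- 2 * (s$a + s$b)
        data.frame(area_px = area, perimeter_px = p,
                   aspect_ratio = max(s$a, s$b) / min(s$a, s$b),
                   circularity = 4 * pi * area / p^2)
      },
      ellipse = {
        area <- pi * s$a * s$b
        p <- pi * (3 * (s$a + s$b) - sqrt((3 * s$a + s$b) * (s$a + 3 * s$b)))
        data.frame(area_px = area, perimeter_px = p,
                   aspect_ratio = max(s$a, s$b) / min(s$a, s$b),
                   circularity = 4 * pi * area / p^2)
      })
    truth[[i]] <- cbind(data.frame(label = i, type = s$type), tm)
  }
  list(labels = labels, truth = do.call(rbind, truth), pixel_pitch = pixel_pitch)
}
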