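#' Generate a synthetic axial slice with a dark curvilinear sulcus
#'
#' Produces a bright 2-D grayscale image (matrix, values in `[0, 1]`) crossed
#' by a dark curvilinear path emulating the central sulcus on an axial slice:
#' the path starts at its fundus near the interhemispheric midline and runs
#' laterally with a sinusoidal wiggle. Pixels on the path are darker than the
#' background by `depth_contrast` before noise. Labelled probe points (one
#' on-path, one within a pixel of the seed, one offset to each side) are
#' returned for testing peak categorisation.
#'
#' Coordinates are `(row, col)` 1-based matrix indices; the anterior axis is
#' by convention the +row direction.
#'
#' @param size Image side in pixels.
#' @param path_spec List: `start` `(row, col)` of the fundus (default centre
#'   row, 10 px lateral of the midline), `length` lateral extent in px,
#'   `amplitude` sinusoid amplitude in px, `cycles` number of sinusoid
#'   cycles, `hemisphere` `"left"` (path runs toward column 1) or `"right"`.
#' @param depth_contrast Intensity drop of path pixels (default 0.5).
#' @param noise_sd Additive Gaussian noise (warning if `>= depth_contrast`).
#' @param background Background intensity (default 0.85).
#' @param seed Integer seed.
#' @return List with `image` (matrix), `true_path` (m x 2 matrix of
#'   `(row, col)`, first row = seed/fundus), `seed_px` `(row, col)`,
#'   `midline_col`, and `probe_points` (data frame `row`, `col`, `label`
#'   with labels `ON_LINE`, `FUNDUS`, `ANTERIOR`, `POSTERIOR`).
#' @export
generate_sulcus_image <- function(size = 96, path_spec = list(),
                                  depth_contrast = 0.5, noise_sd = 0.05,
                                  background = 0.85, seed = 1L) {
  stopifnot(size >= 16, depth_contrast > 0, noise_sd >= 0)
  if (noise_sd >= depth_contrast) {
    warn_msg("noise_sd (%g) >= depth_contrast (%g): tracing not guaranteed",
             noise_sd, depth_contrast)
  }
  midline <- round(size / 2)
  ps <- utils::modifyList(
    list(start = c(round(size / 2), midline - 10),
         length = NULL, amplitude = NULL, cycles = 1.2,
         hemisphere = "left"),
    path_spec)
  lat_dir <- if (identical(ps$hemisphere, "left")) -1 else 1
  if (is.null(ps$length)) {
    room <- if (lat_dir < 0) ps$start[2] - 2 else size - 1 - ps$start[2]
    ps$length <- min(round(size * 0.35), room)
  }
  if (is.null(ps$amplitude)) ps$amplitude <- ps$length / 10
  r0 <- ps$start[1]; c0 <- ps$start[2]
  end_col <- c0 + lat_dir * ps$length
  if (r0 < 1 || r0 > size || c0 < 1 || c0 > size ||
      end_col < 1 || end_col > size) {
    stop_bad("path endpoints outside the image")
  }
  # max |d row / d col| must stay <= 1 so the rasterised chain is 8-connected
  max_slope <- ps$amplitude * 2 * pi * ps$cycles / ps$length
  if (max_slope > 1) {
    stop_bad("path too steep (amplitude * cycles too large for its length)")
  }

  tfine <- seq(0, 1, length.out = ps$length * 8L)
  cols <- c0 + lat_dir * tfine * ps$length
  rows <- r0 + ps$amplitude * sin(2 * pi * ps$cycles * tfine)
  px <- cbind(row = round(rows), col = round(cols))
  px <- px[!duplicated(px), , drop = FALSE]
  px <- px[px[, 1] >= 1 & px[, 1] <= size & px[, 2] >= 1 & px[, 2] <= size, ,
           drop = FALSE]

  set.seed(child_seed(seed, 29L))
  img <- matrix(background, size, size)
  img[px] <- background - depth_contrast
  img <- img + matrix(rnorm(size * size, 0, noise_sd), size, size)
  img <- pmin(pmax(img, 0), 1)

  seed_px <- px[1L, ]
  mid_i <- max(2L, round(nrow(px) / 2))
  mid_px <- px[mid_i, ]
  probes <- data.frame(
    row = c(mid_px[1], seed_px[1] + 0.4, mid_px[1] + 5 + ps$amplitude,
            mid_px[1] - 5 - ps$amplitude),
    col = c(mid_px[2], seed_px[2] + 0.4, mid_px[2], mid_px[2]),
    label = c("ON_LINE", "FUNDUS", "ANTERIOR", "POSTERIOR"),
    stringsAsFactors = FALSE)

  list(image = img, true_path = px, seed_px = unname(seed_px),
       midline_col = midline, probe_points = probes)
}

#' Write / read a grayscale image as 16-bit PNG
#'
#' @param image Matrix with values in `[0, 1]`.
#' @param path File path.
#' @return `read_slice_png` returns the image matrix.
#' @export
write_slice_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path, dpi = NULL)
  invisible(path)
}

#' @rdname write_slice_png
#' @export
read_slice_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
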