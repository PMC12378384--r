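straight_image <- function(size = 64, row = 20, cols = 10:50,
                           bg = 0.9, dark = 0.2) {
  img <- matrix(bg, size, size)
  img[row, cols] <- dark
  img
}

test_that("find_seed locates the fundus nearest the midline", {
  g <- generate_sulcus_image(size = 96, seed = 3)
  seed <- find_seed(g$image, midline_x = g$midline_col, hemisphere = "left",
                    intensity_band = c(0.15, 0.55))
  expect_lte(sqrt(sum((seed - g$seed_px)^2)), 2)
  # user-supplied seed overrides
  expect_equal(find_seed(g$image, g$midline_col, "left", c(0, 1),
                         seed = c(7, 9)), c(7L, 9L))
  expect_error(find_seed(matrix(1, 10, 10), 5, "left", c(0, 0.1)),
               "no pixel in the grey-matter")
})

test_that("a straight dark line is traced exactly with zero noise", {
  img <- straight_image()
  path <- trace_sulcus(img, seed = c(20, 50), midline_x = 55)
  expect_equal(nrow(path$pixels), 41)
  expect_true(all(path$pixels[, 1] == 20))
  expect_equal(path$pixels[, 2], 50:10)
})

test_that("paths are self-avoiding 8-connected chains, deterministically", {
  for (s in 1:6) {
    g <- generate_sulcus_image(size = 80, noise_sd = 0.05, seed = s)
    p <- trace_sulcus(g$image, g$seed_px, midline_x = g$midline_col)
    px <- p$pixels
    expect_false(any(duplicated(px)))
    if (nrow(px) > 1) {
      steps <- abs(diff(px))
      expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
    }
    expect_identical(
      p, trace_sulcus(g$image, g$seed_px, midline_x = g$midline_col))
  }
})

test_that("tracing follows the generating curve at 10% noise", {
  frac <- vapply(1:20, function(s) {
    g <- generate_sulcus_image(size = 96, depth_contrast = 0.5,
                               noise_sd = 0.05, seed = 100 + s)
    p <- trace_sulcus(g$image, g$seed_px, midline_x = g$midline_col)
    d <- vapply(seq_len(nrow(p$pixels)), function(i) {
      min(sqrt((g$true_path[, 1] - p$pixels[i, 1])^2 +
                 (g$true_path[, 2] - p$pixels[i, 2])^2))
    }, numeric(1))
    mean(d <= 1)
  }, numeric(1))
  expect_gte(min(frac), 0.95)
})

test_that("tracing is invariant under a global intensity offset", {
  g <- generate_sulcus_image(size = 64, noise_sd = 0.03, seed = 9)
  p1 <- trace_sulcus(g$image, g$seed_px, midline_x = g$midline_col)
  p2 <- trace_sulcus(g$image + 0.05, g$seed_px, midline_x = g$midline_col,
                     stop_intensity = (min(g$image + 0.05) +
                                         median(g$image + 0.05)) / 2)
  expect_identical(p1$pixels, p2$pixels)
})

test_that("a bright seed yields a single-pixel path with a warning", {
  img <- straight_image()
  expect_warning(p <- trace_sulcus(img, seed = c(5, 5), midline_x = 55),
                 "single-pixel")
  expect_equal(nrow(p$pixels), 1)
})

test_that("peak categorisation follows the fixed evaluation order", {
  img <- straight_image()
  path <- trace_sulcus(img, seed = c(20, 50), midline_x = 55)
  # on a path pixel -> ON_LINE
  expect_equal(categorize_peak(path, c(20, 30)), "ON_LINE")
  # closer than one pixel to the seed -> FUNDUS even though on the line
  expect_equal(categorize_peak(path, c(20.3, 50.4)), "FUNDUS")
  expect_equal(categorize_peak(path, c(20.5, 50)), "FUNDUS")
  # +/- 5 px along the anterior axis (+row) from a vertical path
  expect_equal(categorize_peak(path, c(25, 30)), "ANTERIOR")
  expect_equal(categorize_peak(path, c(15, 30)), "POSTERIOR")
})

test_that("probe points of generated images are categorised as labelled", {
  for (s in 1:5) {
    g <- generate_sulcus_image(size = 96, noise_sd = 0.05, seed = 200 + s)
    p <- structure(list(seed = g$seed_px, pixels = g$true_path,
                        midline_x = g$midline_col),
                   class = "sulcus_path")
    pr <- g$probe_points
    got <- vapply(seq_len(nrow(pr)), function(i) {
      categorize_peak(p, c(pr$row[i], pr$col[i]))
    }, character(1))
    expect_identical(got, pr$label)
  }
})

test_that("mirroring the image flips the hemisphere but not the categories", {
  g <- generate_sulcus_image(size = 80, noise_sd = 0.04, seed = 11)
  nc <- ncol(g$image)
  mir <- g$image[, nc:1]
  seed_m <- c(g$seed_px[1], nc + 1 - g$seed_px[2])
  p <- trace_sulcus(g$image, g$seed_px, midline_x = g$midline_col)
  pm <- trace_sulcus(mir, seed_m, midline_x = nc + 1 - g$midline_col)
  pr <- g$probe_points
  for (i in seq_len(nrow(pr))) {
    a <- categorize_peak(p, c(pr$row[i], pr$col[i]))
    b <- categorize_peak(pm, c(pr$row[i], nc + 1 - pr$col[i]))
    expect_identical(a, b)
  }
})

test_that("category tallies count every peak exactly once", {
  expect_equal(sum(tally_categories(character(0))), 0)
  planted <- c(rep("ON_LINE", 3), rep("FUNDUS", 2), rep("ANTERIOR", 4),
               "POSTERIOR")
  tal <- tally_categories(sample(planted))
  expect_equal(as.integer(tal), c(3L, 2L, 4L, 1L))
  expect_equal(sum(tal), length(planted))
  expect_error(tally_categories("ELSEWHERE"), "unknown category")
})

test_that("slice PNG round-trips through 16-bit grayscale", {
  g <- generate_sulcus_image(size = 48, seed = 12)
  f <- withr::local_tempfile(fileext = ".png")
  write_slice_png(g$image, f)
  back <- read_slice_png(f)
  expect_equal(dim(back), dim(g$image))
  expect_lt(max(abs(back - g$image)), 2 / 255)
})
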