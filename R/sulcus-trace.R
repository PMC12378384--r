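# Central-sulcus localisation on a 2-D axial grayscale slice.
# Coordinates are (row, col) 1-based matrix indices; the anterior axis is
# declared by the caller (default +row under the package's slice
# orientation convention). "Centrifugal" means moving away from the
# interhemispheric midline column.

#' Find a tracing seed at the sulcal fundus closest to the midline
#'
#' Among pixels whose intensity falls in the grey-matter band and which lie
#' in the requested hemisphere, returns the one closest to the midline
#' column (ties broken toward the darkest pixel). The sulcus never reaches
#' the midline at this axial level, so the seed sits at the fundus. A
#' user-supplied seed always overrides the search (manual seeding is the
#' reference procedure).
#'
#' @param image Numeric matrix, grayscale.
#' @param midline_x Midline column index.
#' @param hemisphere `"left"` (columns below the midline) or `"right"`.
#' @param intensity_band `c(low, high)` grey-matter intensity range.
#' @param seed Optional `(row, col)`; returned unchanged when given.
#' @return Integer `(row, col)`.
#' @export
find_seed <- function(image, midline_x, hemisphere = c("left", "right"),
                      intensity_band, seed = NULL) {
  if (!is.null(seed)) return(as.integer(seed))
  hemisphere <- match.arg(hemisphere)
  stopifnot(is.matrix(image), midline_x >= 1, midline_x <= ncol(image),
            length(intensity_band) == 2L)
  cols <- if (hemisphere == "left") {
    seq_len(max(1L, floor(midline_x - 1)))
  } else {
    seq(min(ncol(image), ceiling(midline_x + 1)), ncol(image))
  }
  sub <- image[, cols, drop = FALSE]
  in_band <- sub >= intensity_band[1] & sub <= intensity_band[2]
  if (!any(in_band)) stop_bad("no pixel in the grey-matter intensity band")
  idx <- which(in_band, arr.ind = TRUE)
  cc <- cols[idx[, 2]]
  d <- abs(cc - midline_x)
  best <- which(d == min(d))
  if (length(best) > 1L) {
    best <- best[which.min(sub[idx[best, , drop = FALSE]])]
  }
  c(idx[best, 1], cols[idx[best, 2]])
}

#' Trace the central sulcus by centrifugal lowest-intensity path following
#'
#' Greedy walk from the seed: among the 8-neighbours of the current pixel
#' that are not already on the path and whose distance from the midline
#' column is not decreasing (with a 1 px hysteresis, preventing immediate
#' stalls on diagonal sulci), step to the lowest-intensity pixel. The walk
#' stops at the image border, after `max_len` pixels, or when the best
#' candidate is brighter than `stop_intensity`. Intensity ties break by
#' preferring the continuation of the previous step direction, then by
#' clockwise angular order.
#'
#' @param image Numeric matrix, grayscale (dark sulcus on bright surround).
#' @param seed `(row, col)` starting pixel (the fundus).
#' @param max_len Maximum path length in pixels.
#' @param stop_intensity Stop when the best next pixel exceeds this
#'   intensity; default midpoint between the image's darkest level and its
#'   median (separating the dark sulcal band from the bright surround).
#' @param midline_x Midline column; default the seed's column (the seed is
#'   the path's closest approach to the midline).
#' @return A list of class `sulcus_path`: `seed`, `pixels` (m x 2 matrix of
#'   `(row, col)`, first row = seed), `midline_x`.
#' @export
trace_sulcus <- function(image, seed, max_len = 4096L,
                         stop_intensity = NULL, midline_x = NULL) {
  stopifnot(is.matrix(image), length(seed) == 2L)
  nr <- nrow(image); nc <- ncol(image)
  r <- as.integer(seed[1]); c0 <- as.integer(seed[2])
  if (r < 1L || r > nr || c0 < 1L || c0 > nc) stop_bad("seed outside image")
  if (is.null(midline_x)) midline_x <- c0
  if (is.null(stop_intensity)) {
    stop_intensity <- (min(image) + median(image)) / 2
  }
  if (image[r, c0] > stop_intensity) {
    warn_msg("seed intensity %.3f exceeds stop_intensity %.3f; single-pixel path",
             image[r, c0], stop_intensity)
    return(structure(list(seed = c(r, c0),
                          pixels = matrix(c(r, c0), 1L, 2L,
                                          dimnames = list(NULL, c("row", "col"))),
                          midline_x = midline_x),
                     class = "sulcus_path"))
  }
  # 8-neighbourhood in clockwise order starting at "up"
  nbr <- cbind(row = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
               col = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
  on_path <- matrix(FALSE, nr, nc)
  path <- matrix(NA_integer_, max_len, 2L)
  path[1L, ] <- c(r, c0)
  on_path[r, c0] <- TRUE
  len <- 1L
  prev_dir <- NA_integer_
  while (len < max_len) {
    cur <- path[len, ]
    if (cur[1] == 1L || cur[1] == nr || cur[2] == 1L || cur[2] == nc) break
    cand_r <- cur[1] + nbr[, 1]
    cand_c <- cur[2] + nbr[, 2]
    ok <- cand_r >= 1L & cand_r <= nr & cand_c >= 1L & cand_c <= nc
    ok <- ok & !on_path[cbind(pmax(1L, pmin(nr, cand_r)),
                              pmax(1L, pmin(nc, cand_c)))]
    # centrifugal with 1 px hysteresis
    ok <- ok & (abs(cand_c - midline_x) >= abs(cur[2] - midline_x) - 1)
    if (!any(ok)) break
    ints <- image[cbind(cand_r, cand_c)]
    ints[!ok] <- Inf
    best_val <- min(ints)
    if (best_val > stop_intensity) break
    tied <- which(ints == best_val)
    pick <- if (length(tied) == 1L) {
      tied
    } else if (!is.na(prev_dir) && prev_dir %in% tied) {
      prev_dir
    } else {
      tied[1L]  # clockwise order from "up"
    }
    len <- len + 1L
    path[len, ] <- c(cand_r[pick], cand_c[pick])
    on_path[cand_r[pick], cand_c[pick]] <- TRUE
    prev_dir <- pick
  }
  structure(list(seed = c(r, c0),
                 pixels = matrix(path[seq_len(len), ], len, 2L,
                                 dimnames = list(NULL, c("row", "col"))),
                 midline_x = midline_x),
            class = "sulcus_path")
}

#' @export
print.sulcus_path <- function(x, ...) {
  cat(sprintf("<sulcus_path> %d pixels from seed (%d, %d)\n",
              nrow(x$pixels), x$seed[1], x$seed[2]))
  invisible(x)
}

#' Categorise an activation peak relative to a traced sulcus
#'
#' Fixed evaluation order: `FUNDUS` when the peak is closer than
#' `fundus_radius` to the seed (the sulcal fundus); otherwise `ON_LINE`
#' when its distance to the traced line is below `on_line_radius`;
#' otherwise `ANTERIOR` or `POSTERIOR` by the sign of the projection of
#' (peak - nearest path point) onto the anterior axis.
#'
#' @param path A `sulcus_path` with at least 2 pixels.
#' @param peak `(row, col)` coordinate (may be fractional).
#' @param fundus_radius Pixels (default 1).
#' @param on_line_radius Pixels (default 1).
#' @param anterior_axis Unit `(row, col)` direction pointing anteriorly
#'   (default `c(1, 0)`, the package's slice orientation convention).
#' @return One of `"FUNDUS"`, `"ON_LINE"`, `"ANTERIOR"`, `"POSTERIOR"`.
#' @export
categorize_peak <- function(path, peak, fundus_radius = 1,
                            on_line_radius = 1, anterior_axis = c(1, 0)) {
  stopifnot(inherits(path, "sulcus_path"), nrow(path$pixels) >= 2L,
            length(peak) == 2L)
  peak <- as.numeric(peak)
  if (sqrt(sum((peak - path$seed)^2)) < fundus_radius) return("FUNDUS")
  d2 <- (path$pixels[, 1] - peak[1])^2 + (path$pixels[, 2] - peak[2])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) < on_line_radius) return("ON_LINE")
  v <- peak - path$pixels[i, ]
  proj <- sum(v * anterior_axis / sqrt(sum(anterior_axis^2)))
  if (proj >= 0) "ANTERIOR" else "POSTERIOR"
}

#' Tally peak categories
#'
#' @param categories Character vector of categories from
#'   [categorize_peak()].
#' @return Named integer vector with counts for `ON_LINE`, `FUNDUS`,
#'   `ANTERIOR`, `POSTERIOR` (sums to `length(categories)`).
#' @export
tally_categories <- function(categories) {
  lv <- c("ON_LINE", "FUNDUS", "ANTERIOR", "POSTERIOR")
  bad <- setdiff(unique(categories), lv)
  if (length(bad)) stop_bad("unknown category '%s'", bad[1])
  table(factor(categories, levels = lv))
}
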