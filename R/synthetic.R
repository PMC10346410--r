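# Synthetic tree scenes: thick strokes with exact, known axis length and
# inclination, paired with ground-truth class masks. Used as test fixtures
# and as stand-in training data for the segmenter.

#' Stroke descriptor for a synthetic scene
#'
#' A stroke is a Bresenham line of chessboard length `length_px` starting
#' at `start` (row, col), at `angle_deg` degrees from the horizontal
#' (y measured upward), dilated by a disk of radius `(width_px - 1) / 2`.
#' Rasterization is anti-alias free, so the ground-truth axis pixel count
#' is exact.
#'
#' @param start integer (row, col) of the axis start pixel.
#' @param length_px chessboard length of the axis in pixels (>= 2).
#' @param angle_deg inclination from horizontal, degrees.
#' @param width_px nominal stroke width in pixels (>= 1).
#' @export
stroke <- function(start, length_px, angle_deg, width_px) {
  stopifnot(length(start) == 2L, length_px >= 2, width_px >= 1)
  list(start = as.integer(start), length_px = as.integer(length_px),
       angle_deg = as.numeric(angle_deg), width_px = as.integer(width_px))
}

#' Scene specification for the synthetic generator
#'
#' @param h,w image size in pixels.
#' @param trunks,branches lists of [stroke()] descriptors.
#' @param clutter list with `n` distractor blobs and `size` range
#'   (radius, pixels); blobs perturb only the RGB image, never the mask.
#' @param noise_sd standard deviation of Gaussian RGB noise.
#' @param condition photometric condition tag: "sunny", "rainy", "night",
#'   "snowy", "foggy" or "typhoon" (fog = contrast compression, typhoon =
#'   horizontal motion blur; both affect the RGB image only).
#' @param seed integer seed making the render deterministic.
#' @export
scene_spec <- function(h = 256L, w = 256L, trunks = list(),
                       branches = list(), clutter = list(n = 0L, size = c(2L, 6L)),
                       noise_sd = 0.02, condition = "sunny", seed = 1L) {
  condition <- match.arg(condition,
                         c("sunny", "rainy", "night", "snowy", "foggy", "typhoon"))
  structure(list(h = as.integer(h), w = as.integer(w), trunks = trunks,
                 branches = branches, clutter = clutter,
                 noise_sd = noise_sd, condition = condition,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# integer Bresenham line, returns matrix of (row, col)
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  out
}

# disk offsets for a nominal width
disk_offsets <- function(width_px) {
  rad <- (width_px - 1) / 2
  R <- ceiling(rad)
  g <- expand.grid(a = -R:R, b = -R:R)
  g <- g[g$a^2 + g$b^2 <= rad^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# paint one stroke; returns list(mask updated, axis_px realized)
paint_stroke <- function(mask, st, label) {
  h <- nrow(mask); w <- ncol(mask)
  th <- st$angle_deg * pi / 180
  dr <- -sin(th); dc <- cos(th)
  s <- (st$length_px - 1) / max(abs(dr), abs(dc))
  r1 <- as.integer(round(st$start[1] + s * dr))
  c1 <- as.integer(round(st$start[2] + s * dc))
  ax <- bresenham(st$start[1], st$start[2], r1, c1)
  inb <- ax[, 1] >= 1L & ax[, 1] <= h & ax[, 2] >= 1L & ax[, 2] <= w
  if (!any(inb)) stop("stroke lies fully outside the image")
  ax <- ax[inb, , drop = FALSE]
  off <- disk_offsets(st$width_px)
  for (i in seq_len(nrow(ax))) {
    rr <- ax[i, 1] + off[, 1]; cc <- ax[i, 2] + off[, 2]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    mask[cbind(rr[ok], cc[ok])] <- label
  }
  axis_px <- max(abs(ax[nrow(ax), 1] - ax[1, 1]),
                 abs(ax[nrow(ax), 2] - ax[1, 2])) + 1L
  list(mask = mask, axis_px = axis_px)
}

#' Render a synthetic tree scene
#'
#' Paints trunks (class 1) then branches (class 2) into a class mask,
#' composes an RGB image with condition-dependent background, clutter
#' blobs, photometric perturbation and Gaussian noise, and returns exact
#' ground-truth records per stroke. Photometric perturbations change only
#' the RGB image, never the mask. Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (h x w x 3 array in \[0,1\]), `mask`
#'   (integer class matrix) and `truth` (data.frame: class, angle_deg in
#'   \[0,180), axis_px, width_px).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$h; w <- spec$w
    mask <- matrix(0L, h, w)
    truth <- list()
    for (st in spec$trunks) {
      p <- paint_stroke(mask, st, 1L)
      mask <- p$mask
      truth[[length(truth) + 1L]] <-
        data.frame(class = "trunk", angle_deg = st$angle_deg %% 180,
                   axis_px = p$axis_px, width_px = st$width_px)
    }
    for (st in spec$branches) {
      p <- paint_stroke(mask, st, 2L)
      mask <- p$mask
      truth[[length(truth) + 1L]] <-
        data.frame(class = "branch", angle_deg = st$angle_deg %% 180,
                   axis_px = p$axis_px, width_px = st$width_px)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(class = character(), angle_deg = numeric(),
                 axis_px = integer(), width_px = integer())

    bgcol <- switch(spec$condition,
                    sunny = c(0.65, 0.75, 0.90), rainy = c(0.50, 0.52, 0.55),
                    night = c(0.25, 0.25, 0.32), snowy = c(0.90, 0.90, 0.95),
                    foggy = c(0.55, 0.56, 0.58), typhoon = c(0.48, 0.50, 0.54))
    trunk_col <- c(0.30, 0.20, 0.10)
    branch_col <- c(0.45, 0.33, 0.16)
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) {
      pl <- matrix(bgcol[ch], h, w)
      pl[mask == 1L] <- trunk_col[ch]
      pl[mask == 2L] <- branch_col[ch]
      img[, , ch] <- pl
    }
    # clutter: photometric distractors on the background only
    if (spec$clutter$n > 0L) {
      for (k in seq_len(spec$clutter$n)) {
        rad <- sample(spec$clutter$size[1]:spec$clutter$size[2], 1L)
        cr <- sample(seq_len(h), 1L); cc <- sample(seq_len(w), 1L)
        col <- stats::runif(3, 0.2, 0.8)
        off <- disk_offsets(2L * rad + 1L)
        rr <- cr + off[, 1]; cc2 <- cc + off[, 2]
        ok <- rr >= 1L & rr <= h & cc2 >= 1L & cc2 <= w &
          mask[cbind(pmax(pmin(rr, h), 1L), pmax(pmin(cc2, w), 1L))] == 0L
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[cbind(rr[ok], cc2[ok])] <- col[ch]
          img[, , ch] <- pl
        }
      }
    }
    bright <- switch(spec$condition, sunny = 1.0, rainy = 0.85, night = 0.35,
                     snowy = 1.0, foggy = 0.9, typhoon = 0.85)
    img <- img * bright
    if (spec$condition == "foggy") img <- 0.5 + (img - 0.5) * 0.4
    if (spec$condition == "typhoon") {
      # horizontal 5-tap box blur (motion streak); RGB only
      for (ch in 1:3) {
        pl <- img[, , ch]
        pad <- cbind(pl[, c(1, 1)], pl, pl[, c(w, w)])
        acc <- pl * 0
        for (s in 0:4) acc <- acc + pad[, (1 + s):(w + s)]
        img[, , ch] <- acc / 5
      }
    }
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
    list(image = img, mask = mask, truth = truth)
  })
}

#' Draw a random scene specification
#'
#' One vertical-ish trunk plus `n_branches` branch strokes fanning out
#' from the trunk, with widths, lengths and angles drawn uniformly from
#' the given ranges. Branch strokes are rejected (up to 20 retries each)
#' if they would touch an already placed branch, so ground-truth stroke
#' counts match the number of branch components. Uses the current RNG
#' state; seed with [with_seed()] or `set.seed()` for reproducibility.
#'
#' @param h,w image size.
#' @param n_branches number of branch strokes.
#' @param widths,lengths,angles ranges (inclusive) to sample branch
#'   width, chessboard length and inclination from.
#' @param condition photometric condition tag; "random" samples one.
#' @param seed seed stored in the returned spec (drives [render_scene()]).
#' @return a [scene_spec()].
#' @export
random_scene_spec <- function(h = 256L, w = 256L, n_branches = 3L,
                              widths = c(2L, 8L), lengths = c(40L, 120L),
                              angles = c(5, 175), condition = "sunny",
                              seed = 1L) {
  if (identical(condition, "random"))
    condition <- sample(c("sunny", "rainy", "night", "snowy", "foggy",
                          "typhoon"), 1L)
  trunk_w <- sample(8:14, 1L)
  trunk <- stroke(start = c(h - 5L, sample(seq(w %/% 3, 2L * w %/% 3), 1L)),
                  length_px = h - 10L,
                  angle_deg = stats::runif(1, 85, 95), width_px = trunk_w)
  branches <- list()
  # branches may not touch the trunk or each other: overwriting labels
  # would otherwise split components and break the stroke-count truth
  occupied <- paint_stroke(matrix(0L, h, w), trunk, 1L)$mask
  tries <- 0L
  while (length(branches) < n_branches && tries < 20L * n_branches) {
    tries <- tries + 1L
    len <- sample(lengths[1]:lengths[2], 1L)
    wd <- sample(widths[1]:widths[2], 1L)
    ang <- stats::runif(1, angles[1], angles[2])
    # keep the start inside; strokes larger than the canvas get clipped
    # at the border and their realized axis length recorded as truth
    margin <- min(len + wd + 2L, (min(h, w) - 2L) %/% 2L)
    st <- stroke(start = c(sample(seq(margin, h - margin), 1L),
                           sample(seq(margin, w - margin), 1L)),
                 length_px = len, angle_deg = ang, width_px = wd)
    cand <- paint_stroke(matrix(0L, h, w), st, 1L)$mask
    # 1-px dilation of the candidate must not meet existing branches
    dil <- cand
    dil[-1, ] <- pmax(dil[-1, ], cand[-h, ])
    dil[-h, ] <- pmax(dil[-h, ], cand[-1, ])
    dil[, -1] <- pmax(dil[, -1], cand[, -w])
    dil[, -w] <- pmax(dil[, -w], cand[, -1])
    if (any(dil == 1L & occupied == 1L)) next
    occupied[cand == 1L] <- 1L
    branches[[length(branches) + 1L]] <- st
  }
  scene_spec(h = h, w = w, trunks = list(trunk), branches = branches,
             clutter = list(n = sample(0:3, 1L), size = c(2L, 5L)),
             noise_sd = 0.02, condition = condition, seed = seed)
}

#' Write a synthetic dataset to disk
#'
#' Generates `n` random scenes and writes the VOC-like layout used by the
#' training loop: `images/<stem>.png`, `masks/<stem>.png` (gray level =
#' class id), `truth/<stem>.csv` ground-truth stroke records, and
#' `train.txt` / `val.txt` split lists at a 9:1 ratio (validation size
#' `floor(n/10)`, at least 1).
#'
#' @param n number of scenes (>= 2).
#' @param dir output directory (created if missing).
#' @param seed master seed; scene i uses seed `seed + i`.
#' @param ... forwarded to [random_scene_spec()].
#' @return invisibly, the vector of scene stems.
#' @export
make_dataset <- function(n, dir, seed = 1L, ...) {
  if (n < 2L) stop("need n >= 2 for a train/val split")
  for (d in file.path(dir, c("images", "masks", "truth")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  stems <- sprintf("scene_%03d", seq_len(n))
  for (i in seq_len(n)) {
    spec <- with_seed(seed + i, random_scene_spec(seed = seed + i, ...))
    sc <- render_scene(spec)
    write_image(sc$image, file.path(dir, "images", paste0(stems[i], ".png")))
    write_mask(sc$mask, file.path(dir, "masks", paste0(stems[i], ".png")))
    utils::write.csv(sc$truth,
                     file.path(dir, "truth", paste0(stems[i], ".csv")),
                     row.names = FALSE)
  }
  n_val <- max(1L, n %/% 10L)
  writeLines(stems[seq_len(n - n_val)], file.path(dir, "train.txt"))
  writeLines(stems[(n - n_val + 1L):n], file.path(dir, "val.txt"))
  invisible(stems)
}
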