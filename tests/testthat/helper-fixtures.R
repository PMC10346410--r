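# Shared fixtures: an independent whole-image thinning oracle (vectorized
# shifted-matrix arithmetic, a different route than the package's
# per-pixel scan), random blob masks, and single-stroke render helpers.

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  r_src <- seq_len(h) + dr
  c_src <- seq_len(w) + dc
  rok <- r_src >= 1L & r_src <= h
  cok <- c_src >= 1L & c_src <= w
  out[rok, cok] <- m[r_src[rok], c_src[cok]]
  out
}

# neighbor maps in the clockwise order P2..P9 (N, NE, E, SE, S, SW, W, NW)
neighbor_maps <- function(m) {
  list(shift_mat(m, -1L, 0L), shift_mat(m, -1L, 1L), shift_mat(m, 0L, 1L),
       shift_mat(m, 1L, 1L), shift_mat(m, 1L, 0L), shift_mat(m, 1L, -1L),
       shift_mat(m, 0L, -1L), shift_mat(m, -1L, -1L))
}

oracle_step_mask <- function(m, step) {
  p <- neighbor_maps(m)
  n <- Reduce(`+`, p)
  s <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) {
    nxt <- p[[if (i == 8L) 1L else i + 1L]]
    s <- s + (p[[i]] == 0L & nxt == 1L)
  }
  cond <- m == 1L & n >= 2L & n <= 6L & s == 1L
  if (step == 1L)
    cond & p[[1]] * p[[3]] * p[[5]] == 0L & p[[3]] * p[[5]] * p[[7]] == 0L
  else
    cond & p[[1]] * p[[3]] * p[[7]] == 0L & p[[1]] * p[[5]] * p[[7]] == 0L
}

oracle_thin <- function(m) {
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      del <- oracle_step_mask(m, step)
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) return(m)
  }
}

random_grid <- function(h = 16L, w = 16L, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.2, 0.8)
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# union of a few random filled rectangles and disks; features are >= 3 px
# on a side (the two-subiteration scheme deletes isolated 2x2 squares
# entirely, which would confound connectivity-count checks)
random_blob <- function(h = 24L, w = 24L) {
  m <- matrix(0L, h, w)
  for (k in seq_len(sample(1:3, 1))) {
    r0 <- sample(seq_len(h - 3L), 1); c0 <- sample(seq_len(w - 3L), 1)
    r1 <- min(h, r0 + sample(2:7, 1)); c1 <- min(w, c0 + sample(2:7, 1))
    m[r0:r1, c0:c1] <- 1L
  }
  for (k in seq_len(sample(0:2, 1))) {
    cr <- sample(seq_len(h), 1); cc <- sample(seq_len(w), 1)
    rad <- sample(2:5, 1)
    for (a in -rad:rad) for (b in -rad:rad)
      if (a^2 + b^2 <= rad^2) {
        rr <- cr + a; c2 <- cc + b
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w) m[rr, c2] <- 1L
      }
  }
  m
}

# render one branch stroke centered in an adaptive canvas; returns the
# class mask and the exact ground-truth record
render_single_stroke <- function(angle_deg, length_px, width_px, seed = 1L) {
  sz <- as.integer(length_px + 2L * width_px + 20L)
  th <- angle_deg * pi / 180
  dr <- -sin(th); dc <- cos(th)
  s <- (length_px - 1) / max(abs(dr), abs(dc))
  start <- c(round(sz / 2 - s * dr / 2), round(sz / 2 - s * dc / 2))
  spec <- scene_spec(h = sz, w = sz, trunks = list(),
                     branches = list(stroke(start, length_px, angle_deg,
                                            width_px)),
                     noise_sd = 0, seed = seed)
  render_scene(spec)
}

# brute-force per-pixel segmentation metrics, independent of confusion()
brute_seg_metrics <- function(truth, pred, K1) {
  iou <- prec <- rec <- numeric(K1)
  for (i in seq_len(K1) - 1L) {
    tp <- sum(truth == i & pred == i)
    fp <- sum(truth != i & pred == i)
    fn <- sum(truth == i & pred != i)
    iou[i + 1] <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
    prec[i + 1] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i + 1] <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  p <- mean(prec); r <- mean(rec)
  list(miou = mean(iou), precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
}

# 8-connected component count via the package's internal labeler
cpp_label8_test <- function(m) branchmorph:::cpp_label8(m)

# independent 8-component count via igraph (when available)
igraph_components8 <- function(m) {
  fg <- which(m == 1L, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(0L)
  id <- seq_len(nrow(fg))
  key <- paste(fg[, 1], fg[, 2])
  lookup <- stats::setNames(id, key)
  edges <- integer(0)
  for (k in id) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- lookup[paste(fg[k, 1] + dr, fg[k, 2] + dc)]
      if (!is.na(nb) && nb > k) edges <- c(edges, k, nb)
    }
  }
  g <- igraph::make_graph(edges, n = nrow(fg), directed = FALSE)
  igraph::components(g)$no
}

small_unet <- function(seed = 1L, use_se = TRUE, use_ram = TRUE) {
  cfg <- unet_config(enc_channels = c(8L, 16L, 32L),
                     enc_convs = c(1L, 1L, 1L), se_reduction = 4L,
                     use_se = use_se, use_ram = use_ram)
  build_unet(cfg, seed = seed)
}
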