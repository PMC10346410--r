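#' Configuration of the attention-augmented UNet
#'
#' The default architecture uses a VGG16-style encoder: 13 convolutional
#' layers (3x3, stride 1, zero padding) in blocks of \[2, 2, 3, 3, 3\]
#' with channel widths \[64, 128, 256, 512, 512\] and 4 max-pooling layers
#' (2x2, stride 2) between the first four blocks. The decoder mirrors it
#' with 4 transpose-conv (2x2, stride 2) upsampling stages, each followed
#' by skip concatenation and a two-conv block. An SE channel-attention
#' module sits before each of the 4 max-pools and at 5 decoding-path
#' sites (the bottleneck plus each of the 4 skip concatenations); a
#' residual attention module (RAM) follows the first SE module. The head
#' is a 1x1 convolution and a per-pixel softmax over `num_classes`.
#'
#' Smaller `enc_channels`/`enc_convs` give a reduced network with the same
#' topology, useful for CPU-scale experiments.
#'
#' @param in_channels input image channels (3 for RGB).
#' @param num_classes output classes (>= 2; default 3:
#'   background/trunk/branch).
#' @param enc_channels channel width per encoder block; the last entry is
#'   the bottleneck.
#' @param enc_convs convolutions per encoder block.
#' @param se_reduction SE bottleneck reduction ratio r; must divide every
#'   channel width at an SE site.
#' @param ram_kernel RAM convolution kernel size (odd).
#' @param use_se,use_ram toggles for the attention modules (ablations).
#' @return object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 3L, num_classes = 3L,
                        enc_channels = c(64L, 128L, 256L, 512L, 512L),
                        enc_convs = c(2L, 2L, 3L, 3L, 3L),
                        se_reduction = 16L, ram_kernel = 3L,
                        use_se = TRUE, use_ram = TRUE) {
  stopifnot(num_classes >= 2L, length(enc_channels) == length(enc_convs),
            length(enc_channels) >= 2L, ram_kernel %% 2L == 1L)
  depth <- length(enc_channels) - 1L
  if (use_se) {
    sites <- c(enc_channels[seq_len(depth)], enc_channels[depth + 1L],
               2L * enc_channels[seq_len(depth)])
    if (any(sites %% se_reduction != 0L))
      stop("se_reduction must divide the channel count at every SE site")
  }
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 enc_channels = as.integer(enc_channels),
                 enc_convs = as.integer(enc_convs),
                 se_reduction = as.integer(se_reduction),
                 ram_kernel = as.integer(ram_kernel),
                 use_se = use_se, use_ram = use_ram, depth = depth),
            class = "unet_config")
}

#' Training hyperparameters
#'
#' Defaults follow the reference training recipe: Adam, pixel-wise
#' cross-entropy, initial learning rate 1e-4 with cosine decay
#' lr(t) = lr0 * 0.5 * (1 + cos(pi * t / epochs)), batch size 4,
#' 300 epochs with the encoder frozen for the first 150 then released.
#'
#' @param lr0 initial learning rate.
#' @param epochs total epochs.
#' @param freeze_epochs epochs with encoder conv weights frozen
#'   (<= epochs).
#' @param batch_size images per gradient step.
#' @param seed RNG seed for shuffling (and any augmentation).
#' @export
train_config <- function(lr0 = 1e-4, epochs = 300L, freeze_epochs = 150L,
                         batch_size = 4L, seed = 1L) {
  stopifnot(freeze_epochs <= epochs, batch_size >= 1L, lr0 > 0)
  structure(list(lr0 = lr0, epochs = as.integer(epochs),
                 freeze_epochs = as.integer(freeze_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

he_mat <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)

#' Build (initialize) the network
#'
#' Allocates all parameters with He initialization (pretrained encoder
#' weights are not bundled; the builder is fully offline). Deterministic
#' given `seed`.
#'
#' @param cfg a [unet_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `unet` with fields `cfg` and `params`.
#' @export
build_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  with_seed(seed, {
    p <- list()
    ch <- cfg$enc_channels
    depth <- cfg$depth
    r <- cfg$se_reduction
    cin <- cfg$in_channels
    for (b in seq_len(depth + 1L)) {
      for (i in seq_len(cfg$enc_convs[b])) {
        cc <- if (i == 1L) (if (b == 1L) cin else ch[b - 1L]) else ch[b]
        p[[sprintf("enc%d_conv%d_W", b, i)]] <- he_mat(9L * cc, ch[b], 9L * cc)
        p[[sprintf("enc%d_conv%d_b", b, i)]] <- rep(0, ch[b])
      }
      if (cfg$use_se) {
        site <- if (b <= depth) sprintf("se_enc%d", b) else "se_bott"
        p[[paste0(site, "_W1")]] <- he_mat(ch[b] %/% r, ch[b], ch[b])
        p[[paste0(site, "_W2")]] <- he_mat(ch[b], ch[b] %/% r, ch[b] %/% r)
      }
      if (b == 1L && cfg$use_ram) {
        ram <- ram_init(ch[1], k = cfg$ram_kernel)
        p$ram_Wc <- ram$Wc; p$ram_bc <- ram$bc
        p$ram_Wg <- ram$Wg; p$ram_bg <- ram$bg
        p$ram_Wd <- ram$Wd; p$ram_bd <- ram$bd
      }
    }
    for (d in rev(seq_len(depth))) {
      up_in <- if (d == depth) ch[depth + 1L] else ch[d + 1L]
      p[[sprintf("up%d_W", d)]] <- he_mat(4L * up_in, ch[d], up_in)
      p[[sprintf("up%d_b", d)]] <- rep(0, ch[d])
      if (cfg$use_se) {
        cc <- 2L * ch[d]
        p[[sprintf("se_dec%d_W1", d)]] <- he_mat(cc %/% r, cc, cc)
        p[[sprintf("se_dec%d_W2", d)]] <- he_mat(cc, cc %/% r, cc %/% r)
      }
      for (i in 1:2) {
        cc <- if (i == 1L) 2L * ch[d] else ch[d]
        p[[sprintf("dec%d_conv%d_W", d, i)]] <- he_mat(9L * cc, ch[d], 9L * cc)
        p[[sprintf("dec%d_conv%d_b", d, i)]] <- rep(0, ch[d])
      }
    }
    p$head_W <- he_mat(ch[1], cfg$num_classes, ch[1])
    p$head_b <- rep(0, cfg$num_classes)
    structure(list(cfg = cfg, params = p), class = "unet")
  })
}

# reflect-pad an (h, w, c) array (bottom/right) to multiples of 2^depth
pad_input <- function(x, depth) {
  mult <- 2L^depth
  d <- dim(x)
  ph <- (mult - d[1] %% mult) %% mult
  pw <- (mult - d[2] %% mult) %% mult
  if (ph > 0L) {
    rows <- rep(c(seq_len(d[1]), rev(seq_len(d[1]))), length.out = d[1] + ph)
    x <- x[rows, , , drop = FALSE]
  }
  if (pw > 0L) {
    cols <- rep(c(seq_len(d[2]), rev(seq_len(d[2]))), length.out = d[2] + pw)
    x <- x[, cols, , drop = FALSE]
  }
  list(x = x, h = d[1], w = d[2])
}

abind3 <- function(a, b, along) {
  da <- dim(a); db <- dim(b)
  if (along == 1L) {
    out <- array(0, c(da[1] + db[1], da[2], da[3]))
    out[seq_len(da[1]), , ] <- a
    out[da[1] + seq_len(db[1]), , ] <- b
  } else if (along == 2L) {
    out <- array(0, c(da[1], da[2] + db[2], da[3]))
    out[, seq_len(da[2]), ] <- a
    out[, da[2] + seq_len(db[2]), ] <- b
  } else {
    out <- array(0, c(da[1], da[2], da[3] + db[3]))
    out[, , seq_len(da[3])] <- a
    out[, , da[3] + seq_len(db[3])] <- b
  }
  out
}

#' Forward pass of the network
#'
#' @param net a `unet` from [build_unet()].
#' @param x input (h, w, in_channels) array; h and w need not be
#'   multiples of 2^depth (reflect padding and output cropping are
#'   applied).
#' @param want_cache keep intermediate activations for backprop
#'   (internal).
#' @param se_identity force every SE excitation gate to 1 (ablation: the
#'   output then equals the SE-free network with identical remaining
#'   weights).
#' @return list with `probs` (h, w, num_classes per-pixel softmax) and,
#'   when `want_cache`, the activation caches.
#' @export
unet_forward <- function(net, x, want_cache = FALSE, se_identity = FALSE) {
  cfg <- net$cfg
  p <- net$params
  if (length(dim(x)) != 3L || dim(x)[3] != cfg$in_channels)
    stop("input must be h x w x in_channels")
  pad <- pad_input(x, cfg$depth)
  x <- pad$x
  depth <- cfg$depth
  caches <- list()
  skips <- list()
  for (b in seq_len(depth + 1L)) {
    for (i in seq_len(cfg$enc_convs[b])) {
      cc <- conv_relu_fw(x, p[[sprintf("enc%d_conv%d_W", b, i)]],
                         p[[sprintf("enc%d_conv%d_b", b, i)]], 3L)
      x <- cc$y
      if (want_cache) caches[[sprintf("enc%d_conv%d", b, i)]] <- cc[c("x", "pre")]
    }
    if (cfg$use_se) {
      site <- if (b <= depth) sprintf("se_enc%d", b) else "se_bott"
      sc <- se_fw(x, p[[paste0(site, "_W1")]], p[[paste0(site, "_W2")]],
                  identity = se_identity)
      x <- sc$y
      if (want_cache) caches[[site]] <- sc[c("xm", "z", "a1", "h1", "s", "d")]
    }
    if (b == 1L && cfg$use_ram) {
      rp <- list(Wc = p$ram_Wc, bc = p$ram_bc, Wg = p$ram_Wg, bg = p$ram_bg,
                 Wd = p$ram_Wd, bd = p$ram_bd)
      rc <- ram_fw(x, rp, k = cfg$ram_kernel)
      x <- rc$y
      if (want_cache) caches$ram <- rc[c("x", "f_pre", "f", "g", "A", "mu", "d", "k")]
    }
    if (b <= depth) {
      skips[[b]] <- x
      mp <- cpp_maxpool_fw(x)
      if (want_cache) caches[[sprintf("pool%d", b)]] <-
        list(idx = mp$idx, h = dim(x)[1], w = dim(x)[2])
      x <- mp$y
    }
  }
  for (d in rev(seq_len(depth))) {
    if (want_cache) caches[[sprintf("up%d_in", d)]] <- x
    x <- cpp_upconv_fw(x, p[[sprintf("up%d_W", d)]], p[[sprintf("up%d_b", d)]])
    nup <- dim(x)[3]
    x <- abind3(x, skips[[d]], along = 3L)
    if (want_cache) caches[[sprintf("concat%d", d)]] <- nup
    if (cfg$use_se) {
      site <- sprintf("se_dec%d", d)
      sc <- se_fw(x, p[[paste0(site, "_W1")]], p[[paste0(site, "_W2")]],
                  identity = se_identity)
      x <- sc$y
      if (want_cache) caches[[site]] <- sc[c("xm", "z", "a1", "h1", "s", "d")]
    }
    for (i in 1:2) {
      cc <- conv_relu_fw(x, p[[sprintf("dec%d_conv%d_W", d, i)]],
                         p[[sprintf("dec%d_conv%d_b", d, i)]], 3L)
      x <- cc$y
      if (want_cache) caches[[sprintf("dec%d_conv%d", d, i)]] <- cc[c("x", "pre")]
    }
  }
  logits <- cpp_conv_fw(x, p$head_W, p$head_b, 1L)
  if (want_cache) caches$head_in <- x
  probs <- softmax_channels(logits)
  # crop back to the original size
  crop <- function(a) a[seq_len(pad$h), seq_len(pad$w), , drop = FALSE]
  out <- list(probs = crop(probs), pad = pad[c("h", "w")])
  if (want_cache) {
    out$probs_full <- probs
    out$caches <- caches
  }
  out
}

# Backward pass: dlogits -> parameter gradients (same names as params).
unet_backward <- function(net, fwd, dlogits) {
  cfg <- net$cfg
  p <- net$params
  caches <- fwd$caches
  g <- list()
  hb <- cpp_conv_bw(caches$head_in, p$head_W, dlogits, 1L)
  g$head_W <- hb$dW; g$head_b <- hb$db
  dx <- hb$dx
  depth <- cfg$depth
  dskips <- vector("list", depth)
  for (d in seq_len(depth)) {
    for (i in 2:1) {
      nm <- sprintf("dec%d_conv%d", d, i)
      cb <- conv_relu_bw(caches[[nm]], p[[paste0(nm, "_W")]], 3L, dx)
      g[[paste0(nm, "_W")]] <- cb$dW; g[[paste0(nm, "_b")]] <- cb$db
      dx <- cb$dx
    }
    if (cfg$use_se) {
      site <- sprintf("se_dec%d", d)
      sb <- se_bw(caches[[site]], p[[paste0(site, "_W1")]],
                  p[[paste0(site, "_W2")]], dx)
      g[[paste0(site, "_W1")]] <- sb$dW1; g[[paste0(site, "_W2")]] <- sb$dW2
      dx <- sb$dx
    }
    nup <- caches[[sprintf("concat%d", d)]]
    dup <- dx[, , seq_len(nup), drop = FALSE]
    dskips[[d]] <- dx[, , nup + seq_len(dim(dx)[3] - nup), drop = FALSE]
    ub <- cpp_upconv_bw(caches[[sprintf("up%d_in", d)]],
                        p[[sprintf("up%d_W", d)]], dup)
    g[[sprintf("up%d_W", d)]] <- ub$dW; g[[sprintf("up%d_b", d)]] <- ub$db
    dx <- ub$dx
  }
  for (b in rev(seq_len(depth + 1L))) {
    if (b <= depth) {
      pc <- caches[[sprintf("pool%d", b)]]
      dx <- cpp_maxpool_bw(pc$idx, dx, pc$h, pc$w)
      dx <- dx + dskips[[b]]
    }
    if (b == 1L && cfg$use_ram) {
      rp <- list(Wc = p$ram_Wc, bc = p$ram_bc, Wg = p$ram_Wg, bg = p$ram_bg,
                 Wd = p$ram_Wd, bd = p$ram_bd)
      rb <- ram_bw(caches$ram, rp, dx)
      g$ram_Wc <- rb$dWc; g$ram_bc <- rb$dbc
      g$ram_Wg <- rb$dWg; g$ram_bg <- rb$dbg
      g$ram_Wd <- rb$dWd; g$ram_bd <- rb$dbd
      dx <- rb$dx
    }
    if (cfg$use_se) {
      site <- if (b <= depth) sprintf("se_enc%d", b) else "se_bott"
      sb <- se_bw(caches[[site]], p[[paste0(site, "_W1")]],
                  p[[paste0(site, "_W2")]], dx)
      g[[paste0(site, "_W1")]] <- sb$dW1; g[[paste0(site, "_W2")]] <- sb$dW2
      dx <- sb$dx
    }
    for (i in rev(seq_len(cfg$enc_convs[b]))) {
      nm <- sprintf("enc%d_conv%d", b, i)
      cb <- conv_relu_bw(caches[[nm]], p[[paste0(nm, "_W")]], 3L, dx)
      g[[paste0(nm, "_W")]] <- cb$dW; g[[paste0(nm, "_b")]] <- cb$db
      dx <- cb$dx
    }
  }
  g
}

# cross-entropy loss and logit gradient for one image
ce_loss_grad <- function(probs_full, mask_full) {
  d <- dim(probs_full)
  npix <- d[1] * d[2]
  idx <- cbind(as.vector(row(mask_full)), as.vector(col(mask_full)),
               as.vector(mask_full) + 1L)
  pt <- pmax(probs_full[idx], 1e-12)
  loss <- -mean(log(pt))
  dlogits <- probs_full
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / npix)
}

#' Train the network
#'
#' Adam with pixel-wise cross-entropy, cosine learning-rate decay and the
#' two-phase freeze/unfreeze schedule: for the first `freeze_epochs` the
#' encoder (backbone) convolution weights are frozen and only the
#' attention modules, decoder and head are updated; afterwards all
#' parameters train. Deterministic given `tc$seed`.
#'
#' @param net a `unet` from [build_unet()].
#' @param images list of (h, w, in_channels) arrays in \[0, 1\].
#' @param masks list of integer label matrices (0-based classes), same
#'   sizes as the images.
#' @param tc a [train_config()].
#' @param verbose print the per-epoch loss.
#' @return the trained `unet`, with `loss_history` (numeric, one mean
#'   loss per epoch) attached.
#' @export
train_unet <- function(net, images, masks, tc = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(net, "unet"), inherits(tc, "train_config"))
  if (length(images) == 0L) stop("empty dataset")
  if (length(images) != length(masks)) stop("images/masks length mismatch")
  for (i in seq_along(masks)) {
    if (max(masks[[i]]) >= net$cfg$num_classes)
      stop("mask label exceeds num_classes - 1")
    if (!all(dim(images[[i]])[1:2] == dim(masks[[i]])))
      stop("image/mask size mismatch")
  }
  enc_names <- grep("^enc", names(net$params), value = TRUE)
  m1 <- lapply(net$params, function(w) w * 0)
  m2 <- m1
  step <- 0L
  history <- numeric(tc$epochs)
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      lr <- tc$lr0 * 0.5 * (1 + cos(pi * (ep - 1L) / tc$epochs))
      frozen <- ep <= tc$freeze_epochs
      ord <- sample(length(images))
      ep_loss <- 0
      nb <- 0L
      for (bs in split(ord, ceiling(seq_along(ord) / tc$batch_size))) {
        grads <- NULL
        bloss <- 0
        for (ii in bs) {
          fwd <- unet_forward(net, images[[ii]], want_cache = TRUE)
          mask_full <- pad_mask(masks[[ii]], dim(fwd$probs_full)[1:2])
          lg <- ce_loss_grad(fwd$probs_full, mask_full)
          bloss <- bloss + lg$loss
          g <- unet_backward(net, fwd, lg$dlogits)
          grads <- if (is.null(grads)) g else
            mapply(function(a, b) a + b, grads, g[names(grads)],
                   SIMPLIFY = FALSE)
        }
        nbi <- length(bs)
        step <- step + 1L
        for (nm in names(grads)) {
          if (frozen && nm %in% enc_names) next
          gr <- grads[[nm]] / nbi
          m1[[nm]] <- 0.9 * m1[[nm]] + 0.1 * gr
          m2[[nm]] <- 0.999 * m2[[nm]] + 0.001 * gr * gr
          mhat <- m1[[nm]] / (1 - 0.9^step)
          vhat <- m2[[nm]] / (1 - 0.999^step)
          net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
        ep_loss <- ep_loss + bloss / nbi
        nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d loss %.4f lr %.2e",
                                   ep, tc$epochs, history[ep], lr))
    }
  })
  net$loss_history <- history
  net
}

# pad a label mask (with background) to the padded forward size
pad_mask <- function(mask, hw) {
  if (all(dim(mask) == hw)) return(mask)
  out <- matrix(0L, hw[1], hw[2])
  out[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  out
}

#' Segment an image (or a list of images)
#'
#' Runs the forward pass and takes the per-pixel argmax over classes.
#'
#' @param net a `unet`.
#' @param image (h, w, in_channels) array, or a list of them.
#' @return integer class-label matrix (0-based), or a list of matrices in
#'   input order.
#' @export
predict_mask <- function(net, image) {
  if (is.list(image)) return(lapply(image, function(im) predict_mask(net, im)))
  pr <- unet_forward(net, image)$probs
  d <- dim(pr)
  matrix(max.col(matrix(pr, d[1] * d[2], d[3])) - 1L, d[1], d[2])
}

#' Pixel accuracy between two label masks
#' @param pred,truth integer label matrices of equal size.
#' @return fraction of matching pixels.
#' @export
pixel_accuracy <- function(pred, truth) mean(pred == truth)
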