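# Layer primitives for the segmentation network. Each *_fw returns the
# output plus whatever the matching *_bw needs; backward passes return the
# input gradient and parameter gradients. Feature maps are (h, w, c)
# arrays; conv weights are (k*k*cin) x cout matrices flattened
# column-major from (k, k, cin, cout).

sigmoid <- function(x) 1 / (1 + exp(-x))

conv_relu_fw <- function(x, W, b, k) {
  pre <- cpp_conv_fw(x, W, b, k)
  list(y = pre * (pre > 0), x = x, pre = pre)
}

conv_relu_bw <- function(cache, W, k, dy) {
  dpre <- dy * (cache$pre > 0)
  cpp_conv_bw(cache$x, W, dpre, k)
}

#' Squeeze step of the SE module
#'
#' Compresses each channel of a feature map to a scalar by global average
#' pooling: z_m = mean over all spatial positions of channel m.
#'
#' @param u numeric (h, w, c) array.
#' @return numeric vector of length c.
#' @export
se_squeeze <- function(u) {
  d <- dim(u)
  if (length(d) != 3L || any(d < 1L)) stop("feature map must be h x w x c")
  if (!all(is.finite(u))) stop("feature map must be finite")
  colMeans(matrix(u, d[1] * d[2], d[3]))
}

#' Excitation step of the SE module
#'
#' s = Sigmoid(w2 %*% ReLU(w1 %*% z)): a two-layer bottleneck over the
#' squeezed channel vector, yielding one gate in (0, 1) per channel.
#'
#' @param z squeezed channel vector (length c).
#' @param w1 (c / r) x c matrix; `w2` c x (c / r) matrix.
#' @param w2 see `w1`.
#' @return gate vector s in (0, 1)^c.
#' @export
se_excite <- function(z, w1, w2) {
  if (ncol(w1) != length(z) || ncol(w2) != nrow(w1) || nrow(w2) != length(z))
    stop("SE weight shapes inconsistent with channel count")
  as.vector(sigmoid(w2 %*% pmax(w1 %*% z, 0)))
}

#' Channel rescaling step of the SE module
#'
#' Multiplies channel m of the feature map by gate s_m.
#'
#' @param u numeric (h, w, c) array.
#' @param s gate vector of length c.
#' @return rescaled array, same shape as `u`.
#' @export
se_scale <- function(u, s) {
  d <- dim(u)
  if (length(d) != 3L) stop("feature map must be h x w x c")
  if (length(s) != d[3]) stop("gate length must equal channel count")
  array(matrix(u, d[1] * d[2], d[3]) *
          matrix(s, d[1] * d[2], d[3], byrow = TRUE), d)
}

se_fw <- function(x, W1, W2, identity = FALSE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3])
  z <- colMeans(xm)
  a1 <- as.vector(W1 %*% z)
  h1 <- pmax(a1, 0)
  s <- as.vector(sigmoid(W2 %*% h1))
  if (identity) s <- rep(1, d[3])
  y <- array(xm * matrix(s, hw, d[3], byrow = TRUE), d)
  list(y = y, xm = xm, z = z, a1 = a1, h1 = h1, s = s, d = d)
}

se_bw <- function(cache, W1, W2, dy) {
  d <- cache$d
  hw <- d[1] * d[2]
  dym <- matrix(dy, hw, d[3])
  ds <- colSums(dym * cache$xm)
  dxm <- dym * matrix(cache$s, hw, d[3], byrow = TRUE)
  da2 <- ds * cache$s * (1 - cache$s)
  dW2 <- da2 %o% cache$h1
  dh1 <- as.vector(t(W2) %*% da2)
  da1 <- dh1 * (cache$a1 > 0)
  dW1 <- da1 %o% cache$z
  dz <- as.vector(t(W1) %*% da1)
  dxm <- dxm + matrix(dz / hw, hw, d[3], byrow = TRUE)
  list(dx = array(dxm, d), dW1 = dW1, dW2 = dW2)
}

# Residual attention module. f = ReLU(Conv(x)); channel attention is the
# per-channel population variance of f over spatial positions; spatial
# attention is a depthwise 3x3 convolution of f; the fused map is
# sigmoid-gated and multiplies a second convolution of f; the input is
# added back (residual). With all weights and biases zero the module is
# exactly the identity.
ram_fw <- function(x, p, k = 3L) {
  d <- dim(x)
  hw <- d[1] * d[2]
  f_pre <- cpp_conv_fw(x, p$Wc, p$bc, k)
  f <- f_pre * (f_pre > 0)
  g <- cpp_conv_fw(f, p$Wg, p$bg, k)
  fm <- matrix(f, hw, d[3])
  mu <- colMeans(fm)
  va <- colMeans(fm * fm) - mu^2
  sa <- cpp_dwconv_fw(f, p$Wd, p$bd)
  pre <- sa + array(matrix(va, hw, d[3], byrow = TRUE), d)
  A <- sigmoid(pre)
  list(y = x + A * g, x = x, f_pre = f_pre, f = f, g = g, A = A,
       mu = mu, d = d, k = k)
}

ram_bw <- function(cache, p, dy) {
  d <- cache$d
  hw <- d[1] * d[2]
  dx <- dy
  dA <- dy * cache$g
  dg <- dy * cache$A
  dpre <- dA * cache$A * (1 - cache$A)
  dva <- colSums(matrix(dpre, hw, d[3]))
  bd1 <- cpp_dwconv_bw(cache$f, p$Wd, dpre)
  bg1 <- cpp_conv_bw(cache$f, p$Wg, dg, cache$k)
  mu_b <- array(matrix(cache$mu, hw, d[3], byrow = TRUE), d)
  dva_b <- array(matrix(dva, hw, d[3], byrow = TRUE), d)
  df <- bd1$dx + bg1$dx + dva_b * (2 / hw) * (cache$f - mu_b)
  dfpre <- df * (cache$f_pre > 0)
  bc1 <- cpp_conv_bw(cache$x, p$Wc, dfpre, cache$k)
  list(dx = dx + bc1$dx, dWc = bc1$dW, dbc = bc1$db,
       dWg = bg1$dW, dbg = bg1$db, dWd = bd1$dW, dbd = bd1$db)
}

#' Residual attention module forward pass
#'
#' Parallel channel attention (per-channel variance pooling) and spatial
#' attention (depthwise 3x3 convolution) over ReLU(Conv(x)), fused by
#' broadcast addition, sigmoid-gated, multiplied with a second convolution
#' of the same features, and added back to the input. With all module
#' weights zero the output equals the input exactly.
#'
#' @param x numeric (h, w, c) array, finite.
#' @param params list with `Wc`, `bc` (first conv), `Wg`, `bg` (second
#'   conv), `Wd`, `bd` (depthwise). Defaults to zero weights (identity).
#' @return array of the same shape as `x`.
#' @export
ram_forward <- function(x, params = NULL) {
  if (!all(is.finite(x))) stop("input must be finite")
  d <- dim(x)
  if (length(d) != 3L) stop("input must be h x w x c")
  if (is.null(params)) params <- ram_init(d[3], k = 3L, zero = TRUE)
  ram_fw(x, params)$y
}

ram_init <- function(c, k = 3L, zero = FALSE) {
  rn <- function(n, fan) if (zero) rep(0, n) else
    stats::rnorm(n, 0, sqrt(2 / fan))
  list(Wc = matrix(rn(k * k * c * c, k * k * c), k * k * c, c),
       bc = rep(0, c),
       Wg = matrix(rn(k * k * c * c, k * k * c), k * k * c, c),
       bg = rep(0, c),
       Wd = array(rn(k * k * c, k * k), c(k, k, c)),
       bd = rep(0, c))
}

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1] * d[2], d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}
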