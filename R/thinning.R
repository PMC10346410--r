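#' Count foreground neighbors in a 3x3 window
#'
#' The 8 neighbors of the center pixel P1 are enumerated clockwise starting
#' from the pixel directly above: P2 = north, P3 = NE, ..., P9 = NW. The
#' neighbor count N(P1) is the number of those neighbors equal to 1.
#'
#' @param wdw integer vector of length 8 (P2..P9) with values in \{0, 1\},
#'   or a 3x3 matrix whose center is P1.
#' @return integer in \[0, 8\].
#' @seealso [transition_count()], [zhang_suen_thin()]
#' @export
neighbor_count <- function(wdw) {
  p <- as_window(wdw)
  sum(p)
}

#' Count 0-to-1 transitions around a 3x3 window
#'
#' S(P1) is the number of 0 -> 1 transitions in the cyclic neighbor sequence
#' P2, P3, ..., P9, P2.
#'
#' @inheritParams neighbor_count
#' @return integer in \[0, 4\].
#' @export
transition_count <- function(wdw) {
  p <- as_window(wdw)
  nxt <- p[c(2:8, 1)]
  sum(p == 0L & nxt == 1L)
}

# Accept either the P2..P9 vector or a full 3x3 window matrix.
as_window <- function(wdw) {
  if (is.matrix(wdw)) {
    stopifnot(nrow(wdw) == 3L, ncol(wdw) == 3L)
    # clockwise from north: N, NE, E, SE, S, SW, W, NW
    wdw <- c(wdw[1, 2], wdw[1, 3], wdw[2, 3], wdw[3, 3],
             wdw[3, 2], wdw[3, 1], wdw[2, 1], wdw[1, 1])
  }
  p <- as.integer(wdw)
  if (length(p) != 8L || anyNA(p) || !all(p %in% c(0L, 1L)))
    stop("window must be 8 binary values (P2..P9)")
  p
}

#' Zhang-Suen skeleton thinning
#'
#' Two-subiteration parallel thinning of a binary mask. In each round,
#' sub-iteration 1 deletes every foreground pixel with 2 <= N(P1) <= 6,
#' S(P1) = 1, P2*P4*P6 = 0 and P4*P6*P8 = 0; sub-iteration 2 uses the same
#' neighbor/transition conditions with P2*P4*P8 = 0 and P2*P6*P8 = 0.
#' Deletion within a sub-iteration is simultaneous (mark, then delete).
#' Rounds repeat until nothing is deleted; the result is the one-pixel-wide
#' skeleton. Pixels outside the image count as background.
#'
#' @param mask numeric or integer matrix with values in \{0, 1\};
#'   foreground = 1.
#' @return integer matrix of the same dimensions, a subset of the input
#'   foreground.
#' @examples
#' m <- matrix(0L, 9, 24); m[3:7, 3:22] <- 1L
#' sum(zhang_suen_thin(m))
#' @export
zhang_suen_thin <- function(mask) {
  m <- as_binary_mask(mask)
  cpp_zhang_suen(m)
}

as_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- mask
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("mask must be strictly binary (0/1)")
  m
}
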