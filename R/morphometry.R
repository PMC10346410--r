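#' Split a class mask into per-instance binary masks
#'
#' Each non-background class (1 = trunk, 2 = branch) is binarized and
#' decomposed into 8-connected components. Components smaller than
#' `min_area` pixels are discarded as segmentation fragments; survivors are
#' re-labeled with sequential instance ids ordered by (class, top-left
#' pixel in raster order). Overlapping branches that merge into one
#' component are kept as a single instance.
#'
#' @param cm integer matrix of class labels (0 = background, 1 = trunk,
#'   2 = branch).
#' @param min_area minimum component area in pixels (default 50).
#' @return list of `instance_mask` objects, each with fields `mask`
#'   (binary matrix), `class_label` ("trunk"/"branch"), `class_id`,
#'   `area`, `instance_id`.
#' @export
split_instances <- function(cm, min_area = 50L) {
  cm <- as_class_mask(cm)
  out <- list()
  id <- 0L
  for (cls in c(1L, 2L)) {
    bin <- matrix(as.integer(cm == cls), nrow(cm), ncol(cm))
    if (!any(bin == 1L)) next
    lab <- cpp_label8(bin)
    areas <- tabulate(lab[lab > 0L])
    for (k in seq_along(areas)) {
      if (areas[k] < min_area) next
      id <- id + 1L
      out[[id]] <- structure(
        list(mask = matrix(as.integer(lab == k), nrow(cm), ncol(cm)),
             class_label = if (cls == 1L) "trunk" else "branch",
             class_id = cls,
             area = areas[k],
             instance_id = id),
        class = "instance_mask")
    }
  }
  out
}

as_class_mask <- function(cm) {
  if (!is.matrix(cm)) stop("class mask must be a matrix")
  storage.mode(cm) <- "integer"
  if (anyNA(cm) || any(cm < 0L)) stop("class mask labels must be >= 0")
  cm
}

#' Branch (or trunk) length as skeleton pixel count
#'
#' The instance mask is thinned with [zhang_suen_thin()] and the number of
#' remaining foreground pixels is the length in pixels.
#'
#' @param inst an `instance_mask` from [split_instances()], or a binary
#'   matrix.
#' @return integer pixel count (>= 1).
#' @export
branch_length <- function(inst) {
  m <- if (inherits(inst, "instance_mask")) inst$mask else as_binary_mask(inst)
  if (!any(m == 1L)) stop("empty instance mask")
  sum(zhang_suen_thin(m))
}

#' Total-least-squares line fit to a skeleton
#'
#' Fits the line through the centroid along the principal axis of the
#' skeleton pixel coordinates, minimizing the sum of squared orthogonal
#' (Euclidean) distances from the pixels to the line. Coordinates use the
#' image convention (row increases downward); the reported slope is in
#' mathematical y-up coordinates. The direction sign is normalized so
#' d_col >= 0, and d_row <= 0 when d_col = 0.
#'
#' @param skel binary matrix (a skeleton), or a two-column matrix of
#'   (row, col) pixel coordinates.
#' @return object of class `line_fit` with fields `centroid` (row, col),
#'   `direction` (unit vector, d_row, d_col), `slope` (y-up; `Inf` when
#'   vertical), `vertical` and `degenerate` flags, `n` points.
#' @export
fit_line <- function(skel) {
  pts <- if (is.matrix(skel) && ncol(skel) == 2L && !all(skel %in% c(0, 1)))
    skel else which(as_binary_mask(skel) == 1L, arr.ind = TRUE)
  if (nrow(pts) < 2L) stop("line fit needs at least 2 pixels")
  # mathematical coordinates: x = col, y = -row (y up)
  x <- pts[, 2]
  y <- -pts[, 1]
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2)
  syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (abs(sxy) < 1e-12 && abs(sxx - syy) < 1e-12) {
    return(structure(list(centroid = c(row = -my, col = mx),
                          direction = c(d_row = NA_real_, d_col = NA_real_),
                          slope = NA_real_, vertical = FALSE,
                          degenerate = TRUE, n = nrow(pts)),
                     class = "line_fit"))
  }
  # principal axis of the 2x2 scatter matrix, closed form
  theta <- 0.5 * atan2(2 * sxy, sxx - syy)
  dx <- cos(theta); dy <- sin(theta)
  if (dx < 0 || (abs(dx) < 1e-9 && dy < 0)) { dx <- -dx; dy <- -dy }
  vertical <- abs(dx) < 1e-9
  slope <- if (vertical) Inf else dy / dx
  structure(list(centroid = c(row = -my, col = mx),
                 direction = c(d_row = -dy, d_col = dx),
                 slope = slope, vertical = vertical,
                 degenerate = FALSE, n = nrow(pts)),
            class = "line_fit")
}

#' Inclination angle of a fitted line
#'
#' Angle of the fitted axis relative to the horizontal image axis, measured
#' with y upward (image rows flipped), mapped into \[0, 180) degrees via the
#' inverse tangent. A horizontal line is 0, a vertical line 90; values
#' above 90 lean "down-right"/"up-left".
#'
#' @param fit a `line_fit` from [fit_line()].
#' @return angle in degrees in \[0, 180).
#' @export
inclination <- function(fit) {
  stopifnot(inherits(fit, "line_fit"))
  if (isTRUE(fit$degenerate)) stop("degenerate fit: no unique axis")
  if (fit$vertical) return(90)
  theta <- atan2(-fit$direction[["d_row"]], fit$direction[["d_col"]]) * 180 / pi
  if (theta < 0) theta <- theta + 180
  if (theta >= 180) theta <- theta - 180
  theta
}

#' Measure all trunk/branch instances in a class mask
#'
#' The full morphometry pipeline: instance separation with contour-area
#' filtering, per-instance skeleton thinning, skeleton pixel counting
#' (length), total-least-squares line fit and inclination angle. Instances
#' whose skeleton is too small or isotropic for a line fit are returned as
#' flagged records with `NA` inclination rather than aborting the run.
#'
#' @inheritParams split_instances
#' @return data.frame with columns `instance_id`, `class`, `area`,
#'   `length_px`, `inclination_deg`, `flagged`, ordered by (class,
#'   top-left pixel).
#' @examples
#' cm <- matrix(0L, 40, 40)
#' cm[5:35, 18:23] <- 1L          # vertical trunk
#' cm[10:13, 24:39] <- 2L         # horizontal branch
#' measure_all(cm, min_area = 20)
#' @export
measure_all <- function(cm, min_area = 50L) {
  inst <- split_instances(cm, min_area)
  rows <- lapply(inst, function(it) {
    skel <- zhang_suen_thin(it$mask)
    len <- sum(skel)
    ang <- NA_real_
    flagged <- TRUE
    if (len >= 2L) {
      fit <- fit_line(skel)
      if (!fit$degenerate) {
        ang <- inclination(fit)
        flagged <- FALSE
      }
    }
    data.frame(instance_id = it$instance_id, class = it$class_label,
               area = it$area, length_px = len, inclination_deg = ang,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(instance_id = integer(), class = character(),
                      area = integer(), length_px = integer(),
                      inclination_deg = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
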