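# PNG/CSV/JSON I/O. Class masks are stored as 8-bit grayscale PNG whose
# integer gray level IS the class id (0 = background, 1 = trunk,
# 2 = branch); they are read back by level, never by color. A display
# palette is a rendering concern, not part of the format.

#' Read an RGB image
#' @param path PNG file.
#' @return h x w x 3 array in \[0, 1\].
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image
#' @param img h x w x 3 array in \[0, 1\].
#' @param path output PNG file.
#' @export
write_image <- function(img, path) {
  img[img < 0] <- 0; img[img > 1] <- 1
  png::writePNG(img, path)
}

#' Read a class mask (gray level = class id)
#' @param path PNG file.
#' @return integer matrix of class labels.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  out
}

#' Write a class mask (gray level = class id)
#' @param mask integer matrix of class labels (0..255).
#' @param path output PNG file.
#' @export
write_mask <- function(mask, path) {
  stopifnot(max(mask) <= 255L, min(mask) >= 0L)
  png::writePNG(mask / 255, path)
}

#' Write a measurement table as CSV
#'
#' Emits the columns `instance_id,class,length_px,inclination_deg`.
#' @param df data.frame from [measure_all()].
#' @param path output CSV file.
#' @export
write_measurements <- function(df, path) {
  utils::write.csv(df[, c("instance_id", "class", "length_px",
                          "inclination_deg")],
                   path, row.names = FALSE)
}

#' Save network weights with a JSON config sidecar
#'
#' Weights go to `path` (RDS); the architecture config goes to
#' `<path>.json` so a checkpoint is self-describing.
#' @param net a network from [build_unet()].
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net$params, path)
  jsonlite::write_json(net$cfg[setdiff(names(net$cfg), "depth")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file.
#' @return a network usable with [predict_mask()].
#' @export
load_checkpoint <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  net <- do.call(unet_config, cfg)
  net <- build_unet(net, seed = 0L)
  net$params <- readRDS(path)
  net
}
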