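#' @keywords internal
#' TIFF storage is [0,1]-normalised; images are scaled affinely and the
#' gain/offset recorded in a YAML sidecar so readers can invert exactly.
#' ΔF/F is invariant to the scaling, so analysis results do not depend on it.
scale01 <- function(x) {
  off <- min(x)
  gain <- max(x) - off
  if (gain <= 0) gain <- 1
  list(data = (x - off) / gain, offset = off, gain = gain)
}

#' Write a single-frame image as TIFF with a scaling sidecar entry
#' @keywords internal
write_image_tiff <- function(img, path) {
  s <- scale01(img)
  tiff::writeTIFF(s$data, path, bits.per.sample = 32L)
  list(offset = s$offset, gain = s$gain)
}

#' Write a movie as multi-page TIFF with one global scaling
#' @keywords internal
write_movie_tiff <- function(movie, path) {
  s <- scale01(movie)
  pages <- lapply(seq_len(dim(movie)[3]), function(k) s$data[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  list(offset = s$offset, gain = s$gain)
}

#' Read an image written by [write_image_tiff()]
#' @param path TIFF path.
#' @param scale list with `offset` and `gain` (from the sidecar); identity
#'   when NULL.
#' @return numeric matrix in original units.
#' @export
read_image_tiff <- function(path, scale = NULL) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (!is.null(scale)) img <- img * scale$gain + scale$offset
  img
}

#' Read a movie written by [write_movie_tiff()]
#' @inheritParams read_image_tiff
#' @return ny x nx x nframes array in original units.
#' @export
read_movie_tiff <- function(path, scale = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , k] <- p
  }
  if (!is.null(scale)) arr <- arr * scale$gain + scale$offset
  arr
}

#' Read an integer label mask written by [write_population()]
#' @param path TIFF path.
#' @param n_labels maximum label value stored.
#' @return integer matrix of labels (0 = background).
#' @export
read_mask_tiff <- function(path, n_labels) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * n_labels)), nrow(img), ncol(img))
}

#' Write a simulated population to disk as pipeline input files
#'
#' Writes the structural TIFF, functional multi-page TIFF, labeled territory
#' mask TIFF, soma-seed CSV, ground-truth CSV (one row per domain and per
#' soma), a config echo and an `images.yaml` sidecar holding the affine
#' scaling of each TIFF (TIFF storage is [0,1]-normalised).
#'
#' @param pop a [simulate_population()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of written file paths.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  n_lab <- max(pop$territory_mask)
  if (n_lab > 254) stop("more than 254 territories cannot be stored as 8-bit labels")
  sc_struct <- write_image_tiff(pop$structural, f("structural.tif"))
  sc_mov <- write_movie_tiff(pop$movie, f("functional.tif"))
  tiff::writeTIFF(pop$territory_mask / n_lab, f("territory_mask.tif"),
                  bits.per.sample = 16L)
  write.csv(pop$soma_seeds, f("soma_seeds.csv"), row.names = FALSE)
  gt <- pop$ground_truth
  gt_rows <- rbind(
    data.frame(astrocyte_id = gt$astro$astrocyte_id, roi_type = "soma",
               roi_id = "soma", active = gt$astro$soma_active,
               onset_s = gt$astro$soma_onset_s,
               radius_um = 0, phase = NA_character_),
    data.frame(astrocyte_id = gt$domains$astrocyte_id, roi_type = "domain",
               roi_id = gt$domains$domain_id, active = gt$domains$active,
               onset_s = gt$domains$onset_s,
               radius_um = gt$domains$radius_um, phase = gt$domains$phase))
  write.csv(gt_rows, f("ground_truth.csv"), row.names = FALSE)
  cfg <- pop$config
  cfg_echo <- cfg[setdiff(names(cfg), "p_domain")]
  cfg_echo$p_domain <- paste(deparse(cfg$p_domain), collapse = " ")
  yaml::write_yaml(cfg_echo, f("config.yaml"))
  yaml::write_yaml(list(structural = sc_struct, functional = sc_mov,
                        territory_mask = list(n_labels = n_lab)),
                   f("images.yaml"))
  invisible(list(structural = f("structural.tif"),
                 functional = f("functional.tif"),
                 territory_mask = f("territory_mask.tif"),
                 soma_seeds = f("soma_seeds.csv"),
                 ground_truth = f("ground_truth.csv"),
                 config = f("config.yaml"),
                 images = f("images.yaml")))
}
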