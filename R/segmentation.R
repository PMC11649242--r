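#' Polar transform of an astrocyte territory around its soma seed
#'
#' Computes, for every pixel of the territory mask, the radius and angle
#' relative to the soma seed: `r = sqrt((x - x_soma)^2 + (y - y_soma)^2)`
#' (in pixels) and `theta = atan2(y - y_soma, x - x_soma)` (radians in
#' (-pi, pi]). Pixel coordinates are 0-based, x rightward, y downward.
#'
#' @param mask logical matrix (rows = y, cols = x), `TRUE` inside the
#'   territory. Must be a single connected component.
#' @param seed_x_px,seed_y_px 0-based soma-seed pixel coordinates; must lie
#'   inside the mask.
#' @param pixel_size_um pixel size (µm/px).
#' @param check_connected verify the mask is one 4-connected component
#'   reachable from the seed (default `TRUE`).
#' @return An object of class `radial_frame`: list with `r_px` and `theta`
#'   matrices (`NA` outside the mask), plus the mask, seed and pixel size.
#' @export
polar_transform <- function(mask, seed_x_px, seed_y_px, pixel_size_um,
                            check_connected = TRUE) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size_um > 0)
  sx <- as.integer(seed_x_px); sy <- as.integer(seed_y_px)
  if (sx < 0 || sy < 0 || sx >= ncol(mask) || sy >= nrow(mask) ||
      !mask[sy + 1L, sx + 1L])
    stop("soma seed must lie inside the territory mask")
  if (check_connected && !mask_connected(mask, sx, sy))
    stop("territory mask is not a single connected component around the seed")
  xs <- matrix(rep(0:(ncol(mask) - 1L), each = nrow(mask)), nrow(mask))
  ys <- matrix(rep(0:(nrow(mask) - 1L), ncol(mask)), nrow(mask))
  r <- sqrt((xs - sx)^2 + (ys - sy)^2)
  th <- atan2(ys - sy, xs - sx)
  r[!mask] <- NA_real_
  th[!mask] <- NA_real_
  structure(list(r_px = r, theta = th, mask = mask,
                 seed_x_px = sx, seed_y_px = sy,
                 pixel_size_um = pixel_size_um),
            class = "radial_frame")
}

#' @keywords internal
#' TRUE when every mask pixel is 4-connected to the seed (vectorised
#' iterative dilation).
mask_connected <- function(mask, sx, sy) {
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[sy + 1L, sx + 1L] <- TRUE
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(reach), ] <- grown[-nrow(reach), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(reach)] <- grown[, -ncol(reach)] | reach[, -1]
    grown <- grown & mask
    if (identical(grown, reach)) break
    reach <- grown
  }
  all(reach[mask])
}

#' Radial fluorescence profile by ring averaging
#'
#' Partitions the territory pixels into concentric rings of fixed width
#' around the soma seed and averages fluorescence over the angle within each
#' ring: ring `j` covers radii `[(j-1)*w, j*w)` and is reported at its inner
#' radius. Rings containing no pixels are kept but flagged (`NA` statistics),
#' never treated as zero.
#'
#' @param image numeric matrix, same dimensions as the mask.
#' @param frame a [polar_transform()] result.
#' @param ring_width_px ring width in pixels (>= 1).
#' @return data.frame with `ring`, `r_inner_px`, `n_pixels`, `mean`,
#'   `median`, `sd`.
#' @export
ring_profile <- function(image, frame, ring_width_px = 1) {
  stopifnot(inherits(frame, "radial_frame"), ring_width_px >= 1,
            all(dim(image) == dim(frame$r_px)))
  r <- frame$r_px[frame$mask]
  v <- image[frame$mask]
  j <- floor(r / ring_width_px) + 1L
  nr <- max(j)
  out <- data.frame(ring = seq_len(nr),
                    r_inner_px = (seq_len(nr) - 1) * ring_width_px,
                    n_pixels = 0L, mean = NA_real_, median = NA_real_,
                    sd = NA_real_)
  agg_n <- tabulate(j, nr)
  out$n_pixels <- agg_n
  has <- which(agg_n > 0L)
  out$mean[has] <- vapply(split(v, j), mean, numeric(1))[as.character(has)]
  out$median[has] <- vapply(split(v, j), median, numeric(1))[as.character(has)]
  sds <- vapply(split(v, j), function(z) if (length(z) > 1) sd(z) else NA_real_,
                numeric(1))
  out$sd[has] <- sds[as.character(has)]
  out
}

#' Locate the soma from a radial fluorescence profile
#'
#' Scanning outward from the centre, the soma radius is the (inner) radius of
#' the first ring whose mean fluorescence falls below 50% of the centre
#' ring's fluorescence. Profiles that never cross half-max are a segmentation
#' failure for that cell (reported, not guessed).
#'
#' @param profile a [ring_profile()] data.frame (>= 2 rings, positive centre
#'   fluorescence).
#' @param frame optional [polar_transform()] result; when supplied, the soma
#'   pixel mask (`r < r_soma`) is returned as well.
#' @return list with `ok`, and on success `r_soma_px`, `ring` (index of the
#'   crossing ring) and optionally `mask`; on failure `reason`.
#' @export
find_soma <- function(profile, frame = NULL) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 2)
  f1 <- profile$mean[1]
  if (!is.finite(f1) || f1 <= 0)
    return(list(ok = FALSE, reason = "centre ring fluorescence not positive"))
  below <- which(!is.na(profile$mean) & profile$mean < 0.5 * f1 &
                   profile$ring > 1L)
  if (!length(below))
    return(list(ok = FALSE, reason = "profile never falls below half-max"))
  j <- min(below)
  r_soma <- profile$r_inner_px[j]
  out <- list(ok = TRUE, r_soma_px = r_soma, ring = j)
  if (!is.null(frame)) {
    m <- frame$mask & !is.na(frame$r_px) & frame$r_px < r_soma
    m[is.na(m)] <- FALSE
    out$mask <- m
  }
  out
}

#' Arborization mask from per-ring fluorescence statistics
#'
#' A pixel belongs to the arborization when it lies inside the territory,
#' outside the soma, and its fluorescence is at least the median plus 0.25
#' standard deviations of its own ring (the SR101-positive criterion).
#' Single-pixel rings have no spread; their pixel is compared to the ring
#' median alone.
#'
#' @param image numeric matrix.
#' @param frame a [polar_transform()] result.
#' @param profile the matching [ring_profile()].
#' @param soma_mask logical matrix of soma pixels (excluded).
#' @param ring_width_px ring width used for `profile`.
#' @param k multiplier on the ring SD (default 0.25).
#' @return logical matrix; attribute `empty` is `TRUE` when no pixel
#'   qualifies (cell should be excluded from threshold analysis).
#' @export
find_arborization <- function(image, frame, profile, soma_mask,
                              ring_width_px = 1, k = 0.25) {
  stopifnot(inherits(frame, "radial_frame"))
  j <- floor(frame$r_px / ring_width_px) + 1L
  med <- profile$median[j]
  sdv <- profile$sd[j]
  sdv[is.na(sdv)] <- 0
  thr <- matrix(med + k * sdv, nrow(image), ncol(image))
  arb <- frame$mask & !soma_mask & !is.na(frame$r_px) & image >= thr
  arb[is.na(arb)] <- FALSE
  attr(arb, "empty") <- !any(arb)
  arb
}

#' Tile the arborization into a grid of square domains
#'
#' Lays a square grid of side `floor(domain_size_um / pixel_size_um)` pixels
#' over the territory bounding box, anchored at its top-left corner, and
#' clips every cell to the arborization pixels. Cells retaining fewer than
#' `min_pixels` pixels are discarded (a domain trace needs more than a
#' handful of pixels to be meaningful).
#'
#' @param arb_mask logical arborization mask.
#' @param territory_mask logical territory mask (defines the grid anchor).
#' @param pixel_size_um pixel size (µm/px).
#' @param domain_size_um maximal domain side (µm), default 4.3.
#' @param min_pixels minimum retained pixels per domain (default 4).
#' @return list with `catalog` (data.frame: domain_id, gx, gy,
#'   centroid_x_um, centroid_y_um, area_px, radius handled by caller) and
#'   `label` (integer matrix; 0 outside domains, k for the k-th catalog row).
#' @export
grid_domains <- function(arb_mask, territory_mask, pixel_size_um,
                         domain_size_um = 4.3, min_pixels = 4L) {
  stopifnot(is.matrix(arb_mask), is.matrix(territory_mask),
            all(dim(arb_mask) == dim(territory_mask)))
  if (!any(arb_mask)) stop("arborization mask is empty")
  side <- max(1L, floor(domain_size_um / pixel_size_um))
  idx_t <- which(territory_mask, arr.ind = TRUE)
  x0 <- min(idx_t[, 2]) - 1L      # 0-based anchor at mask bounding box
  y0 <- min(idx_t[, 1]) - 1L
  idx <- which(arb_mask, arr.ind = TRUE)
  xp <- idx[, 2] - 1L
  yp <- idx[, 1] - 1L
  gx <- (xp - x0) %/% side
  gy <- (yp - y0) %/% side
  key <- paste(gx, gy)
  cnt <- table(key)
  ok <- names(cnt)[cnt >= min_pixels]
  label <- matrix(0L, nrow(arb_mask), ncol(arb_mask))
  if (!length(ok))
    return(list(catalog = data.frame(), label = label))
  sel <- key %in% ok
  ids <- sort(unique(key[sel]))
  kmap <- match(key[sel], ids)
  cxs <- tapply((xp[sel] + 0.5) * pixel_size_um, kmap, mean)
  cys <- tapply((yp[sel] + 0.5) * pixel_size_um, kmap, mean)
  area <- tabulate(kmap, length(ids))
  parts <- do.call(rbind, strsplit(ids, " "))
  catalog <- data.frame(
    domain_id = ids,
    gx = as.integer(parts[, 1]), gy = as.integer(parts[, 2]),
    centroid_x_um = as.numeric(cxs), centroid_y_um = as.numeric(cys),
    area_px = area, stringsAsFactors = FALSE)
  ord <- order(catalog$gy, catalog$gx)
  catalog <- catalog[ord, ]
  catalog$domain_index <- seq_len(nrow(catalog))
  rownames(catalog) <- NULL
  remap <- match(kmap, ord)
  label[cbind(yp[sel] + 1L, xp[sel] + 1L)] <- remap
  list(catalog = catalog, label = label)
}

#' Segment one astrocyte territory into soma, arborization and domains
#'
#' Runs the full structural segmentation for a single cell: polar transform
#' around the soma seed, radial ring profile, half-max soma rule,
#' median + 0.25 SD arborization rule, and domain gridding.
#'
#' @param image structural image (matrix).
#' @param mask logical territory mask.
#' @param seed_x_px,seed_y_px 0-based soma seed.
#' @param pixel_size_um pixel size (µm/px).
#' @param ring_width_px ring width (default 1).
#' @param domain_size_um domain side (µm), default 4.3.
#' @param min_pixels minimum pixels per clipped domain (default 4).
#' @return object of class `segmentation`: list with `ok`, `r_soma_px`,
#'   `r_soma_um`, `soma_mask`, `arb_mask`, `domains` (catalog with centroid
#'   radii in µm), `domain_label`, `profile`, `frame`; or `ok = FALSE` with a
#'   `reason`.
#' @export
segment_astrocyte <- function(image, mask, seed_x_px, seed_y_px,
                              pixel_size_um, ring_width_px = 1,
                              domain_size_um = 4.3, min_pixels = 4L) {
  frame <- polar_transform(mask, seed_x_px, seed_y_px, pixel_size_um)
  profile <- ring_profile(image, frame, ring_width_px)
  soma <- find_soma(profile, frame)
  if (!soma$ok)
    return(structure(list(ok = FALSE, reason = soma$reason, profile = profile),
                     class = "segmentation"))
  arb <- find_arborization(image, frame, profile, soma$mask, ring_width_px)
  if (isTRUE(attr(arb, "empty")))
    return(structure(list(ok = FALSE, reason = "empty arborization",
                          profile = profile), class = "segmentation"))
  gd <- grid_domains(arb, mask, pixel_size_um, domain_size_um, min_pixels)
  cat <- gd$catalog
  if (nrow(cat)) {
    sx_um <- (seed_x_px + 0.5) * pixel_size_um
    sy_um <- (seed_y_px + 0.5) * pixel_size_um
    cat$radius_um <- sqrt((cat$centroid_x_um - sx_um)^2 +
                            (cat$centroid_y_um - sy_um)^2)
  }
  structure(list(ok = TRUE,
                 r_soma_px = soma$r_soma_px,
                 r_soma_um = soma$r_soma_px * pixel_size_um,
                 soma_mask = soma$mask, arb_mask = arb,
                 domains = cat, domain_label = gd$label,
                 profile = profile, frame = frame),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  if (!x$ok) {
    cat("<segmentation> FAILED:", x$reason, "\n")
  } else {
    cat(sprintf("<segmentation> r_soma %.2f um, %d soma px, %d arbor px, %d domains\n",
                x$r_soma_um, sum(x$soma_mask), sum(x$arb_mask),
                nrow(x$domains)))
  }
  invisible(x)
}

#' Segment every astrocyte of a labeled field
#'
#' @param image structural image.
#' @param territory_label integer matrix of territory labels (0 background).
#' @param seeds data.frame with `astrocyte_id`, `x_px`, `y_px` (0-based).
#' @param pixel_size_um pixel size (µm/px).
#' @param ... passed to [segment_astrocyte()].
#' @return list with `cells` (named list of `segmentation` objects for
#'   successful cells) and `failures` (data.frame astrocyte_id, reason).
#' @export
segment_population <- function(image, territory_label, seeds, pixel_size_um,
                               ...) {
  cells <- list()
  fails <- data.frame(astrocyte_id = integer(), reason = character())
  for (i in seq_len(nrow(seeds))) {
    id <- seeds$astrocyte_id[i]
    mask <- territory_label == id
    if (!any(mask)) {
      fails <- rbind(fails, data.frame(astrocyte_id = id,
                                       reason = "no territory pixels"))
      next
    }
    seg <- tryCatch(
      segment_astrocyte(image, mask, seeds$x_px[i], seeds$y_px[i],
                        pixel_size_um, ...),
      error = function(e) structure(list(ok = FALSE,
                                         reason = conditionMessage(e)),
                                    class = "segmentation"))
    if (seg$ok) cells[[as.character(id)]] <- seg
    else fails <- rbind(fails, data.frame(astrocyte_id = id,
                                          reason = seg$reason))
  }
  list(cells = cells, failures = fails)
}
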