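#' @keywords internal
#' Deterministic grid placement of non-overlapping territories.
#' Fails loudly when the requested field cannot hold all territories.
place_territories <- function(config) {
  R <- config$territory_radius_um
  pitch <- 2 * R + config$territory_gap_um
  margin <- R + config$territory_gap_um / 2
  n <- config$n_astrocytes
  if (is.null(config$field_size_um)) {
    k <- ceiling(sqrt(n))
    field <- 2 * margin + (k - 1) * pitch
  } else {
    field <- config$field_size_um
    k <- floor((field - 2 * margin) / pitch) + 1
    if (k < 1 || k * k < n)
      stop(sprintf(
        "cannot place %d territories of radius %g um in a %g um field", n, R,
        field))
  }
  coords <- margin + pitch * (seq_len(k) - 1)
  grid <- expand.grid(cx_um = coords, cy_um = coords)[seq_len(n), ]
  list(field_size_um = field, centers = grid)
}

#' @keywords internal
#' All pixels (0-based x, y and centre coordinates) whose centre lies inside
#' a territory circle, plus the pixel bounding box. This is the same pixel
#' set a labeled territory mask yields, so grids anchored at (x0, y0) here
#' coincide exactly with grids anchored at the mask bounding box downstream.
territory_pixels <- function(cx_um, cy_um, R, px) {
  xa <- floor((cx_um - R) / px):(ceiling((cx_um + R) / px) - 1L)
  ya <- floor((cy_um - R) / px):(ceiling((cy_um + R) / px) - 1L)
  g <- expand.grid(y = ya, x = xa)
  xc <- (g$x + 0.5) * px
  yc <- (g$y + 0.5) * px
  r <- sqrt((xc - cx_um)^2 + (yc - cy_um)^2)
  keep <- r <= R
  d <- data.frame(x = g$x[keep], y = g$y[keep],
                  xc_um = xc[keep], yc_um = yc[keep], r_um = r[keep])
  list(pix = d, x0 = min(d$x), y0 = min(d$y))
}

#' @keywords internal
#' Domain grid for one territory, on the pixel lattice used by segmentation:
#' cells of side floor(domain_size/pixel) px anchored at the top-left of the
#' territory-mask bounding box; a cell is a domain when >= min_px of its
#' pixels lie in the annulus between the structural soma radius and the
#' territory edge.
territory_domains <- function(cx_um, cy_um, config, min_px = 4L,
                              cache = NULL) {
  px <- config$pixel_size_um
  # the grid only depends on the territory centre through its sub-pixel
  # phase, so identical-radius territories can share one computed grid
  key <- NULL
  if (!is.null(cache)) {
    key <- sprintf("%.9f_%.9f", cx_um %% px, cy_um %% px)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      out <- hit$rel
      out$centroid_x_um <- out$centroid_x_um + (cx_um - hit$cx)
      out$centroid_y_um <- out$centroid_y_um + (cy_um - hit$cy)
      return(out)
    }
  }
  R <- config$territory_radius_um
  r_half <- analytic_half_max_um(config)
  side <- max(1L, floor(config$domain_size_um / px))
  tp <- territory_pixels(cx_um, cy_um, R, px)
  p <- tp$pix
  keep <- p$r_um > r_half + config$soma_clearance_um
  if (!any(keep)) return(NULL)
  p <- p[keep, ]
  gx <- (p$x - tp$x0) %/% side
  gy <- (p$y - tp$y0) %/% side
  cell <- gx * 100000L + gy
  cnt <- table(cell)
  ok <- as.integer(names(cnt)[cnt >= min_px])
  if (!length(ok)) return(NULL)
  sel <- cell %in% ok
  cs <- cell[sel]
  cx_dom <- rowsum(p$xc_um[sel], cs) / as.vector(rowsum(rep(1, sum(sel)), cs))
  cy_dom <- rowsum(p$yc_um[sel], cs) / as.vector(rowsum(rep(1, sum(sel)), cs))
  npx <- as.vector(rowsum(rep(1L, sum(sel)), cs))
  ids <- as.integer(rownames(cx_dom))
  out <- data.frame(
    gx = ids %/% 100000L, gy = ids %% 100000L,
    centroid_x_um = as.numeric(cx_dom), centroid_y_um = as.numeric(cy_dom),
    n_px = npx,
    stringsAsFactors = FALSE
  )
  out$domain_id <- paste(out$gx, out$gy)
  out$radius_um <- sqrt((out$centroid_x_um - cx_um)^2 +
                          (out$centroid_y_um - cy_um)^2)
  out <- out[order(out$gy, out$gx),
             c("domain_id", "gx", "gy", "centroid_x_um", "centroid_y_um",
               "n_px", "radius_um")]
  rownames(out) <- NULL
  if (!is.null(cache)) cache[[key]] <- list(rel = out, cx = cx_um, cy = cy_um)
  out
}

#' Simulate ground-truth astrocyte activity (no image rendering)
#'
#' Generates the event-level ground truth of a synthetic astrocyte
#' population: territory geometry, the domain grid, per-domain activation and
#' onsets, and the soma decision. The soma of a (wild-type) astrocyte
#' activates if and only if the fraction of its domains active before the
#' soma decision is at least `theta_true`; domains active before the soma
#' follow a centripetal onset gradient (distal earlier), domains recruited
#' during the post-soma surge follow an outward centrifugal wavefront. In KO
#' mode domain activity is capped below the threshold and the soma never
#' activates.
#'
#' This table-level generator is cheap (no pixels) and is what large
#' parameter-recovery experiments run on; [simulate_population()] adds the
#' rendered structural image and functional movie.
#'
#' @param config a [sim_config()].
#' @return An object of class `ground_truth`: a list with elements
#'   `config`, `field_size_um`, `astro` (one row per astrocyte:
#'   geometry, stimulus level, `frac_active_pre`, `frac_active_total`,
#'   `soma_active`, `soma_onset_s`, `soma_amplitude`) and `domains`
#'   (one row per domain: grid position, centroid, radius from the soma
#'   centre, `active`, `pre_active`, `recruited`, `onset_s`, `phase`).
#' @export
#' @examples
#' gt <- simulate_ground_truth(sim_config(n_astrocytes = 3, seed = 7))
#' table(gt$domains$phase)
simulate_ground_truth <- function(config) {
  validate_sim_config(config)
  placement <- place_territories(config)
  centers <- placement$centers
  n <- config$n_astrocytes
  dt <- config$frame_interval_s

  dom_list <- vector("list", n)
  grid_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    d <- territory_domains(centers$cx_um[i], centers$cy_um[i], config,
                           cache = grid_cache)
    if (is.null(d) || nrow(d) < 2)
      stop("territory too small to hold any domains; increase territory_radius_um")
    d$astrocyte_id <- i
    dom_list[[i]] <- d
  }

  set.seed(config$seed + 2L)   # event stream; structure uses no randomness
  lvl <- if (length(config$stim_level) == 2L) {
    runif(n, config$stim_level[1], config$stim_level[2])
  } else rep(config$stim_level, n)
  p_act <- vapply(lvl, config$p_domain, numeric(1))
  if (config$ko_mode) p_act <- pmin(p_act, config$ko_cap)

  astro <- data.frame(
    astrocyte_id = seq_len(n),
    cx_um = centers$cx_um, cy_um = centers$cy_um,
    territory_radius_um = config$territory_radius_um,
    soma_radius_um = config$soma_radius_um,
    soma_struct_radius_um = analytic_half_max_um(config),
    stim_level = lvl, p_active = p_act,
    n_domains = vapply(dom_list, nrow, integer(1)),
    frac_active_pre = NA_real_, frac_active_total = NA_real_,
    soma_active = FALSE, soma_onset_s = NA_real_, soma_amplitude = 0
  )

  for (i in seq_len(n)) {
    d <- dom_list[[i]]
    nd <- nrow(d)
    pre <- rbinom(nd, 1L, p_act[i]) == 1L
    if (config$ko_mode) {
      cap <- max(0L, as.integer(ceiling((config$theta_true - config$ko_margin) * nd)) - 1L)
      if (sum(pre) > cap) {
        keep <- sample(which(pre), cap)
        pre[] <- FALSE
        pre[keep] <- TRUE
      }
    }
    frac_pre <- mean(pre)
    soma_on <- !config$ko_mode && frac_pre >= config$theta_true
    soma_t <- if (soma_on)
      config$stim_onset_s + config$base_latency_s + config$soma_delay_s else NA_real_

    onset <- rep(NA_real_, nd)
    if (any(pre)) {
      r <- d$radius_um[pre]
      base <- config$stim_onset_s + config$base_latency_s -
        config$centripetal_slope_s_per_um * (r - mean(d$radius_um))
      o <- base + rnorm(sum(pre), 0, config$onset_jitter_s)
      o <- pmax(o, config$stim_onset_s + dt)
      # pre-soma events lead the soma by at least two frames, so that the
      # slight detection delay of small-ROI traces cannot flip their order
      if (soma_on) o <- pmin(o, soma_t - 2 * dt)
      onset[pre] <- o
    }
    recruited <- rep(FALSE, nd)
    if (soma_on) {
      cand <- !pre
      recruited[cand] <- rbinom(sum(cand), 1L, config$surge_recruit_prob) == 1L
      onset[recruited] <- soma_t +
        d$radius_um[recruited] / config$centrifugal_speed_um_per_s
    }
    active <- pre | recruited
    phase <- rep(NA_character_, nd)
    phase[pre] <- if (soma_on) "pre_soma" else "no_soma"
    phase[recruited] <- "post_soma"

    d$active <- active; d$pre_active <- pre; d$recruited <- recruited
    d$onset_s <- onset; d$phase <- phase
    dom_list[[i]] <- d

    astro$frac_active_pre[i] <- frac_pre
    astro$frac_active_total[i] <- mean(active)
    astro$soma_active[i] <- soma_on
    astro$soma_onset_s[i] <- soma_t
    astro$soma_amplitude[i] <- if (soma_on)
      max(0.2, config$amp_soma * (1 + rnorm(1, 0, 0.05))) else 0
  }

  domains <- do.call(rbind, dom_list)
  rownames(domains) <- NULL
  structure(list(config = config, field_size_um = placement$field_size_um,
                 astro = astro, domains = domains),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d astrocytes, %d domains, %d active somas (%s)\n",
              nrow(x$astro), nrow(x$domains), sum(x$astro$soma_active),
              if (x$config$ko_mode) "KO" else "WT"))
  invisible(x)
}

#' @keywords internal
#' Structural radial profile: plateau 1.0 to r_s, steep linear fall to 0.15
#' over fall_width, shallow decay to 0.10 at the territory edge. The fall
#' spans the whole plausible range of the noisy half-max reference, so the
#' 50%-of-centre crossing always lands inside the steep segment and the
#' soma radius estimate stays within one ring of the analytic value.
structural_profile <- function(r, r_s, w, R) {
  out <- numeric(length(r))
  out[r <= r_s] <- 1
  fall <- r > r_s & r <= r_s + w
  out[fall] <- 1 - 0.85 * (r[fall] - r_s) / w
  tail <- r > r_s + w & r <= R
  out[tail] <- 0.15 - 0.05 * (r[tail] - r_s - w) / (R - r_s - w)
  out
}

#' @keywords internal
field_dims <- function(field_size_um, pixel_size_um) {
  n <- as.integer(ceiling(field_size_um / pixel_size_um))
  c(ny = n, nx = n)
}

#' Render the structural (SR101-like) channel of a simulated population
#'
#' @param gt a [simulate_ground_truth()] result.
#' @param noise logical; add the configured Gaussian structural noise.
#' @return list with `image` (ny x nx matrix, soma plateau = 1.0),
#'   `mask` (integer matrix, territory labels, 0 = background) and
#'   `seeds` (data.frame astrocyte_id, x_px, y_px; 0-based soma centres).
#' @export
render_structural <- function(gt, noise = TRUE) {
  cfg <- gt$config
  px <- cfg$pixel_size_um
  dims <- field_dims(gt$field_size_um, px)
  img <- matrix(0, dims["ny"], dims["nx"])
  lab <- matrix(0L, dims["ny"], dims["nx"])
  for (i in seq_len(nrow(gt$astro))) {
    a <- gt$astro[i, ]
    tp <- territory_pixels(a$cx_um, a$cy_um, a$territory_radius_um, px)
    p <- tp$pix
    val <- structural_profile(p$r_um, a$soma_radius_um, cfg$fall_width_um,
                              a$territory_radius_um)
    idx <- cbind(p$y + 1L, p$x + 1L)
    img[idx] <- val
    lab[idx] <- a$astrocyte_id
  }
  if (noise) {
    set.seed(cfg$seed)          # structural stream: independent of event draws
    img <- img + matrix(rnorm(length(img), 0, cfg$struct_noise_sd),
                        nrow(img), ncol(img))
  }
  seeds <- data.frame(astrocyte_id = gt$astro$astrocyte_id,
                      x_px = floor(gt$astro$cx_um / px),
                      y_px = floor(gt$astro$cy_um / px))
  list(image = img, mask = lab, seeds = seeds)
}

#' @keywords internal
#' Per-astrocyte ROI pixel indices (1-based, column-major into the field):
#' the structural soma disc and one entry per domain grid cell.
astro_roi_index <- function(a, cfg, dims) {
  px <- cfg$pixel_size_um
  side <- max(1L, floor(cfg$domain_size_um / px))
  tp <- territory_pixels(a$cx_um, a$cy_um, a$territory_radius_um, px)
  p <- tp$pix
  lin <- p$x * dims[["ny"]] + p$y + 1L
  soma <- lin[p$r_um <= a$soma_struct_radius_um]
  ann <- p$r_um > a$soma_struct_radius_um + cfg$soma_clearance_um
  key <- paste((p$x - tp$x0) %/% side, (p$y - tp$y0) %/% side)
  dom <- split(lin[ann], key[ann])
  list(soma = soma, domains = dom)
}

#' Render the functional (GCaMP-like) movie of a simulated population
#'
#' The movie is `baseline_f * (1 + dFF) + noise`, where each active ROI's
#' ΔF/F is a piecewise-linear event waveform with the configured kinetics.
#' Soma events are painted over the structural soma (radius = analytic
#' half-max), domain events over their grid-cell pixels.
#'
#' @param gt a [simulate_ground_truth()] result.
#' @param noise logical; add per-pixel Gaussian noise (`noise_sd`, ΔF/F
#'   units).
#' @return list with `movie` (ny x nx x nframes array, fluorescence units)
#'   and `times` (frame start times in s).
#' @export
render_movie <- function(gt, noise = TRUE) {
  cfg <- gt$config
  dims <- field_dims(gt$field_size_um, cfg$pixel_size_um)
  nt <- as.integer(round(cfg$movie_duration_s / cfg$frame_interval_s))
  times <- (seq_len(nt) - 1) * cfg$frame_interval_s
  npx <- prod(dims)
  if (noise) {
    set.seed(cfg$seed + 1L)     # movie-noise stream
    dff <- matrix(rnorm(npx * nt, 0, cfg$noise_sd), npx, nt)
  } else {
    dff <- matrix(0, npx, nt)
  }
  for (i in seq_len(nrow(gt$astro))) {
    a <- gt$astro[i, ]
    roi <- astro_roi_index(a, cfg, dims)
    if (a$soma_active) {
      w <- event_waveform(times, a$soma_onset_s, a$soma_amplitude,
                          cfg$rise_10_90_soma_s, cfg$decay_90_10_soma_s)
      dff[roi$soma, ] <- dff[roi$soma, ] + rep(w, each = length(roi$soma))
    }
    dd <- gt$domains[gt$domains$astrocyte_id == a$astrocyte_id &
                       gt$domains$active, , drop = FALSE]
    for (k in seq_len(nrow(dd))) {
      idx <- roi$domains[[paste(dd$gx[k], dd$gy[k])]]
      if (is.null(idx) || !length(idx)) next
      w <- event_waveform(times, dd$onset_s[k], cfg$amp_domain,
                          cfg$rise_10_90_domain_s, cfg$decay_90_10_domain_s)
      dff[idx, ] <- dff[idx, ] + rep(w, each = length(idx))
    }
  }
  movie <- cfg$baseline_f * (1 + dff)
  dim(movie) <- c(dims[["ny"]], dims[["nx"]], nt)
  list(movie = movie, times = times)
}

#' Simulate a full synthetic astrocyte population
#'
#' Combines [simulate_ground_truth()], [render_structural()] and
#' [render_movie()] into the complete set of pipeline inputs plus ground
#' truth. Deterministic: the same config and seed reproduce bit-identical
#' outputs, and wild-type vs KO runs of the same seed share the identical
#' structural channel (only the event tables differ).
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_population`: list with `config`,
#'   `ground_truth`, `structural` (matrix), `territory_mask` (integer
#'   matrix), `soma_seeds` (data.frame), `movie` (ny x nx x nt array),
#'   `times` (frame times, s).
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_astrocytes = 2, seed = 3,
#'                                       territory_radius_um = 15))
#' dim(pop$movie)
simulate_population <- function(config) {
  gt <- simulate_ground_truth(config)
  st <- render_structural(gt)
  mv <- render_movie(gt)
  structure(list(config = config, ground_truth = gt,
                 structural = st$image, territory_mask = st$mask,
                 soma_seeds = st$seeds, movie = mv$movie, times = mv$times),
            class = "sim_population")
}

#' Simulate an IP3R2-knockout astrocyte population
#'
#' Convenience wrapper around [simulate_population()] that enforces KO mode:
#' per-domain activation probability is capped (default 0.145) and realized
#' per-cell active fractions are kept below `theta_true - ko_margin`, so the
#' population can never cross the spatial threshold and no soma activates.
#'
#' @param config a [sim_config()] with `ko_mode = TRUE`.
#' @return as [simulate_population()].
#' @export
simulate_ko_population <- function(config) {
  if (!isTRUE(config$ko_mode))
    stop("simulate_ko_population() requires a config with ko_mode = TRUE")
  simulate_population(config)
}

#' Emulate imperfect event detection on ground truth
#'
#' Applies a simple observation model to a ground-truth table: each truly
#' active domain is detected with probability `1 - miss_rate`, each inactive
#' domain yields a false detection with probability `fp_rate` (onset drawn
#' uniformly in the response window). Soma state is observed faithfully.
#' Used to study estimator behaviour under realistic detection noise without
#' rendering movies.
#'
#' @param gt a [simulate_ground_truth()] result.
#' @param miss_rate per-domain false-negative probability.
#' @param fp_rate per-domain false-positive probability.
#' @param seed RNG seed for the observation draws.
#' @return a `ground_truth`-shaped list with observed `domains` and
#'   recomputed per-cell fractions in `astro` (soma decisions untouched).
#' @export
observe_responses <- function(gt, miss_rate = 0.1, fp_rate = 0, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"),
            miss_rate >= 0, miss_rate < 1, fp_rate >= 0, fp_rate < 1)
  set.seed(as.integer(seed))
  d <- gt$domains
  obs <- d$active & runif(nrow(d)) >= miss_rate
  fp <- !d$active & runif(nrow(d)) < fp_rate
  d$active <- obs | fp
  cfg <- gt$config
  if (any(fp))
    d$onset_s[fp] <- runif(sum(fp), cfg$stim_onset_s, cfg$movie_duration_s)
  d$onset_s[!d$active] <- NA_real_
  d$phase[!d$active] <- NA_character_
  a <- gt$astro
  for (i in seq_len(nrow(a))) {
    di <- d[d$astrocyte_id == a$astrocyte_id[i], ]
    if (a$soma_active[i]) {
      a$frac_active_pre[i] <- mean(di$active & di$onset_s < a$soma_onset_s[i],
                                   na.rm = TRUE)
    } else {
      a$frac_active_pre[i] <- mean(di$active)
    }
    a$frac_active_total[i] <- mean(di$active)
  }
  structure(list(config = gt$config, field_size_um = gt$field_size_um,
                 astro = a, domains = d),
            class = "ground_truth")
}

#' Per-astrocyte response table for threshold fitting
#'
#' Collapses a ground-truth (or observed) table into the per-cell records the
#' threshold estimator consumes: the active-domain fraction `a` (the
#' pre-soma fraction for soma-active cells, the whole-window fraction
#' otherwise), the binary soma state `soma_active`, the soma amplitude, and
#' the pre/post/whole-window fractions used by the surge comparison.
#'
#' @param gt a `ground_truth` object (possibly from [observe_responses()]).
#' @return data.frame with one row per astrocyte.
#' @export
response_table <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  a <- gt$astro
  data.frame(
    astrocyte_id = a$astrocyte_id,
    n_domains = a$n_domains,
    a = ifelse(a$soma_active, a$frac_active_pre, a$frac_active_total),
    soma_active = as.integer(a$soma_active),
    soma_amplitude = a$soma_amplitude,
    soma_onset_s = a$soma_onset_s,
    frac_pre = a$frac_active_pre,
    frac_post = a$frac_active_total,
    frac_whole = a$frac_active_total,
    stim_level = a$stim_level
  )
}

#' Active-domain onset table for spatiotemporal analysis
#'
#' @param gt a `ground_truth` object.
#' @return data.frame (one row per active domain): astrocyte_id, domain_id,
#'   centroid coordinates (µm), radius from the soma centre (µm), onset (s),
#'   phase (`pre_soma` / `post_soma` / `no_soma`), and the cell's soma onset.
#' @export
surge_table <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  d <- gt$domains[gt$domains$active & !is.na(gt$domains$onset_s), ]
  m <- match(d$astrocyte_id, gt$astro$astrocyte_id)
  data.frame(
    astrocyte_id = d$astrocyte_id, domain_id = d$domain_id,
    x_um = d$centroid_x_um, y_um = d$centroid_y_um,
    radius_um = d$radius_um, onset_s = d$onset_s, phase = d$phase,
    soma_onset_s = gt$astro$soma_onset_s[m],
    stringsAsFactors = FALSE
  )
}
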