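#' Analysis parameters for the pipeline
#'
#' @param ring_width_px radial ring width for segmentation (px).
#' @param domain_size_um domain grid side (µm).
#' @param min_pixels minimum pixels per clipped domain.
#' @param k_sd event-detection threshold in baseline SDs.
#' @param min_consec consecutive supra-threshold frames required.
#' @param min_domains minimum segmented domains for a cell to enter the
#'   threshold analysis.
#' @param min_cells minimum cells for the Heaviside fit.
#' @param bootstrap_reps bootstrap replicates for the threshold CI.
#' @param bin_width_um radial bin width for population onset-radius
#'   regressions (µm).
#' @param glm_min_cells minimum cells for the soma-driver model.
#' @return named list of class `pipeline_params`.
#' @export
pipeline_params <- function(ring_width_px = 1, domain_size_um = 4.3,
                            min_pixels = 4L, k_sd = 3, min_consec = 2L,
                            min_domains = 10L, min_cells = 20L,
                            bootstrap_reps = 500L, bin_width_um = 5,
                            glm_min_cells = 50L) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' @keywords internal
load_pipeline_input <- function(input) {
  if (inherits(input, "sim_population")) {
    cfg <- input$config
    return(list(structural = input$structural, movie = input$movie,
                mask = input$territory_mask, seeds = input$soma_seeds,
                meta = list(pixel_size_um = cfg$pixel_size_um,
                            frame_interval_s = cfg$frame_interval_s,
                            stim_onset_s = cfg$stim_onset_s,
                            stim_end_s = cfg$stim_onset_s + cfg$stim_duration_s,
                            seed = cfg$seed)))
  }
  if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    f <- function(x) file.path(input, x)
    for (p in c("structural.tif", "functional.tif", "territory_mask.tif",
                "soma_seeds.csv", "config.yaml", "images.yaml"))
      if (!file.exists(f(p))) stop("missing pipeline input file: ", p)
    cfg <- yaml::read_yaml(f("config.yaml"))
    sc <- yaml::read_yaml(f("images.yaml"))
    list(structural = read_image_tiff(f("structural.tif"), sc$structural),
         movie = read_movie_tiff(f("functional.tif"), sc$functional),
         mask = read_mask_tiff(f("territory_mask.tif"),
                               sc$territory_mask$n_labels),
         seeds = read.csv(f("soma_seeds.csv")),
         meta = list(pixel_size_um = cfg$pixel_size_um,
                     frame_interval_s = cfg$frame_interval_s,
                     stim_onset_s = cfg$stim_onset_s,
                     stim_end_s = cfg$stim_onset_s + cfg$stim_duration_s,
                     seed = cfg$seed))
  } else {
    stop("input must be a sim_population or a directory of pipeline inputs")
  }
}

#' @keywords internal
#' Extract soma / arbor / domain traces for all segmented cells.
extract_all_traces <- function(movie, segs, meta) {
  nt <- dim(movie)[3]
  flat <- matrix(movie, dim(movie)[1] * dim(movie)[2], nt)
  out <- list()
  for (id in names(segs$cells)) {
    seg <- segs$cells[[id]]
    tr <- list()
    mk <- function(idx) trace_from_f(colMeans(flat[idx, , drop = FALSE]),
                                     meta$frame_interval_s,
                                     meta$stim_onset_s, meta$stim_end_s)
    tr$soma <- mk(which(seg$soma_mask))
    tr$arbor <- mk(which(seg$arb_mask))
    tr$domains <- list()
    for (k in seq_len(nrow(seg$domains))) {
      idx <- which(seg$domain_label == seg$domains$domain_index[k])
      tr$domains[[seg$domains$domain_id[k]]] <- mk(idx)
    }
    out[[id]] <- tr
  }
  out
}

#' Per-astrocyte responses from a measured event table
#'
#' Builds the threshold-analysis records from detected events: for each
#' astrocyte the number of segmented domains, the soma state and onset, the
#' active-domain fractions before soma onset (`frac_pre`), over the whole
#' window (`frac_whole` = `frac_post`, cumulative), and the fraction `a`
#' entering the Heaviside fit (pre-soma for soma-active cells, whole-window
#' otherwise). Cells with fewer than `min_domains` domains are excluded.
#'
#' @param events an [event_table()] data.frame.
#' @param min_domains minimum domains per cell (default 10).
#' @return data.frame, one row per retained astrocyte.
#' @export
build_responses <- function(events, min_domains = 10L) {
  rows <- lapply(split(events, events$astrocyte_id), function(ev) {
    soma <- ev[ev$roi_type == "soma", ]
    arb <- ev[ev$roi_type == "arbor", ]
    dom <- ev[ev$roi_type == "domain", ]
    if (nrow(soma) != 1 || nrow(dom) < min_domains) return(NULL)
    s_act <- isTRUE(soma$active)
    frac_whole <- mean(dom$active)
    frac_pre <- if (s_act)
      mean(dom$active & !is.na(dom$onset_s) & dom$onset_s < soma$onset_s)
    else frac_whole
    data.frame(
      astrocyte_id = ev$astrocyte_id[1],
      n_domains = nrow(dom),
      a = if (s_act) frac_pre else frac_whole,
      soma_active = as.integer(s_act),
      soma_amplitude = if (s_act) soma$amplitude else 0,
      soma_onset_s = if (s_act) soma$onset_s else NA_real_,
      frac_pre = frac_pre, frac_post = frac_whole,
      frac_whole = frac_whole,
      arbor_active = as.integer(isTRUE(arb$active[1])),
      stim_level = NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
#' Measured domain-onset table (events joined to segmentation centroids).
build_onset_table <- function(events, segs) {
  dom <- events[events$roi_type == "domain" & events$active, ]
  if (!nrow(dom)) return(NULL)
  rows <- lapply(seq_len(nrow(dom)), function(i) {
    seg <- segs$cells[[as.character(dom$astrocyte_id[i])]]
    k <- match(dom$roi_id[i], seg$domains$domain_id)
    data.frame(astrocyte_id = dom$astrocyte_id[i],
               domain_id = dom$roi_id[i],
               x_um = seg$domains$centroid_x_um[k],
               y_um = seg$domains$centroid_y_um[k],
               radius_um = seg$domains$radius_um[k],
               onset_s = dom$onset_s[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates segmentation, trace extraction, event detection, threshold
#' estimation and surge characterisation, writing every intermediate table,
#' the threshold fit as JSON, figures, and a manifest with a content hash of
#' every artifact. Rerunning with the same inputs and seed reproduces
#' identical tables.
#'
#' @param input a [simulate_population()] object or a directory containing
#'   pipeline input files (as written by [write_population()]).
#' @param out_dir output directory.
#' @param params a [pipeline_params()] list.
#' @param seed seed for the bootstrap.
#' @param figures write PNG figures (default TRUE).
#' @return list with `segmentation`, `events`, `responses`, `threshold`,
#'   `ci`, `sigmoid`, `surge` (onset table, metrics, regressions, glm),
#'   `files` (written paths), `manifest`.
#' @export
run_pipeline <- function(input, out_dir, params = pipeline_params(),
                         seed = 1L, figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- load_pipeline_input(input)
  meta <- dat$meta
  files <- character()
  fp <- function(x) file.path(out_dir, x)

  ## --- segmentation -------------------------------------------------------
  segs <- segment_population(dat$structural, dat$mask, dat$seeds,
                             meta$pixel_size_um,
                             ring_width_px = params$ring_width_px,
                             domain_size_um = params$domain_size_um,
                             min_pixels = params$min_pixels)
  if (!length(segs$cells))
    stop("stage segmentation failed: no cell could be segmented")
  catalog <- do.call(rbind, lapply(names(segs$cells), function(id) {
    d <- segs$cells[[id]]$domains
    if (!nrow(d)) return(NULL)
    data.frame(astrocyte_id = as.integer(id), domain_id = d$domain_id,
               centroid_x_um = d$centroid_x_um,
               centroid_y_um = d$centroid_y_um,
               area_px = d$area_px, radius_um = d$radius_um,
               r_soma_um = segs$cells[[id]]$r_soma_um,
               stringsAsFactors = FALSE)
  }))
  write.csv(catalog, fp("domain_catalog.csv"), row.names = FALSE)
  write.csv(segs$failures, fp("segmentation_failures.csv"), row.names = FALSE)
  files <- c(files, fp("domain_catalog.csv"), fp("segmentation_failures.csv"))

  ## --- signals ------------------------------------------------------------
  traces <- extract_all_traces(dat$movie, segs, meta)
  events <- event_table(traces, segs$cells, k_sd = params$k_sd,
                        min_consec = params$min_consec)
  write.csv(events, fp("event_table.csv"), row.names = FALSE)
  files <- c(files, fp("event_table.csv"))

  ## --- responses & threshold ---------------------------------------------
  responses <- build_responses(events, params$min_domains)
  write.csv(responses, fp("responses.csv"), row.names = FALSE)
  files <- c(files, fp("responses.csv"))

  thr <- ci <- sig <- NULL
  if (!is.null(responses) && nrow(responses) >= params$min_cells &&
      length(unique(responses$soma_active)) == 2) {
    thr <- fit_heaviside(responses, params$min_cells)
    ci <- tryCatch(bootstrap_ci(responses, params$bootstrap_reps, seed = seed,
                                min_cells = params$min_cells),
                   error = function(e) NULL)
    sig <- tryCatch(fit_sigmoid(responses, params$min_cells),
                    error = function(e) list(ok = FALSE,
                                             reason = conditionMessage(e)))
  }
  thr_json <- list(
    a_T = if (!is.null(thr) && !thr$degenerate) thr$a_T else NA,
    r_squared = if (!is.null(thr) && !thr$degenerate) thr$r_squared else NA,
    n_cells = if (!is.null(thr)) thr$n_cells else nrow(responses),
    ci_95 = if (!is.null(ci)) ci$ci else c(NA, NA),
    error_curve = if (!is.null(thr) && !thr$degenerate) thr$error_curve else NULL,
    sigmoid = if (!is.null(sig) && isTRUE(sig$ok))
      as.list(sig$params) else NULL,
    settings = list(min_cells = params$min_cells,
                    min_domains = params$min_domains,
                    bootstrap_reps = params$bootstrap_reps, seed = seed))
  jsonlite::write_json(thr_json, fp("threshold_fit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  files <- c(files, fp("threshold_fit.json"))

  ## --- spatiotemporal -----------------------------------------------------
  surge <- NULL
  onset_tab <- build_onset_table(events, segs)
  if (!is.null(onset_tab) && !is.null(responses)) {
    soma_tab <- responses[, c("astrocyte_id", "soma_active", "soma_onset_s")]
    onset_tab <- onset_tab[onset_tab$astrocyte_id %in% soma_tab$astrocyte_id, ]
    classified <- classify_phases(onset_tab, soma_tab)
    metrics <- surge_metrics(classified, early_only = TRUE)
    reg_pre <- onset_radius_regression(classified, "pre_soma",
                                       bin_width_um = params$bin_width_um)
    reg_post <- onset_radius_regression(classified, "post_soma",
                                        bin_width_um = params$bin_width_um)
    glm_fit <- NULL
    # per-cell whole-window pairwise metrics for the driver model
    pm <- surge_cell_metrics(classified)
    cells_glm <- merge(responses, pm, by = "astrocyte_id", all.x = TRUE)
    if (sum(complete.cases(cells_glm[, c("a", "mean_pair_dist_um",
                                         "mean_pair_time_s")])) >=
        params$glm_min_cells)
      glm_fit <- tryCatch(glm_soma_drivers(cells_glm, params$glm_min_cells),
                          error = function(e) NULL)
    write.csv(metrics, fp("surge_metrics.csv"), row.names = FALSE)
    write.csv(classified, fp("domain_onsets.csv"), row.names = FALSE)
    jsonlite::write_json(list(pre_soma = reg_pre, post_soma = reg_post),
                         fp("regressions.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    files <- c(files, fp("surge_metrics.csv"), fp("domain_onsets.csv"),
               fp("regressions.json"))
    surge <- list(onsets = classified, metrics = metrics,
                  regression_pre = reg_pre, regression_post = reg_post,
                  glm = glm_fit)
  }

  ## --- figures ------------------------------------------------------------
  if (figures && !is.null(thr) && !thr$degenerate) {
    grDevices::png(fp("threshold_fit.png"), 640, 480)
    plot_threshold_fit(thr, responses)
    grDevices::dev.off()
    files <- c(files, fp("threshold_fit.png"))
  }
  if (figures && !is.null(surge)) {
    ids <- unique(surge$onsets$astrocyte_id[surge$onsets$phase != "no_soma"])
    if (length(ids)) {
      id <- as.character(ids[1])
      grDevices::png(fp("temporal_map.png"), 480, 480)
      plot_temporal_map(segs$cells[[id]], surge$onsets)
      grDevices::dev.off()
      files <- c(files, fp("temporal_map.png"))
    }
  }

  ## --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "astrosurge",
    version = as.character(utils::packageVersion("astrosurge")),
    seed = seed,
    parameters = unclass(params),
    n_cells_segmented = length(segs$cells),
    n_cells_failed = nrow(segs$failures),
    outputs = lapply(files, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, fp("manifest.json"))

  invisible(list(segmentation = segs, events = events, responses = responses,
                 threshold = thr, ci = ci, sigmoid = sig, surge = surge,
                 files = files, manifest = manifest))
}

#' @keywords internal
#' Per-cell pairwise metrics of the domain activity leading up to the soma
#' decision: pre-soma events for soma-active cells, all events otherwise.
#' Post-soma (surge) events are excluded so that the soma-driver model's
#' predictors describe the activity that could have caused the soma
#' response, not its consequences.
surge_cell_metrics <- function(classified) {
  classified <- classified[is.na(classified$phase) |
                             classified$phase != "post_soma", ]
  sp <- split(classified, classified$astrocyte_id)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    astrocyte_id = g$astrocyte_id[1],
    mean_pair_dist_um = pairwise_distance(g$x_um, g$y_um),
    mean_pair_time_s = pairwise_time(g$onset_s))))
  rownames(out) <- NULL
  out
}
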