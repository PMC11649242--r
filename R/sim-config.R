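#' Simulation configuration for synthetic astrocyte populations
#'
#' Bundles every parameter of the synthetic-data generator: field geometry,
#' acquisition timing, the ground-truth spatial threshold, the activation and
#' propagation model, event kinetics and noise. Defaults emulate the study
#' conditions of in vivo two-photon somatosensory-cortex recordings: 1.43 µm
#' pixels (366 µm field at 256 px), 0.5 s frames, 60 s movies with a 20 s
#' stimulus starting at 10 s, 4.3 µm domains, a spatial threshold of 0.226,
#' arbor/soma 10–90% rise times of 5.7/3.5 s, 90–10% decay times of 4.8/4.3 s,
#' and an arbor response latency of 11.1 s with the soma following ~2.1 s
#' later.
#'
#' @param n_astrocytes number of astrocytes to place.
#' @param field_size_um side of the square imaging field (µm). `NULL` (the
#'   default) sizes the field automatically to hold `n_astrocytes`
#'   non-overlapping territories.
#' @param pixel_size_um pixel size (µm/px).
#' @param frame_interval_s frame interval of the functional movie (s).
#' @param movie_duration_s total movie duration (s).
#' @param stim_onset_s,stim_duration_s stimulation onset and duration (s). At
#'   least 10 s of baseline must precede the onset.
#' @param soma_radius_um radius of the bright structural soma plateau (µm).
#' @param fall_width_um width of the steep fluorescence fall-off just outside
#'   the plateau (µm); the analytic half-max (structural soma) radius is
#'   `soma_radius_um + (0.5/0.85) * fall_width_um`.
#' @param soma_clearance_um clearance band between the structural soma and
#'   the first domains (µm): domain pixels start beyond
#'   `half-max radius + soma_clearance_um`, so a soma mask recovered with
#'   ±1-ring discretization error never overlaps responding domains.
#' @param territory_radius_um astrocyte territory radius (µm).
#' @param territory_gap_um minimum gap between neighbouring territories (µm).
#' @param domain_size_um side of the square domain grid cells (µm).
#' @param theta_true ground-truth spatial threshold: the soma activates iff
#'   the fraction of domains active before the soma decision is >= this value.
#' @param stim_level scalar stimulus level, or a length-2 range from which a
#'   per-astrocyte level is drawn uniformly (heterogeneous drive across the
#'   population).
#' @param p_domain monotone nondecreasing function mapping stimulus level to
#'   the per-domain activation probability. Default: identity clipped to
#'   \[0, 1\].
#' @param surge_recruit_prob probability that a domain inactive before soma
#'   activation is recruited during the post-soma calcium surge.
#' @param centripetal_slope_s_per_um pre-soma onset gradient (s/µm): distal
#'   domains respond earlier by this much per µm.
#' @param centrifugal_speed_um_per_s outward propagation speed of the
#'   post-soma surge (µm/s).
#' @param base_latency_s mean latency of pre-soma domain onsets after stimulus
#'   onset (s).
#' @param soma_delay_s delay of soma onset after the mean pre-soma domain
#'   latency (s).
#' @param onset_jitter_s SD of the Gaussian jitter on pre-soma onsets (s).
#' @param rise_10_90_domain_s,decay_90_10_domain_s domain/arbor event
#'   10–90% rise and 90–10% decay times (s).
#' @param rise_10_90_soma_s,decay_90_10_soma_s soma event kinetics (s).
#' @param amp_domain,amp_soma event amplitudes (ΔF/F₀ units).
#' @param noise_sd per-pixel, per-frame Gaussian noise SD of the functional
#'   movie, in ΔF/F₀ units.
#' @param struct_noise_sd Gaussian noise SD of the structural image, in units
#'   of the soma plateau intensity (structural SNR = 1 / `struct_noise_sd`).
#' @param baseline_f baseline fluorescence (arbitrary units).
#' @param ko_mode logical; emulate IP3R2-knockout astrocytes (domain activity
#'   capped below the spatial threshold, soma never activates).
#' @param ko_cap per-domain activation probability cap in KO mode.
#' @param ko_margin hard cap margin: realized KO active fractions are kept
#'   below `theta_true - ko_margin`.
#' @param seed integer RNG seed (< 2^31 - 16; the generator derives a small
#'   number of sub-seeds from it).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_population()], [simulate_ground_truth()]
#' @export
#' @examples
#' cfg <- sim_config(n_astrocytes = 4, seed = 1)
#' cfg$theta_true
sim_config <- function(n_astrocytes = 30,
                       field_size_um = NULL,
                       pixel_size_um = 1.43,
                       frame_interval_s = 0.5,
                       movie_duration_s = 60,
                       stim_onset_s = 10,
                       stim_duration_s = 20,
                       soma_radius_um = 5,
                       fall_width_um = 1.5,
                       soma_clearance_um = 1.5,
                       territory_radius_um = 25,
                       territory_gap_um = 2,
                       domain_size_um = 4.3,
                       theta_true = 0.226,
                       stim_level = c(0.05, 0.6),
                       p_domain = function(level) pmin(pmax(level, 0), 1),
                       surge_recruit_prob = 0.28,
                       centripetal_slope_s_per_um = 0.1,
                       centrifugal_speed_um_per_s = 5,
                       base_latency_s = 11.1,
                       soma_delay_s = 2.1,
                       onset_jitter_s = 0.5,
                       rise_10_90_domain_s = 5.7,
                       decay_90_10_domain_s = 4.8,
                       rise_10_90_soma_s = 3.5,
                       decay_90_10_soma_s = 4.3,
                       amp_domain = 2.0,
                       amp_soma = 2.0,
                       noise_sd = 0.1,
                       struct_noise_sd = 0.1,
                       baseline_f = 100,
                       ko_mode = FALSE,
                       ko_cap = 0.145,
                       ko_margin = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_astrocytes = as.integer(n_astrocytes),
    field_size_um = field_size_um,
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    movie_duration_s = movie_duration_s,
    stim_onset_s = stim_onset_s,
    stim_duration_s = stim_duration_s,
    soma_radius_um = soma_radius_um,
    fall_width_um = fall_width_um,
    soma_clearance_um = soma_clearance_um,
    territory_radius_um = territory_radius_um,
    territory_gap_um = territory_gap_um,
    domain_size_um = domain_size_um,
    theta_true = theta_true,
    stim_level = stim_level,
    p_domain = p_domain,
    surge_recruit_prob = surge_recruit_prob,
    centripetal_slope_s_per_um = centripetal_slope_s_per_um,
    centrifugal_speed_um_per_s = centrifugal_speed_um_per_s,
    base_latency_s = base_latency_s,
    soma_delay_s = soma_delay_s,
    onset_jitter_s = onset_jitter_s,
    rise_10_90_domain_s = rise_10_90_domain_s,
    decay_90_10_domain_s = decay_90_10_domain_s,
    rise_10_90_soma_s = rise_10_90_soma_s,
    decay_90_10_soma_s = decay_90_10_soma_s,
    amp_domain = amp_domain,
    amp_soma = amp_soma,
    noise_sd = noise_sd,
    struct_noise_sd = struct_noise_sd,
    baseline_f = baseline_f,
    ko_mode = isTRUE(ko_mode),
    ko_cap = ko_cap,
    ko_margin = ko_margin,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (!(theta_true > 0 && theta_true < 1))
      stop("theta_true must lie strictly in (0, 1)")
    durs <- c(frame_interval_s, movie_duration_s, stim_duration_s,
              territory_radius_um, soma_radius_um, domain_size_um,
              pixel_size_um, fall_width_um)
    if (any(durs <= 0)) stop("all durations and lengths must be > 0")
    if (domain_size_um > territory_radius_um)
      stop("domain_size_um must not exceed territory_radius_um")
    if (stim_onset_s < 10)
      stop("need >= 10 s of pre-stimulus baseline (stim_onset_s >= 10)")
    if (stim_onset_s + stim_duration_s > movie_duration_s)
      stop("stimulation window must end before the movie does")
    if (soma_radius_um + fall_width_um + soma_clearance_um >=
        territory_radius_um - domain_size_um)
      stop("soma plateau, fall width and clearance leave no room for domains")
    if (!is.function(p_domain)) stop("p_domain must be a function")
    grid <- seq(0, 1, by = 0.05)
    pv <- vapply(grid, p_domain, numeric(1))
    if (any(diff(pv) < -1e-12))
      stop("p_domain must be nondecreasing in the stimulus level")
    if (any(pv < -1e-12 | pv > 1 + 1e-12))
      stop("p_domain must map into [0, 1]")
    if (!(length(stim_level) %in% c(1L, 2L)) || any(!is.finite(stim_level)))
      stop("stim_level must be a scalar or a length-2 range")
    if (length(stim_level) == 2L && stim_level[2] < stim_level[1])
      stop("stim_level range must be increasing")
    if (seed < 0 || seed >= 2^31 - 16)
      stop("seed must be a non-negative integer below 2^31 - 16")
    if (ko_mode && theta_true - ko_margin <= 0)
      stop("ko_margin too large: KO cap would be non-positive")
  })
  invisible(cfg)
}

#' Analytic half-maximum (structural soma) radius of the generator profile
#'
#' The synthetic radial profile is a plateau at 1.0 out to the soma radius,
#' a steep linear fall to 0.15 over `fall_width_um`, then a shallow decay to
#' 0.10 at the territory edge. The radius at which it crosses 50% of the
#' centre intensity is therefore available in closed form and serves as the
#' ground truth for segmentation recovery.
#'
#' @param config a [sim_config()].
#' @return half-max radius in µm.
#' @export
analytic_half_max_um <- function(config) {
  config$soma_radius_um + (0.5 / 0.85) * config$fall_width_um
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d astrocytes, territory %g um, soma %g um (struct soma %.2f um)\n",
              x$n_astrocytes, x$territory_radius_um, x$soma_radius_um,
              analytic_half_max_um(x)))
  cat(sprintf("  movie %g s @ %g s/frame, stim %g-%g s, pixel %g um\n",
              x$movie_duration_s, x$frame_interval_s, x$stim_onset_s,
              x$stim_onset_s + x$stim_duration_s, x$pixel_size_um))
  cat(sprintf("  theta_true %.3f, mode %s, seed %d\n", x$theta_true,
              if (x$ko_mode) "KO" else "WT", x$seed))
  invisible(x)
}
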