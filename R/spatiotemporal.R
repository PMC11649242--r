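#' Classify active domains into pre-soma, post-soma and no-soma phases
#'
#' Domain events in cells whose soma activated are `pre_soma` when their
#' onset precedes the soma onset and `post_soma` otherwise; all events in
#' cells without somatic activation are `no_soma`. Cells are additionally
#' flagged as early responders when their soma onset precedes the population
#' median soma onset (analyses of surge structure are restricted to early
#' responders so that responses reflect the sensory drive rather than
#' neighbouring astrocyte activation).
#'
#' @param events data.frame of active domain events: `astrocyte_id`,
#'   `domain_id`, `x_um`, `y_um`, `radius_um`, `onset_s`.
#' @param soma data.frame per astrocyte: `astrocyte_id`, `soma_active`,
#'   `soma_onset_s`.
#' @return the events data.frame with `phase`, `soma_onset_s`,
#'   `onset_rel_soma_s` (NA for no-soma cells) and `early_responder` added.
#' @export
classify_phases <- function(events, soma) {
  m <- match(events$astrocyte_id, soma$astrocyte_id)
  if (anyNA(m)) stop("events reference astrocytes missing from soma table")
  act <- soma$soma_active[m] == 1 | soma$soma_active[m] == TRUE
  on <- soma$soma_onset_s[m]
  phase <- ifelse(!act, "no_soma",
                  ifelse(events$onset_s < on, "pre_soma", "post_soma"))
  med <- median(soma$soma_onset_s[soma$soma_active %in% c(1, TRUE)],
                na.rm = TRUE)
  out <- events
  out$phase <- phase
  out$soma_onset_s <- ifelse(act, on, NA_real_)
  out$onset_rel_soma_s <- ifelse(act, events$onset_s - on, NA_real_)
  out$early_responder <- ifelse(act, on < med, NA)
  out
}

#' Mean pairwise distance between active domains (µm)
#'
#' Mean Euclidean distance between domain centroids over all unordered
#' pairs. Undefined (NA) for fewer than two domains.
#'
#' @param x_um,y_um centroid coordinates (µm).
#' @return mean pairwise distance in µm, or NA.
#' @export
pairwise_distance <- function(x_um, y_um) {
  n <- length(x_um)
  if (n < 2) return(NA_real_)
  mean(stats::dist(cbind(x_um, y_um)))
}

#' Mean pairwise inter-onset time between active domains (s)
#'
#' @param onset_s event onsets (s).
#' @return mean |onset_i - onset_j| over unordered pairs, or NA if < 2.
#' @export
pairwise_time <- function(onset_s) {
  n <- length(onset_s)
  if (n < 2) return(NA_real_)
  mean(stats::dist(matrix(onset_s, ncol = 1)))
}

#' Per-astrocyte, per-phase surge metrics
#'
#' Computes, for every astrocyte and phase with at least two active domains,
#' the mean pairwise centroid distance and the mean pairwise inter-onset
#' time.
#'
#' @param table a classified onset table ([classify_phases()] output or
#'   [surge_table()]).
#' @param early_only restrict soma-active cells to early responders when the
#'   flag is available (default FALSE).
#' @return data.frame: astrocyte_id, phase, n_active, mean_pair_dist_um,
#'   mean_pair_time_s.
#' @export
surge_metrics <- function(table, early_only = FALSE) {
  tb <- table[!is.na(table$phase), ]
  if (early_only && "early_responder" %in% names(tb))
    tb <- tb[is.na(tb$early_responder) | tb$early_responder, ]
  if (!nrow(tb))
    return(data.frame(astrocyte_id = integer(), phase = character(),
                      n_active = integer(), mean_pair_dist_um = numeric(),
                      mean_pair_time_s = numeric()))
  sp <- split(tb, list(tb$astrocyte_id, tb$phase), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    astrocyte_id = g$astrocyte_id[1], phase = g$phase[1],
    n_active = nrow(g),
    mean_pair_dist_um = pairwise_distance(g$x_um, g$y_um),
    mean_pair_time_s = pairwise_time(g$onset_s))))
  rownames(out) <- NULL
  out[order(out$astrocyte_id, out$phase), ]
}

#' Onset-vs-radius regression (centripetal / centrifugal propagation)
#'
#' Regresses domain onset (relative to soma onset where available, absolute
#' otherwise) on the domain's radial distance from the soma centre. Before
#' soma activation a negative slope indicates centripetal flow (distal
#' domains respond sooner); after soma activation a positive slope indicates
#' the centrifugal spread of the calcium surge. In `"population"` mode the
#' radii are binned (default 5 µm) and the regression is on bin means,
#' mirroring aggregated population analyses; `"per_cell"` regresses raw
#' points.
#'
#' @param table classified onset table.
#' @param phase `"pre_soma"`, `"post_soma"` or `"no_soma"`.
#' @param mode `"population"` (binned) or `"raw"`.
#' @param bin_width_um radial bin width for population mode.
#' @return list with `slope` (s/µm), `intercept`, `r_squared`, `p_value`,
#'   `n`; NA slope when radii have no variance.
#' @export
onset_radius_regression <- function(table, phase,
                                    mode = c("population", "raw"),
                                    bin_width_um = 5) {
  mode <- match.arg(mode)
  tb <- table[!is.na(table$phase) & table$phase == phase, ]
  y <- if (all(is.na(tb$onset_rel_soma_s))) tb$onset_s else tb$onset_rel_soma_s
  x <- tb$radius_um
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3 || sd(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, p_value = NA_real_, n = length(x)))
  if (mode == "population") {
    b <- floor(x / bin_width_um)
    xb <- tapply(x, b, mean)
    yb <- tapply(y, b, mean)
    if (length(xb) < 3)
      return(list(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, p_value = NA_real_, n = length(xb)))
    x <- as.numeric(xb); y <- as.numeric(yb)
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # deterministic data fit perfectly
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]), n = length(x))
}

#' Logistic model of soma-activation drivers
#'
#' Fits a binomial (logit) model of the binary soma state on three z-scored
#' per-cell descriptors of domain activation: the fraction of active domains
#' (`a`), the mean pairwise distance between active domains, and the mean
#' pairwise inter-onset time (all computed on the activity leading up to the
#' soma decision). Reports per-predictor likelihood-ratio p-values (robust
#' near separation, where Wald tests collapse) and the whole-model
#' likelihood-ratio test against the intercept-only model.
#'
#' Because a thresholded soma is often nearly separable from the percent
#' area, the default fit (`regularize = TRUE`) adds two weighted
#' pseudo-observations at the predictor centre — a weakly-informative prior
#' that bounds the likelihood and restores the calibration of the
#' likelihood-ratio tests for the nuisance predictors (without it a
#' pure-noise predictor is flagged at roughly twice the nominal rate).
#' Complete separation of the unregularized fit is still detected and
#' reported.
#'
#' @param cells data.frame with `soma_active` (0/1), `a`,
#'   `mean_pair_dist_um`, `mean_pair_time_s`.
#' @param min_cells minimum cells (default 50).
#' @param regularize add the weakly-informative pseudo-observations
#'   (default TRUE).
#' @return list with `coefficients` (data.frame: term, estimate, wald_p,
#'   lrt_p), `model_p` (whole-model LRT), `separation` flag, `n`.
#' @export
glm_soma_drivers <- function(cells, min_cells = 50L, regularize = TRUE) {
  need <- c("soma_active", "a", "mean_pair_dist_um", "mean_pair_time_s")
  stopifnot(all(need %in% names(cells)))
  d <- cells[complete.cases(cells[, need]), need]
  if (nrow(d) < min_cells)
    stop(sprintf("need at least %d complete cells, got %d", min_cells, nrow(d)))
  if (length(unique(d$soma_active)) < 2L)
    stop("degenerate: all soma states identical")
  z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  dz <- data.frame(S = d$soma_active, area = z(d$a),
                   dist = z(d$mean_pair_dist_um),
                   time = z(d$mean_pair_time_s))
  raw <- suppressWarnings(glm(S ~ area + dist + time, binomial(), data = dz))
  eps <- 1e-8
  separation <- !raw$converged ||
    all(fitted(raw) < eps | fitted(raw) > 1 - eps)
  if (regularize) {
    aug <- rbind(dz, transform(dz[rep(1, 2), ], S = c(0, 1),
                               area = 0, dist = 0, time = 0))
    wts <- c(rep(1, nrow(dz)), 1, 1)
    fit <- suppressWarnings(glm(S ~ area + dist + time, binomial(),
                                data = aug, weights = wts))
  } else {
    fit <- raw
  }
  dr <- suppressWarnings(drop1(fit, test = "Chisq"))
  null <- suppressWarnings(update(fit, . ~ 1))
  lrt <- suppressWarnings(anova(null, fit, test = "Chisq"))
  sm <- summary(fit)$coefficients
  terms <- c("area", "dist", "time")
  coefs <- data.frame(
    term = terms,
    estimate = sm[terms, "Estimate"],
    wald_p = sm[terms, "Pr(>|z|)"],
    lrt_p = dr[terms, "Pr(>Chi)"])
  rownames(coefs) <- NULL
  list(coefficients = coefs,
       model_p = lrt$`Pr(>Chi)`[2],
       separation = separation, n = nrow(d))
}

#' Population-level report: response categories, correlations, stimulus curves
#'
#' Summarises a set of imaged populations (fields of view): per-population
#' proportions of response categories (both arbor and soma active, arbor
#' only, soma only, none), Pearson correlations between percent of arbors
#' active and percent of somas active (and percent of domains active vs
#' somas active) across populations, the stimulus-response relation of
#' domain activation, and a one-way ANOVA of domain fractions across
#' stimulus levels.
#'
#' @param pops named list of per-population response tables (each as
#'   [response_table()], plus an `arbor_active` column when available;
#'   cells' `frac_whole` is used for percent domains active).
#' @return list with `categories`, `correlations`, `stim_curve`, `anova`.
#' @export
population_report <- function(pops) {
  stopifnot(is.list(pops), length(pops) >= 1)
  per_pop <- do.call(rbind, lapply(names(pops), function(nm) {
    p <- pops[[nm]]
    arbor <- if ("arbor_active" %in% names(p)) p$arbor_active == 1
    else p$frac_whole > 0
    soma <- p$soma_active == 1
    data.frame(
      population = nm, n_cells = nrow(p),
      pct_both = 100 * mean(arbor & soma),
      pct_arbor_only = 100 * mean(arbor & !soma),
      pct_soma_only = 100 * mean(!arbor & soma),
      pct_none = 100 * mean(!arbor & !soma),
      pct_arbors_active = 100 * mean(arbor),
      pct_somas_active = 100 * mean(soma),
      pct_domains_active = 100 * mean(p$frac_whole),
      mean_stim_level = mean(p$stim_level))
  }))
  correlations <- if (nrow(per_pop) >= 3 &&
                      sd(per_pop$pct_somas_active) > 0 &&
                      sd(per_pop$pct_arbors_active) > 0 &&
                      sd(per_pop$pct_domains_active) > 0) {
    ca <- suppressWarnings(
      cor.test(per_pop$pct_arbors_active, per_pop$pct_somas_active))
    cd <- suppressWarnings(
      cor.test(per_pop$pct_domains_active, per_pop$pct_somas_active))
    data.frame(
      comparison = c("arbors_vs_somas", "domains_vs_somas"),
      r = c(unname(ca$estimate), unname(cd$estimate)),
      r_squared = c(unname(ca$estimate)^2, unname(cd$estimate)^2),
      p_value = c(ca$p.value, cd$p.value))
  } else NULL
  all_cells <- do.call(rbind, lapply(pops, function(p)
    p[, c("frac_whole", "stim_level")]))
  lev <- cut(all_cells$stim_level, breaks = 4)
  anova_fit <- if (nlevels(droplevels(lev)) >= 2) {
    summary(aov(frac_whole ~ lev, data = all_cells))
  } else NULL
  stim_curve <- if (!is.null(anova_fit)) {
    data.frame(level = levels(droplevels(lev)),
               mean_frac = as.numeric(tapply(all_cells$frac_whole,
                                             droplevels(lev), mean)))
  } else NULL
  list(categories = per_pop, correlations = correlations,
       stim_curve = stim_curve, anova = anova_fit,
       single_population = nrow(per_pop) < 3)
}
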