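test_that("phase classification follows soma onset and covers all events", {
  soma <- data.frame(astrocyte_id = 1:2, soma_active = c(1, 0),
                     soma_onset_s = c(6, NA))
  ev <- data.frame(astrocyte_id = c(1, 1, 1, 2, 2),
                   domain_id = letters[1:5],
                   x_um = 1:5, y_um = 1:5, radius_um = 1:5,
                   onset_s = c(3, 5, 9, 4, 7))
  cl <- classify_phases(ev, soma)
  expect_equal(cl$phase, c("pre_soma", "pre_soma", "post_soma",
                           "no_soma", "no_soma"))
  expect_true(all(!is.na(cl$phase)))            # exhaustive partition
  expect_equal(cl$onset_rel_soma_s[1:3], c(-3, -1, 3))
})

test_that("pairwise statistics match hand calculations and the O(n^2) oracle", {
  expect_equal(pairwise_distance(c(0, 10), c(0, 0)), 10)
  expect_equal(pairwise_distance(c(0, 3, 6), c(0, 0, 0)), 4)
  expect_equal(pairwise_time(c(0, 4)), 4)
  expect_equal(pairwise_time(c(0, 2, 4)), 8 / 3)
  expect_true(is.na(pairwise_distance(1, 1)))
  set.seed(9)
  x <- runif(50, 0, 50); y <- runif(50, 0, 50); t <- runif(50, 0, 30)
  expect_equal(pairwise_distance(x, y), brute_pair_dist(x, y))
  expect_equal(pairwise_time(t), brute_pair_time(t))
})

test_that("surge metrics are computed per astrocyte and phase", {
  gt <- simulate_ground_truth(sim_config(n_astrocytes = 40, seed = 900))
  tb <- surge_table(gt)
  soma <- data.frame(astrocyte_id = gt$astro$astrocyte_id,
                     soma_active = gt$astro$soma_active,
                     soma_onset_s = gt$astro$soma_onset_s)
  cl <- classify_phases(tb, soma)
  # generator phases agree with the classification rule
  expect_equal(cl$phase, tb$phase)
  m <- surge_metrics(cl)
  expect_true(all(m$n_active >= 2))
  expect_true(all(m$mean_pair_dist_um > 0))
  # spot-check one group against the oracle
  g <- cl[cl$astrocyte_id == m$astrocyte_id[1] & cl$phase == m$phase[1], ]
  expect_equal(m$mean_pair_dist_um[1], brute_pair_dist(g$x_um, g$y_um))
  expect_equal(m$mean_pair_time_s[1], brute_pair_time(g$onset_s))
})

test_that("onset-radius regression recovers analytic slopes", {
  r <- seq(5, 40, by = 1)
  tb1 <- data.frame(astrocyte_id = 1, domain_id = seq_along(r),
                    x_um = r, y_um = 0, radius_um = r,
                    onset_s = -0.1 * r, onset_rel_soma_s = -0.1 * r,
                    phase = "pre_soma")
  fit1 <- onset_radius_regression(tb1, "pre_soma", mode = "raw")
  expect_equal(fit1$slope, -0.1, tolerance = 1e-9)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-9)

  v <- 5
  tb2 <- transform(tb1, onset_rel_soma_s = r / v, phase = "post_soma")
  fit2 <- onset_radius_regression(tb2, "post_soma", mode = "raw")
  expect_equal(fit2$slope, 1 / v, tolerance = 1e-9)

  # binned population mode preserves an exactly linear relation
  fit3 <- onset_radius_regression(tb2, "post_soma", mode = "population")
  expect_equal(fit3$slope, 1 / v, tolerance = 1e-9)

  # degenerate: no radial variance
  tb4 <- transform(tb1, radius_um = 10)
  expect_true(is.na(onset_radius_regression(tb4, "pre_soma", mode = "raw")$slope))
})

test_that("regression slopes convert correctly between px and um radii", {
  set.seed(11)
  r_um <- runif(40, 8, 30)
  tb <- data.frame(astrocyte_id = 1, domain_id = 1:40, x_um = r_um, y_um = 0,
                   radius_um = r_um, onset_s = -0.1 * r_um + rnorm(40, 0, 0.2),
                   onset_rel_soma_s = -0.1 * r_um + rnorm(40, 0, 0.2),
                   phase = "pre_soma")
  f_um <- onset_radius_regression(tb, "pre_soma", mode = "raw")
  px <- 1.43
  tb_px <- transform(tb, radius_um = radius_um / px)   # radii in pixels
  f_px <- onset_radius_regression(tb_px, "pre_soma", mode = "raw")
  expect_equal(f_px$slope, f_um$slope * px, tolerance = 1e-9)
})

test_that("centripetal and centrifugal signs are recovered on synthetic surges", {
  ok <- 0
  for (s in 1:8) {
    gt <- simulate_ground_truth(sim_config(n_astrocytes = 30, seed = 1000 + s))
    tb <- surge_table(gt)
    soma <- data.frame(astrocyte_id = gt$astro$astrocyte_id,
                       soma_active = gt$astro$soma_active,
                       soma_onset_s = gt$astro$soma_onset_s)
    cl <- classify_phases(tb, soma)
    pre <- onset_radius_regression(cl, "pre_soma")
    post <- onset_radius_regression(cl, "post_soma")
    if (pre$slope < 0 && post$slope > 0) ok <- ok + 1
  }
  expect_equal(ok, 8)
})

test_that("the soma-driver model isolates percent area under detection noise", {
  gt <- simulate_ground_truth(sim_config(n_astrocytes = 200, seed = 1100))
  obs <- observe_responses(gt, miss_rate = 0.1, seed = 2)
  rt <- response_table(obs)
  tb <- surge_table(obs)
  soma <- data.frame(astrocyte_id = obs$astro$astrocyte_id,
                     soma_active = obs$astro$soma_active,
                     soma_onset_s = obs$astro$soma_onset_s)
  cl <- classify_phases(tb, soma)
  pm <- astrosurge:::surge_cell_metrics(cl)
  cells <- merge(rt, pm, by = "astrocyte_id")
  fit <- glm_soma_drivers(cells)
  co <- fit$coefficients
  expect_lt(co$lrt_p[co$term == "area"], 0.05)
  expect_gt(co$lrt_p[co$term == "dist"], 0.05)
  expect_lt(fit$model_p, 0.001)
})

test_that("degenerate soma states and permuted labels behave correctly in the GLM", {
  gt <- simulate_ground_truth(sim_config(n_astrocytes = 120, seed = 1200))
  rt <- response_table(gt)
  tb <- surge_table(gt)
  soma <- data.frame(astrocyte_id = gt$astro$astrocyte_id,
                     soma_active = gt$astro$soma_active,
                     soma_onset_s = gt$astro$soma_onset_s)
  pm <- astrosurge:::surge_cell_metrics(classify_phases(tb, soma))
  cells <- merge(rt, pm, by = "astrocyte_id")
  cells_flat <- transform(cells, soma_active = 1)
  expect_error(glm_soma_drivers(cells_flat), "degenerate")

  # permutation calibration: shuffled labels are significant ~5% of the time
  set.seed(3)
  ps <- replicate(20, {
    cp <- cells
    cp$soma_active <- sample(cp$soma_active)
    glm_soma_drivers(cp)$model_p
  })
  expect_lte(sum(ps < 0.05), 4)
})

test_that("population report summarises categories and correlations", {
  pops <- lapply(1:5, function(s) {
    gt <- simulate_ground_truth(sim_config(n_astrocytes = 40, seed = 1300 + s,
                                           stim_level = c(0.05, 0.2 + 0.1 * s)))
    rt <- response_table(gt)
    rt$arbor_active <- as.integer(rt$frac_whole > 0)
    rt
  })
  names(pops) <- paste0("pop", 1:5)
  rep <- population_report(pops)
  expect_equal(nrow(rep$categories), 5)
  expect_false(rep$single_population)
  pcts <- rowSums(rep$categories[, c("pct_both", "pct_arbor_only",
                                     "pct_soma_only", "pct_none")])
  expect_equal(unname(pcts), rep(100, 5))

  # soma state a deterministic function of arbor fraction -> R^2 = 1
  det <- lapply(1:4, function(k) {
    a <- seq(0.05, 0.6, length.out = 30) * k / 4
    data.frame(a = a, soma_active = as.integer(a >= 0.226),
               frac_whole = a, stim_level = k / 4,
               arbor_active = as.integer(a >= 0.226))
  })
  names(det) <- paste0("d", 1:4)
  rep2 <- population_report(det)
  r2 <- rep2$correlations$r_squared[rep2$correlations$comparison ==
                                      "arbors_vs_somas"]
  expect_equal(r2, 1, tolerance = 1e-9)

  # a single population yields no correlations, flagged
  rep1 <- population_report(pops[1])
  expect_true(rep1$single_population)
  expect_null(rep1$correlations)
})
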