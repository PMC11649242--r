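test_that("simulation is deterministic given config and seed", {
  cfg <- tiny_config(seed = 42, n = 2)
  g1 <- simulate_ground_truth(cfg)
  g2 <- simulate_ground_truth(cfg)
  expect_identical(g1$astro, g2$astro)
  expect_identical(g1$domains, g2$domains)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$structural, p2$structural)
  expect_identical(p1$movie, p2$movie)
})

test_that("soma activates iff the pre-soma active fraction reaches the threshold", {
  for (s in 1:5) {
    gt <- simulate_ground_truth(sim_config(n_astrocytes = 40, seed = s))
    expect_equal(gt$astro$soma_active,
                 gt$astro$frac_active_pre >= gt$config$theta_true)
    # phase structure: pre onsets strictly before soma, post at/after
    d <- merge(gt$domains, gt$astro[, c("astrocyte_id", "soma_onset_s")],
               by = "astrocyte_id")
    pre <- d[!is.na(d$phase) & d$phase == "pre_soma", ]
    post <- d[!is.na(d$phase) & d$phase == "post_soma", ]
    expect_true(all(pre$onset_s < pre$soma_onset_s))
    expect_true(all(post$onset_s >= post$soma_onset_s))
  }
})

test_that("degenerate activation probabilities force the expected extremes", {
  g0 <- simulate_ground_truth(sim_config(n_astrocytes = 6, seed = 3,
                                         p_domain = function(l) 0 * l))
  expect_equal(sum(g0$domains$active), 0)
  expect_equal(sum(g0$astro$soma_active), 0)

  g1 <- simulate_ground_truth(sim_config(n_astrocytes = 6, seed = 3,
                                         p_domain = function(l) 0 * l + 1))
  expect_true(all(g1$astro$soma_active))
  expect_true(all(g1$astro$frac_active_pre >= 0.226))
})

test_that("a fully silent population renders a pure-noise movie", {
  cfg <- tiny_config(seed = 5, p_domain = function(l) 0 * l)
  pop <- simulate_population(cfg)
  dff <- pop$movie / cfg$baseline_f - 1
  expect_lt(abs(mean(dff)), 0.01)
  expect_lt(abs(sd(dff) - cfg$noise_sd), 0.01)
})

test_that("mean active fraction is nondecreasing in stimulus level", {
  levels <- seq(0.1, 0.6, by = 0.1)
  means <- ses <- numeric(length(levels))
  for (i in seq_along(levels)) {
    gt <- simulate_ground_truth(sim_config(n_astrocytes = 30, seed = 7,
                                           stim_level = levels[i]))
    means[i] <- mean(gt$astro$frac_active_pre)
    nd <- sum(gt$astro$n_domains)
    ses[i] <- sqrt(means[i] * (1 - means[i]) / nd)
  }
  tol <- 2 * sqrt(ses[-1]^2 + ses[-length(ses)]^2)
  expect_true(all(diff(means) >= -tol))
})

test_that("empirical soma activation is a step in the active fraction", {
  gt <- simulate_ground_truth(sim_config(n_astrocytes = 200, seed = 1,
                                         stim_level = c(0.05, 0.6)))
  rt <- response_table(gt)
  # direct evaluation of the threshold rule on the ground-truth table
  expect_equal(rt$soma_active, as.integer(rt$frac_pre >= 0.226))
  below <- rt$a[rt$soma_active == 0]
  above <- rt$a[rt$soma_active == 1]
  expect_lt(max(below), 0.226)
  expect_gte(min(above), 0.226)
})

test_that("KO mode caps domain activity and silences every soma", {
  expect_error(simulate_ko_population(tiny_config(seed = 1)), "ko_mode")

  cfg <- sim_config(n_astrocytes = 60, seed = 9, ko_mode = TRUE,
                    stim_level = 0.5)
  gt <- simulate_ground_truth(cfg)
  expect_equal(sum(gt$astro$soma_active), 0)
  expect_true(all(gt$astro$frac_active_pre < cfg$theta_true))
  # calibration: capped per-domain probability 0.145 recovered within
  # sampling error of the mean active fraction
  se <- sd(gt$astro$frac_active_pre) / sqrt(nrow(gt$astro))
  expect_lt(abs(mean(gt$astro$frac_active_pre) - 0.145), 0.01 + 2 * se)
})

test_that("KO and WT populations share the same structural channel", {
  cfg_wt <- sim_config(n_astrocytes = 3, seed = 11)
  cfg_ko <- sim_config(n_astrocytes = 3, seed = 11, ko_mode = TRUE)
  st_wt <- render_structural(simulate_ground_truth(cfg_wt))
  st_ko <- render_structural(simulate_ground_truth(cfg_ko))
  expect_identical(st_wt$image, st_ko$image)
  expect_identical(st_wt$mask, st_ko$mask)
})

test_that("waveform kinetics match the configured rise and decay times", {
  t <- seq(0, 40, by = 0.01)
  for (k in list(c(5.7, 4.8), c(3.5, 4.3), c(2, 8))) {
    w <- event_waveform(t, onset_s = 5, amp = 2,
                        rise_10_90_s = k[1], decay_90_10_s = k[2])
    m <- measure_waveform_times(t, w)
    expect_equal(unname(m["rise_10_90_s"]), k[1], tolerance = 0.01)
    expect_equal(unname(m["decay_90_10_s"]), k[2], tolerance = 0.01)
  }
})

test_that("rendered noiseless events reproduce configured kinetics within a frame", {
  cfg <- tiny_config(seed = 13, p_domain = function(l) 0 * l + 1)
  gt <- simulate_ground_truth(cfg)
  mv <- render_movie(gt, noise = FALSE)
  a <- gt$astro[1, ]
  dims <- c(ny = dim(mv$movie)[1], nx = dim(mv$movie)[2])
  roi <- astrosurge:::astro_roi_index(a, cfg, dims)
  tr <- extract_trace(mv$movie, roi$soma, cfg$frame_interval_s,
                      cfg$stim_onset_s, cfg$stim_onset_s + cfg$stim_duration_s)
  m <- measure_waveform_times(tr$times, tr$values)
  expect_lt(abs(m["rise_10_90_s"] - cfg$rise_10_90_soma_s),
            cfg$frame_interval_s)
  expect_lt(abs(m["decay_90_10_s"] - cfg$decay_90_10_soma_s),
            cfg$frame_interval_s)
})

test_that("impossible territory placement fails loudly", {
  expect_error(
    simulate_ground_truth(sim_config(n_astrocytes = 20, field_size_um = 100,
                                     seed = 1)),
    "cannot place")
})

test_that("observe_responses applies miss and false-positive rates", {
  gt <- simulate_ground_truth(sim_config(n_astrocytes = 50, seed = 21,
                                         stim_level = 0.4))
  obs <- observe_responses(gt, miss_rate = 0.3, fp_rate = 0, seed = 1)
  truly <- sum(gt$domains$active)
  seen <- sum(obs$domains$active)
  expect_lt(abs(seen / truly - 0.7), 3 * sqrt(0.3 * 0.7 / truly))
  # soma decisions are observed faithfully
  expect_identical(obs$astro$soma_active, gt$astro$soma_active)
})
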