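test_that("heaviside step uses the a >= a_T convention", {
  expect_equal(heaviside(0.10, 0.226), 0)
  expect_equal(heaviside(0.226, 0.226), 1)
  expect_equal(heaviside(0.50, 0.226), 1)
})

test_that("perfectly separated data give a zero-error fit with R^2 = 1", {
  a <- c(seq(0.02, 0.20, by = 0.02), seq(0.30, 0.60, by = 0.02))
  S <- as.numeric(a >= 0.25)
  fit <- fit_heaviside(data.frame(a = a, soma_active = S))
  expect_equal(fit$sse, 0)
  expect_equal(fit$r_squared, 1)
  # every candidate inside the gap has zero error; the tie rule returns the
  # smallest zero-error candidate, the midpoint just above the last S=0 cell
  zero <- fit$error_curve$candidate[fit$error_curve$sse == 0]
  expect_equal(fit$a_T, min(zero))
  expect_true(fit$a_T > 0.20 && fit$a_T <= 0.30)
})

test_that("fit matches the exhaustive brute-force scan on random instances", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(20:100, 1)
    a <- round(runif(n), sample(c(1, 2, 3), 1))   # force ties sometimes
    S <- as.numeric(runif(n) < plogis(10 * (a - 0.3)))
    if (length(unique(S)) < 2) next
    fit <- fit_heaviside(data.frame(a = a, soma_active = S), min_cells = 20)
    oracle <- brute_heaviside(a, S)
    expect_identical(fit$a_T, oracle$a_T)
    expect_identical(fit$sse, oracle$sse)
  }
})

test_that("fit is invariant to response ordering", {
  set.seed(5)
  a <- runif(80)
  S <- as.numeric(a >= 0.4)
  S[1:5] <- 1 - S[1:5]
  d <- data.frame(a = a, soma_active = S)
  f1 <- fit_heaviside(d)
  f2 <- fit_heaviside(d[sample(80), ])
  expect_equal(f1$a_T, f2$a_T)
  expect_equal(f1$sse, f2$sse)
})

test_that("degenerate inputs are reported, not fitted", {
  d <- data.frame(a = runif(30), soma_active = 1)
  fit <- fit_heaviside(d)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$a_T))
  expect_error(fit_heaviside(data.frame(a = runif(6), soma_active = rep(0:1, 3))),
               "at least")
})

test_that("threshold recovery is consistent as the cohort grows", {
  errs <- sapply(c(50, 200, 1000), function(n) {
    e <- sapply(1:5, function(s) {
      gt <- simulate_ground_truth(sim_config(n_astrocytes = n, seed = 400 + s))
      fit_heaviside(response_table(gt))$a_T - 0.226
    })
    mean(abs(e))
  })
  expect_lt(errs[3], 0.005)
  expect_lte(errs[3], errs[1] + 1e-9)
})

test_that("bootstrap CI behaves at the edges and under resampling", {
  # zero-variance data: every replicate refits the same values
  d <- data.frame(a = rep(c(0.1, 0.4), each = 20),
                  soma_active = rep(c(0, 1), each = 20))
  ci <- bootstrap_ci(d, reps = 50, seed = 1, smooth = FALSE)
  expect_equal(unname(ci$ci[1]), unname(ci$ci[2]))
  expect_equal(unname(ci$ci[1]), 0.25)
  expect_error(bootstrap_ci(d, reps = 1), "reps")
})

test_that("bootstrap CI covers the generating threshold on synthetic cohorts", {
  cover <- 0
  for (s in 1:10) {
    gt <- simulate_ground_truth(sim_config(n_astrocytes = 300, seed = 500 + s))
    rt <- response_table(gt)
    ci <- bootstrap_ci(rt, reps = 200, seed = s)
    if (ci$ci[1] <= 0.226 && 0.226 <= ci$ci[2]) cover <- cover + 1
  }
  expect_gte(cover, 9)
})

test_that("label noise widens but does not destroy the threshold estimate", {
  set.seed(77)
  for (s in 1:5) {
    gt <- simulate_ground_truth(sim_config(n_astrocytes = 500, seed = 600 + s))
    rt <- response_table(gt)
    flip <- sample(nrow(rt), round(0.1 * nrow(rt)))
    rt$soma_active[flip] <- 1 - rt$soma_active[flip]
    fit <- fit_heaviside(rt)
    expect_lt(abs(fit$a_T - 0.226), 0.04)
  }
})

test_that("sigmoid fit recovers known logistic parameters and flags flat data", {
  a <- seq(0, 1, length.out = 200)
  y <- 0.1 + 1.8 / (1 + exp(-25 * (a - 0.3)))
  fit <- fit_sigmoid(data.frame(a = a, soma_amplitude = y))
  expect_true(fit$ok)
  expect_equal(unname(fit$params["L"]), 1.8, tolerance = 1e-5)
  expect_equal(unname(fit$params["a0"]), 0.3, tolerance = 1e-5)

  # hard-step amplitudes: inflection lands inside the step
  y2 <- ifelse(a >= 0.25, 1.5, 0)
  fit2 <- fit_sigmoid(data.frame(a = a, soma_amplitude = y2))
  expect_true(fit2$ok)
  expect_true(fit2$params["a0"] >= 0.2 && fit2$params["a0"] <= 0.3)

  # flat data: no transition
  fit3 <- fit_sigmoid(data.frame(a = a, soma_amplitude = rep(1, 200)))
  expect_false(isTRUE(fit3$ok) && abs(fit3$params["k"]) > 1)
})

test_that("sigmoid inflection agrees with the Heaviside threshold on step data", {
  gt <- simulate_ground_truth(sim_config(n_astrocytes = 400, seed = 700))
  rt <- response_table(gt)
  hv <- fit_heaviside(rt)
  sg <- fit_sigmoid(rt)
  expect_true(sg$ok)
  expect_lt(abs(unname(sg$params["a0"]) - hv$a_T), 0.05)
})

test_that("pre/no/post comparison reflects the surge recruitment", {
  gt <- simulate_ground_truth(sim_config(n_astrocytes = 300, seed = 800,
                                         surge_recruit_prob = 0.28))
  rt <- response_table(gt)
  cmp <- compare_pre_no_post(rt)
  g <- setNames(cmp$groups$mean, cmp$groups$group)
  # post-soma surge recruits additional domains (paired increase)
  expect_gt(g["post_soma"], g["pre_soma"])
  expect_lt(cmp$test_pre_vs_post$p.value, 0.001)
  # threshold separation puts pre-soma cells above no-soma cells
  expect_gt(g["pre_soma"], g["no_soma"])
  # ground-truth check of the recruitment magnitude
  act <- gt$astro$soma_active
  expect_equal(unname(g["post_soma"]),
               mean(gt$astro$frac_active_total[act]))
  # all-inactive population: groups are empty/NaN but nothing errors
  gt0 <- simulate_ground_truth(sim_config(n_astrocytes = 30, seed = 801,
                                          p_domain = function(l) 0 * l))
  cmp0 <- compare_pre_no_post(response_table(gt0))
  expect_equal(cmp0$groups$n[cmp0$groups$group == "pre_soma"], 0)
})
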