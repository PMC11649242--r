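test_that("polar transform matches direct per-pixel evaluation", {
  mask <- disc_mask(21, 21, 10, 10, 9)
  fr <- polar_transform(mask, 10, 10, 1.0)
  expect_equal(fr$r_px[11, 11], 0)           # seed pixel
  # 3-4-5 triangle: pixel at (seed_x + 3, seed_y + 4)
  expect_equal(fr$r_px[15, 14], 5)
  expect_equal(fr$theta[15, 14], atan2(4, 3))
  # brute-force oracle over every mask pixel
  set.seed(1)
  pts <- which(mask, arr.ind = TRUE)[sample(sum(mask), 50), ]
  for (i in seq_len(nrow(pts))) {
    y <- unname(pts[i, 1]) - 1; x <- unname(pts[i, 2]) - 1
    expect_equal(fr$r_px[pts[i, 1], pts[i, 2]], sqrt((x - 10)^2 + (y - 10)^2))
    expect_equal(fr$theta[pts[i, 1], pts[i, 2]], atan2(y - 10, x - 10))
  }
  expect_true(all(fr$theta[mask] > -pi & fr$theta[mask] <= pi))
})

test_that("polar transform rejects seeds outside the mask", {
  mask <- disc_mask(21, 21, 10, 10, 5)
  expect_error(polar_transform(mask, 0, 0, 1), "inside")
})

test_that("ring profile averages fluorescence over each annulus", {
  mask <- disc_mask(31, 31, 15, 15, 14)
  fr <- polar_transform(mask, 15, 15, 1)
  # uniform image: every ring mean is the constant
  prof_c <- ring_profile(matrix(7, 31, 31), fr)
  expect_true(all(abs(prof_c$mean[prof_c$n_pixels > 0] - 7) < 1e-12))
  # radius-ramp image: ring mean equals the mean radius within the ring
  img_r <- fr$r_px; img_r[is.na(img_r)] <- 0
  prof_r <- ring_profile(img_r, fr)
  for (j in which(prof_r$n_pixels > 0)) {
    rr <- fr$r_px[mask]
    sel <- rr >= (j - 1) & rr < j
    expect_equal(prof_r$mean[j], mean(rr[sel]))
  }
  # the centre ring of a 1-px-wide ring profile is a single pixel
  expect_equal(prof_r$n_pixels[1], 1L)
  expect_equal(prof_r$mean[1], 0)
})

test_that("soma rule takes the first ring below half the centre fluorescence", {
  prof <- data.frame(ring = 1:5, r_inner_px = 0:4, n_pixels = 5L,
                     mean = c(10, 9, 6, 4, 3), median = NA, sd = NA)
  s <- find_soma(prof)
  expect_true(s$ok)
  expect_equal(s$r_soma_px, 3)
  # monotone-increasing profile never crosses half-max
  prof$mean <- c(1, 2, 3, 4, 5)
  expect_false(find_soma(prof)$ok)
})

test_that("arborization rule keeps pixels above ring median + 0.25 SD", {
  # uniform ring (SD = 0): every non-soma pixel qualifies
  mask <- disc_mask(15, 15, 7, 7, 6)
  fr <- polar_transform(mask, 7, 7, 1)
  img <- matrix(5, 15, 15)
  prof <- ring_profile(img, fr)
  soma <- matrix(FALSE, 15, 15)
  arb <- find_arborization(img, fr, prof, soma)
  expect_true(all(arb[mask]))

  # ring with values {0,0,0,10}: median 0, SD 5 -> only the 10 passes
  expect_equal(sd(c(0, 0, 0, 10)), 5)
  expect_true(10 >= 0 + 0.25 * 5)
  expect_false(0 >= 0 + 0.25 * 5)

  # soma pixels never appear in the arborization
  soma2 <- fr$r_px < 3 & mask
  soma2[is.na(soma2)] <- FALSE
  arb2 <- find_arborization(img, fr, prof, soma2)
  expect_false(any(arb2 & soma2))
})

test_that("the field default pixel size yields a 3x3 px domain grid cell", {
  expect_equal(floor(4.3 / 1.43), 3)
})

test_that("domain grid tiles, clips and never overlaps", {
  # full 9x9 block with a 3-px grid: 9 complete domains
  arb <- matrix(FALSE, 12, 12)
  arb[2:10, 2:10] <- TRUE
  terr <- arb
  gd <- grid_domains(arb, terr, pixel_size_um = 1.43)
  expect_equal(nrow(gd$catalog), 9)
  expect_true(all(gd$catalog$area_px == 9))

  # random mask: union of domain pixels = arborization minus discarded cells
  set.seed(2)
  arb_r <- matrix(runif(400) < 0.5, 20, 20)
  terr_r <- matrix(TRUE, 20, 20)
  gd_r <- grid_domains(arb_r, terr_r, pixel_size_um = 1.43, min_pixels = 4)
  lab <- gd_r$label
  expect_true(all(lab[!arb_r] == 0))           # domains only on arbor pixels
  kept <- lab > 0
  # pixels dropped are exactly those in cells with < 4 arbor pixels
  side <- 3
  gx <- (col(arb_r) - 1) %/% side
  gy <- (row(arb_r) - 1) %/% side
  cnt <- table(paste(gx[arb_r], gy[arb_r]))
  small <- names(cnt)[cnt < 4]
  dropped <- arb_r & paste(gx, gy) %in% small
  expect_identical(kept, arb_r & !dropped)
  # no overlap: every labelled pixel belongs to exactly one domain
  expect_equal(sum(gd_r$catalog$area_px), sum(kept))
})

test_that("segmentation of a synthetic astrocyte satisfies the partition invariants", {
  cfg <- tiny_config(seed = 31)
  pop <- simulate_population(cfg)
  seg <- segment_astrocyte(pop$structural, pop$territory_mask == 1,
                           pop$soma_seeds$x_px[1], pop$soma_seeds$y_px[1],
                           cfg$pixel_size_um)
  expect_true(seg$ok)
  expect_false(any(seg$soma_mask & seg$arb_mask))          # disjoint
  expect_true(all((seg$domain_label > 0) <= seg$arb_mask)) # domains in arbor
  terr <- pop$territory_mask == 1
  expect_true(all(seg$soma_mask <= terr))
  expect_true(all(seg$arb_mask <= terr))
  # domain bounding boxes at most 3x3 px = 4.29 um <= 4.3 um
  expect_true(all(seg$domains$area_px <= 9))
  # recovered soma radius within one ring of the analytic half-max
  expect_lt(abs(seg$r_soma_um - analytic_half_max_um(cfg)),
            cfg$pixel_size_um + 1e-9)
})

test_that("soma radius is stable under a 90-degree rotation", {
  cfg <- tiny_config(seed = 33)
  pop <- simulate_population(cfg)
  mask <- pop$territory_mask == 1
  img <- pop$structural
  seg <- segment_astrocyte(img, mask, pop$soma_seeds$x_px[1],
                           pop$soma_seeds$y_px[1], cfg$pixel_size_um)
  rot <- function(m) t(m[nrow(m):1, ])     # 90 deg clockwise
  # rotated seed: (x, y) -> (nrow - 1 - y, x) in 0-based coordinates
  sx <- nrow(img) - 1 - pop$soma_seeds$y_px[1]
  sy <- pop$soma_seeds$x_px[1]
  seg_r <- segment_astrocyte(rot(img), rot(mask), sx, sy, cfg$pixel_size_um)
  expect_true(seg$ok && seg_r$ok)
  expect_lte(abs(seg$r_soma_px - seg_r$r_soma_px), 1)
})

test_that("soma recovery holds across seeded astrocytes at SNR >= 5", {
  hits <- 0
  for (s in 1:20) {
    cfg <- tiny_config(seed = 300 + s, struct_noise_sd = 0.2)  # SNR 5
    pop <- simulate_population(cfg)
    seg <- segment_astrocyte(pop$structural, pop$territory_mask == 1,
                             pop$soma_seeds$x_px[1], pop$soma_seeds$y_px[1],
                             cfg$pixel_size_um)
    if (seg$ok &&
        abs(seg$r_soma_um - analytic_half_max_um(cfg)) <= cfg$pixel_size_um)
      hits <- hits + 1
  }
  expect_equal(hits, 20)
})
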