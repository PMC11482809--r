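test_that("rolling ball removes flat and gradient backgrounds, keeps peaks", {
  # constant image maps to zero
  expect_equal(max(rolling_ball_subtract(matrix(5, 50, 50), 10)), 0)

  # narrow impulse on a flat background survives within 5 percent
  imp <- matrix(10, 60, 60); imp[30, 30] <- 110
  out <- rolling_ball_subtract(imp, 10)
  expect_equal(out[30, 30], 100, tolerance = 0.05 * 100)
  expect_lt(mean(out[imp == 10]), 0.5)

  # linear illumination gradient is removed exactly away from the border
  grad <- outer(1:70, 1:70, function(i, j) 10 + 0.3 * j)
  res <- rolling_ball_subtract(grad, 10)
  expect_equal(max(res[11:60, 11:60]), 0)
  expect_lt(max(res), 0.05 * max(grad))  # border residual stays small

  expect_error(rolling_ball_subtract(matrix(1, 10, 10), 20), "exceeds")
  expect_error(rolling_ball_subtract(matrix(1, 10, 10), 0.2), ">= 1")
})

test_that("rolling ball separates filaments from uneven illumination", {
  s <- simulate_tirf(0.94, field_size = 128, n_filaments = 8, seed = 31)
  corr <- rolling_ball_subtract(s$tetramer, 15)
  bound_px <- do.call(rbind, mapply(function(st, b) st[b, , drop = FALSE],
                                    s$truth$sites, s$truth$bound,
                                    SIMPLIFY = FALSE))
  fil_mask <- matrix(FALSE, 128, 128); fil_mask[bound_px] <- TRUE
  # background region: pixels beyond the PSF halo of any filament
  all_px <- do.call(rbind, s$truth$sites)
  halo <- matrix(FALSE, 128, 128); halo[all_px] <- TRUE
  for (dr in -3:3) for (dc in -3:3)
    halo <- halo | filattice:::.shift_mat(`[<-`(matrix(FALSE, 128, 128),
                                                all_px, TRUE), dr, dc)
  peak <- mean(corr$pixels[fil_mask])
  bg <- mean(corr$pixels[!halo])
  expect_lt(bg, 0.02 * peak)
})

test_that("Yen threshold equals exhaustive criterion maximization", {
  set.seed(5)
  fixtures <- list(
    two_level = c(rep(0, 500), rep(100, 500)),
    bimodal = c(rnorm(3000, 20, 4), rnorm(400, 150, 12)),
    skewed = c(rexp(4000, 1 / 10), rnorm(100, 120, 5)),
    sim = as.numeric(simulate_tirf(2, field_size = 96, seed = 3)$tetramer$pixels))
  for (nm in names(fixtures)) {
    v <- pmax(fixtures[[nm]], 0)
    expect_equal(yen_threshold(matrix(v, nrow = 1)), yen_brute_force(v),
                 info = nm)
  }
})

test_that("Yen binarization behaves on two-level and rescaled images", {
  img <- matrix(c(rep(0, 500), rep(100, 500)), 25, 40)
  thr <- yen_threshold(img)
  expect_gt(thr, 0); expect_lt(thr, 100)
  expect_equal(sum(yen_binarize(img)), 500)

  # scale invariance up to binning: same mask under a*img
  s <- simulate_tirf(2, field_size = 96, seed = 13)
  m1 <- yen_binarize(s$tetramer$pixels)
  m2 <- yen_binarize(3.7 * s$tetramer$pixels)
  expect_gt(mean(m1 == m2), 0.999)

  expect_error(yen_threshold(matrix(1, 5, 5)), "degenerate")
})

test_that("fraction bound is the conjunction area over the filament area", {
  a <- matrix(FALSE, 10, 10); a[3:7, 5] <- TRUE
  t0 <- matrix(FALSE, 10, 10)
  expect_equal(fraction_bound(a, t0), 0)
  expect_equal(fraction_bound(a, !t0), 1)
  t1 <- t0; t1[3:4, 5] <- TRUE
  expect_equal(fraction_bound(a, t1), 2 / 5)
  # monotone in the tetramer mask
  t2 <- t1; t2[5, 5] <- TRUE
  expect_gte(fraction_bound(a, t2), fraction_bound(a, t1))
  expect_error(fraction_bound(t0, t1), "empty")
})

test_that("simulator is deterministic and hits the Hill equilibrium", {
  s1 <- simulate_tirf(0.94, seed = 7)
  s2 <- simulate_tirf(0.94, seed = 7)
  expect_identical(s1$actin$pixels, s2$actin$pixels)
  expect_identical(s1$tetramer$pixels, s2$tetramer$pixels)

  # midpoint: concentration = kd gives bound fraction 0.5 +- 0.02
  expect_equal(s1$truth$bound_fraction, 0.5, tolerance = 0.02 / 0.5)

  # zero concentration: no binding
  s0 <- simulate_tirf(0, seed = 7)
  expect_equal(s0$truth$bound_fraction, 0)
})

test_that("mask pipeline recovers simulated bound fractions", {
  # single field at truth ~0.40
  c40 <- 0.94 * (0.4 / 0.6)^(1 / 2.7)
  s <- simulate_tirf(c40, seed = 5)
  est <- analyze_tirf_field(s$actin, s$tetramer, radius = 15)$fraction_bound
  expect_equal(est, s$truth$bound_fraction, tolerance = 0.05 / 0.4)

  # 20 fields across the titration range: RMSE below 0.05
  concs <- rep(10^seq(log10(0.1), log10(10), length.out = 10), 2)
  est <- tru <- numeric(length(concs))
  for (i in seq_along(concs)) {
    si <- simulate_tirf(concs[i], seed = 1000 + i)
    est[i] <- analyze_tirf_field(si$actin, si$tetramer,
                                 radius = 15)$fraction_bound
    tru[i] <- si$truth$bound_fraction
  }
  expect_lt(sqrt(mean((est - tru)^2)), 0.05)
})

test_that("FWHM matches closed forms and ratio is 1 for identical scans", {
  x <- seq(-30, 30, by = 0.5)
  g <- exp(-x^2 / (2 * 4^2))
  expect_equal(fwhm(g, 0.5), 2.3548 * 4, tolerance = 0.02)

  tri <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0)
  expect_equal(fwhm(tri), 5)  # base 10 triangle: width at half height

  expect_equal(fwhm_ratio(g, g, 0.5), 1)
  expect_error(fwhm(c(1, 2, 3)), "unbounded")
})

test_that("co-sedimentation correction subtracts the no-filament control", {
  expect_equal(cosed_fraction(30, 70, 90, 10), 0.6)
  expect_equal(cosed_fraction(50, 50, 10, 0), 0.5)
  expect_equal(cosed_fraction(1, 0, 1, 0), 0)
  # control exceeding the raw fraction clips at zero
  expect_equal(cosed_fraction(80, 20, 10, 90), 0)
  expect_error(cosed_fraction(0, 0, 1, 1), "zero total")
})
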