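test_that("difference in means matches closed-form oracles", {
  d <- rnorm(500)
  expect_equal(difference_in_means(d, d)$center, 0)
  ci <- difference_in_means(d + 0.7, d)
  expect_equal(ci$center, 0.7, tolerance = 1e-12)
  expect_equal(ci$upper - ci$lower, 0, tolerance = 1e-12)

  set.seed(31)
  fo <- rnorm(1e4, 55.6, 0.05)
  po <- rnorm(1e4, 55.0, 0.05)
  ci <- difference_in_means(fo, po)
  # difference of normals: N(0.6, sqrt(0.005)); symmetric 94% quantile
  expect_equal(ci$center, 0.6, tolerance = 0.01)
  expect_equal(ci$upper, 0.6 + qnorm(0.97) * sqrt(0.005), tolerance = 0.02)
  expect_equal(ci$lower, 0.6 - qnorm(0.97) * sqrt(0.005), tolerance = 0.02)
})

test_that("effect size standardizes by the pooled standard deviation", {
  expect_equal(effect_size(rep(1, 10), rep(0, 10), rep(1, 10),
                           rep(1, 10))$center, 1)
  expect_equal(effect_size(rep(0.5, 10), rep(0, 10), rep(0.25, 10),
                           rep(0.75, 10))$center, 0.5 / sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(effect_size(rep(3, 10), rep(3, 10), rep(0.2, 10),
                           rep(0.9, 10))$center, 0)
  expect_error(effect_size(rep(1, 10), rep(0, 10), rep(-1, 10), rep(1, 10)),
               "positive")
})

test_that("discrimination decision applies both thresholds to CI centers", {
  tol <- tolerance_config()
  ci <- function(center, half = 0) {
    credible_interval(c(center - half, center + half), 0.94)
  }
  # CA: diff 0.45 ppm, effect 0.9 -> passes
  d <- has_discrimination_power(ci(0.45), ci(0.9), "CA", tol)
  expect_true(d$passes)
  # effect too small
  d <- has_discrimination_power(ci(0.45), ci(0.3), "CA", tol)
  expect_false(d$passes)
  expect_true(d$passes_diff)
  # nitrogen tolerance is 0.5: |-0.4| fails even with huge effect
  d <- has_discrimination_power(ci(-0.4), ci(-2), "N", tol)
  expect_false(d$passes)
  expect_false(d$passes_diff)
  expect_true(d$passes_effect)
  # only centers matter: a wide interval straddling zero still passes
  wide <- credible_interval(c(0.45 - 3, 0.45 + 3), 0.94)
  d <- has_discrimination_power(wide, ci(2), "CA", tol)
  expect_true(d$passes)
})

test_that("translation and scale behaviour of the two criteria", {
  set.seed(32)
  mk <- function(mu, sd, n = 2000) rnorm(n, mu, sd)
  fo_m <- mk(55.9, 0.02); po_m <- mk(55.0, 0.02)
  fo_v <- mk(0.09, 0.002)^0 * 0.09; po_v <- rep(0.16, 2000)
  d0 <- difference_in_means(fo_m, po_m)
  e0 <- effect_size(fo_m, po_m, fo_v, po_v)
  # adding a constant to both states changes nothing
  d1 <- difference_in_means(fo_m + 3.7, po_m + 3.7)
  e1 <- effect_size(fo_m + 3.7, po_m + 3.7, fo_v, po_v)
  expect_equal(d1$center, d0$center, tolerance = 1e-12)
  expect_equal(e1$center, e0$center, tolerance = 1e-12)
  # scaling shifts and tolerances by c scales diff, fixes effect
  cc <- 2.5
  d2 <- difference_in_means(cc * fo_m, cc * po_m)
  e2 <- effect_size(cc * fo_m, cc * po_m, cc^2 * fo_v, cc^2 * po_v)
  expect_equal(d2$center, cc * d0$center, tolerance = 1e-12)
  expect_equal(e2$center, e0$center, tolerance = 1e-12)
  # swapping the states negates both centers
  d3 <- difference_in_means(po_m, fo_m)
  e3 <- effect_size(po_m, fo_m, po_v, fo_v)
  expect_equal(d3$center, -d0$center, tolerance = 1e-12)
  expect_equal(e3$center, -e0$center, tolerance = 1e-12)
})

test_that("discriminate_states walks a fit store and flags passers", {
  ent <- expand.grid(residue_number = c(50L, 60L), state = c("PO", "FO"),
                     stringsAsFactors = FALSE)
  ent$residue_type <- "A"; ent$atom <- "CA"; ent$method <- "SPARTA+"
  # residue 50: FO-PO gap 1 ppm, tiny variance -> passes
  # residue 60: identical -> fails
  ent$fit <- lapply(seq_len(nrow(ent)), function(i) {
    gap <- if (ent$residue_number[i] == 50L && ent$state[i] == "FO") 1 else 0
    fake_fit(mu = rnorm(200, 55 + gap, 0.01), sigma = 0.2, alpha = 0)
  })
  disc <- discriminate_states(fake_store(ent), "FO", "PO")
  expect_equal(nrow(disc), 2L)
  expect_equal(disc$passes, disc$residue_number == 50L)
  expect_equal(disc$diff_center[disc$residue_number == 50L], 1,
               tolerance = 0.02)
})
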