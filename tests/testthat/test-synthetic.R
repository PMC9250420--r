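test_that("sampled ensembles converge to the analytic moments", {
  sc <- preset_scenario("e2_panel", n_frames = 2500) # 10k points per row
  p <- sc$params[sc$params$state == "PO" & sc$params$atom == "CA", ][1, ]
  rec <- sample_ensemble(sc, p$residue_number, "CA", "PO", "SPARTA+")
  expect_equal(nrow(rec), 4L * 2500L)
  m <- skewnorm_mean(p$mu, p$sigma, p$alpha)
  v <- skewnorm_var(p$mu, p$sigma, p$alpha)
  expect_lt(abs(mean(rec$shift_ppm) - m), 4 * sqrt(v / nrow(rec)))
  expect_equal(var(rec$shift_ppm), v, tolerance = 0.1)
})

test_that("mixture contamination is visibly bimodal in large samples", {
  sc <- preset_scenario("bimodal_stress", n_frames = 2500)
  p <- sc$params
  i <- which(p$state == "PO" & p$atom == "CA")[1]
  rec <- shiftstate:::sample_param_row(sc, i)
  x <- rec$shift_ppm
  # mixture mean matches the weighted analytic mean
  m <- shiftstate:::row_pop_mean(p[i, ])
  expect_equal(mean(x), m, tolerance = 0.05)
  # density at the midpoint between modes dips below both mode heights
  dens <- density(x)
  mid <- skewnorm_mean(p$mu[i], p$sigma[i], p$alpha[i]) + p$mix_delta[i] / 2
  d_mid <- approx(dens$x, dens$y, mid)$y
  d_lo <- approx(dens$x, dens$y, mid - p$mix_delta[i] / 2)$y
  d_hi <- approx(dens$x, dens$y, mid + p$mix_delta[i] / 2)$y
  expect_lt(d_mid, 0.8 * min(d_lo, d_hi))
})

test_that("scenario emission is byte-identical for a fixed seed", {
  sc <- preset_scenario("b1_panel", n_frames = 20)
  a <- sample_scenario(sc)
  b <- sample_scenario(sc)
  expect_identical(a, b)
  ea <- make_experimental_tables(sc)
  eb <- make_experimental_tables(sc)
  expect_identical(ea, eb)
  sc2 <- preset_scenario("b1_panel", n_frames = 20, seed = 2)
  expect_false(identical(a, sample_scenario(sc2)))
})

test_that("experimental tables reflect the designated true state", {
  sc <- preset_scenario("e2_panel", n_frames = 20)
  sc$experimental_noise_sd <- 0
  ex <- make_experimental_tables(sc)
  p <- sc$params
  # noise-free activated shift equals the PO population mean exactly
  po_ca <- p[p$state == "PO" & p$atom == "CA", ][1, ]
  got <- ex$shift_ppm[ex$residue_number == po_ca$residue_number &
                        ex$atom == "CA" & ex$condition == "activated"]
  expect_equal(got, skewnorm_mean(po_ca$mu, po_ca$sigma, po_ca$alpha),
               tolerance = 1e-12)
  # spectator scenario: both conditions coincide without noise
  sp <- preset_scenario("spectator_only", n_frames = 20)
  sp$experimental_noise_sd <- 0
  ex <- make_experimental_tables(sp)
  act <- ex[ex$condition == "activated", "shift_ppm"]
  deact <- ex[ex$condition == "deactivated", "shift_ppm"]
  expect_equal(act, deact, tolerance = 1e-12)
})

test_that("planted classes are verified analytically at construction", {
  sc <- preset_scenario("b1_panel", n_frames = 20)
  expect_s3_class(sc, "sn_scenario")
  # claiming E2 for a spectator panel must fail verification
  params <- preset_scenario("spectator_only", n_frames = 20)$params
  planted <- unique(params[, c("residue_number", "residue_type", "atom")])
  planted$class <- "E2"
  expect_error(
    synthetic_scenario(params, n_frames = 20, planted_class = planted),
    "not achievable")
})

test_that("relabeling the open states mirrors the scenario exactly", {
  sc <- preset_scenario("e2_panel", n_frames = 20)
  flip <- sc
  flip$params$state <- c(C = "C", PO = "FO", FO = "PO")[sc$params$state]
  flip$true_state <- "FO"
  a <- sample_scenario(sc)
  b <- sample_scenario(flip)
  expect_equal(a$shift_ppm, b$shift_ppm)
  expect_equal(b$state, c(C = "C", PO = "FO", FO = "PO")[a$state],
               ignore_attr = TRUE)
})

test_that("scenario tables round-trip through disk", {
  sc <- preset_scenario("spectator_only", n_frames = 5)
  dir <- tempfile()
  expect_message(paths <- write_scenario_tables(sc, dir), "seed")
  preds <- read_prediction_table(file.path(dir, "predictions.tsv"),
                                 "generic_long")
  expect_equal(nrow(preds), nrow(sc$params) * 4 * 5)
  exps <- read_experimental_table(file.path(dir, "experimental.tsv"))
  expect_equal(nrow(exps), 2 * nrow(unique(sc$params[, 1:3])))
})
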