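test_that("simulated difference shifts follow the difference-of-normals oracle", {
  d <- rnorm(300, 50, 0.1)
  expect_equal(delta_cs_sim(d, d)$ci$center, 0)
  expect_equal(delta_cs_sim(d + 1.3, d)$ci$center, 1.3, tolerance = 1e-12)
  set.seed(41)
  x <- rnorm(1e4, 57.1, 0.1)
  cc <- rnorm(1e4, 56.2, 0.1)
  ci <- delta_cs_sim(x, cc)$ci
  expect_equal(ci$center, 0.9, tolerance = 0.01)
})

test_that("experimental difference shift is simple arithmetic", {
  expect_equal(delta_cs_exp(57.4, 57.4), 0)
  expect_equal(delta_cs_exp(120.8, 121.6), -0.8)
  expect_error(delta_cs_exp(c(1, 2), 1))
})

test_that("marker status uses a strict per-isotope threshold", {
  expect_equal(marker_status(0.15, "CA"), "spectator")
  expect_equal(marker_status(-0.7, "N"), "marker")
  expect_equal(marker_status(0.2, "CA"), "spectator")   # boundary: strict
  expect_equal(marker_status(0.5, "N"), "spectator")
  expect_equal(marker_status(0.21, "CB"), "marker")
})

test_that("state verdicts compare discrepancy centers under the tolerance gate", {
  ci <- function(x) credible_interval(rep(x, 3), 0.94)
  expect_equal(assign_state(ci(0.08), ci(0.12), "CA"), "undetermined")
  expect_equal(assign_state(ci(0.10), ci(0.55), "CA"), "PO")
  expect_equal(assign_state(ci(0.9), ci(0.6), "N"), "FO")
  expect_equal(assign_state(ci(0.3), ci(0.3), "CA"), "undetermined")
  # symmetry: swapping the inputs swaps the verdicts
  expect_equal(assign_state(ci(0.55), ci(0.10), "CA"), "FO")
})

test_that("verdict tallies count nuclei and residue majorities", {
  v <- data.frame(residue_number = c(50L, 50L, 51L, 52L),
                  residue_type = "A",
                  atom = c("CA", "CB", "CA", "N"),
                  method = "SPARTA+",
                  verdict = c("PO", "PO", "FO", "undetermined"),
                  stringsAsFactors = FALSE)
  t_nuc <- tally_verdicts(v, "nucleus")
  expect_equal(unname(t_nuc), c(50, 25, 25))
  expect_equal(sum(t_nuc), 100)

  # one residue with {PO, PO, FO} nuclei -> PO; {PO, FO} tie -> undetermined
  v2 <- data.frame(residue_number = c(50L, 50L, 50L, 60L, 60L),
                   residue_type = "A",
                   atom = c("CA", "CB", "C", "CA", "CB"),
                   method = "SPARTA+",
                   verdict = c("PO", "PO", "FO", "PO", "FO"),
                   stringsAsFactors = FALSE)
  t_res <- tally_verdicts(v2, "residue")
  expect_equal(unname(t_res), c(50, 0, 50))
})

test_that("method disagreement makes a nucleus undetermined in residue tallies", {
  v <- data.frame(residue_number = 50L, residue_type = "A", atom = "CA",
                  method = c("SPARTA+", "SHIFTX2"),
                  verdict = c("PO", "FO"), stringsAsFactors = FALSE)
  t_res <- tally_verdicts(v, "residue")
  expect_equal(unname(t_res), c(0, 0, 100))
})

test_that("absolute RMSE and bias recentering behave as point diagnostics", {
  expect_equal(rmse_absolute(c(a = 1, b = 2), c(a = 1, b = 2)), 0)
  expect_equal(rmse_absolute(c(a = 1, b = 2), c(a = 0, b = 0)), sqrt(2.5))
  expect_equal(rmse_absolute(c(a = 3), c(a = 1)), 2)
  expect_error(rmse_absolute(c(a = 1), c(b = 1)), "no shared")

  rc <- recenter_bias(rep(0.4, 6))
  expect_equal(rc$corrected, rep(0, 6))
  expect_equal(rc$centers$center, 0.4)

  set.seed(42)
  d <- rnorm(100, 0.3, 0.1)
  rc <- recenter_bias(d)
  expect_equal(rc$centers$center, 0.3, tolerance = 3 * 0.1 / sqrt(100))
  expect_equal(mean(rc$corrected), 0, tolerance = 1e-12)

  expect_message(rc <- recenter_bias(c(1, 2), min_n = 5), "fewer than")
  expect_true(is.na(rc$centers$center))
  expect_equal(rc$corrected, c(1, 2))
})

test_that("assign_states produces verdicts with marker status end to end", {
  states <- c("C", "PO", "FO")
  ent <- expand.grid(residue_number = 50L, state = states,
                     stringsAsFactors = FALSE)
  ent$residue_type <- "A"; ent$atom <- "CA"; ent$method <- "SPARTA+"
  mus <- c(C = 55, PO = 55.7, FO = 54.3)
  ent$fit <- lapply(seq_len(nrow(ent)), function(i)
    fake_fit(mu = rnorm(300, mus[ent$state[i]], 0.01), sigma = 0.2,
             alpha = 0))
  store <- fake_store(ent)
  disc <- discriminate_states(store, "FO", "PO")
  expect_true(disc$passes)
  exps <- data.frame(residue_number = 50L, residue_type = "A", atom = "CA",
                     condition = c("activated", "deactivated"),
                     shift_ppm = c(55.68, 55.0), stringsAsFactors = FALSE)
  v <- assign_states(store, disc, exps)
  expect_equal(v$verdict, "PO")
  expect_equal(v$marker_status, "marker")
  expect_equal(v$exp_delta, 0.68)
  expect_lt(v$dd_po_center, v$dd_fo_center)
})
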