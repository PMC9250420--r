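# write a minimal 4-chain PDB with one CA per chain at given coordinates
write_tetramer_pdb <- function(xyz, resno = 112L, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(1:4, function(i) {
    sprintf("ATOM  %5d  CA  THR %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, LETTERS[i], resno, xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

test_that("gate distance on a square is the exact diagonal", {
  d <- 10
  sq <- rbind(c(d / 2, d / 2, 0), c(-d / 2, d / 2, 0),
              c(-d / 2, -d / 2, 0), c(d / 2, -d / 2, 0))
  g <- gate_distance(write_tetramer_pdb(sq), 112)
  expect_equal(g$mean, d * sqrt(2), tolerance = 1e-9)
  expect_equal(g$diagonals, rep(d * sqrt(2), 2), tolerance = 1e-9)
})

test_that("gate distance is invariant under rigid motion and chain order", {
  set.seed(51)
  pts <- rbind(c(7, 7.5, 0), c(-7.2, 6.8, 1), c(-6.9, -7.1, 0.5),
               c(7.3, -7.4, -0.2))
  g0 <- gate_distance(write_tetramer_pdb(pts), 112)
  # random rotation (QR of a random matrix) + translation
  qr_r <- qr.Q(qr(matrix(rnorm(9), 3)))
  moved <- t(qr_r %*% t(pts)) + matrix(rep(c(11, -4, 3), each = 4), ncol = 3)
  g1 <- gate_distance(write_tetramer_pdb(moved), 112)
  # coordinates are written at 0.001 A precision
  expect_equal(sort(g1$diagonals), sort(g0$diagonals), tolerance = 1e-4)
  # permuting chains leaves the diagonal pairing intact
  g2 <- gate_distance(write_tetramer_pdb(pts[c(2, 4, 1, 3), ]), 112)
  expect_equal(sort(g2$diagonals), sort(g0$diagonals), tolerance = 1e-9)
})

test_that("missing atoms are reported with the chains found", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  THR A 112      10.000  10.000   0.000  1.00  0.00           C",
    "END"), path)
  expect_error(gate_distance(path, 112), "chain")
})

test_that("water-entry exclusion truncates the usable window", {
  w <- exclude_after_water_entry(400L, 1000L)
  expect_equal(c(w$start, w$end), c(0L, 400L))
  w <- exclude_after_water_entry(NULL, 1000L)
  expect_equal(c(w$start, w$end), c(0L, 1000L))
  expect_warning(w <- exclude_after_water_entry(1200L, 1000L), "full window")
  expect_equal(w$end, 1000L)
  expect_error(exclude_after_water_entry(0L, 1000L), "no usable")
})

test_that("stable-gate selection honours explicit and heuristic modes", {
  tm <- seq(0, 999)
  s <- gate_series(tm, rep(14, 1000))
  w <- stable_gate_window(s, explicit = c(400, 1000))
  expect_equal(c(w$start, w$end), c(400L, 1000L))
  # constant series: heuristic keeps everything
  w <- stable_gate_window(s, window_length = 10, max_drift = 0.5)
  expect_equal(c(w$start, w$end), c(0L, 1000L))
  # 2 A step at midpoint with 0.5 A bound: second half survives
  stepped <- gate_series(tm, c(rep(14, 500), rep(16, 500)))
  w <- stable_gate_window(stepped, window_length = 10, max_drift = 0.5)
  expect_equal(w$end, 1000L)
  expect_gte(w$start, 490L)
  expect_lte(w$start, 510L)
  # brute-force oracle: every rolling mean inside the window is within bound
  roll <- stats::filter(stepped$distance, rep(0.1, 10), sides = 1)
  inside <- roll[(w$start + 10):1000]
  expect_lte(max(inside) - min(inside), 0.5)
  expect_error(stable_gate_window(gate_series(0:9, 1:10 * 5),
                                  window_length = 2, max_drift = 0.1),
               "no stable")
})

test_that("window composition is an intersection of end-anchored intervals", {
  water <- exclude_after_water_entry(700L, 1000L)
  s <- gate_series(0:999, c(rep(20, 300), rep(22, 700)))
  stable <- stable_gate_window(s, window_length = 10, max_drift = 0.5)
  lo <- max(water$start, stable$start)
  hi <- min(water$end, stable$end)
  expect_true(lo < hi)
  expect_equal(c(lo, hi), c(stable$start, water$end))
})

test_that("occupancy strings round-trip and validate", {
  expect_equal(occupancy_string(c("W", "K", "K", "0", "K", "W")), "WKK0KW")
  expect_equal(occupancy_string(rep("K", 6)), "KKKKKK")
  expect_error(occupancy_string(c("W", "K", "K", "0", "K")), "expected 6")
  expect_error(occupancy_string(c("W", "K", "K", "0", "K", "X")), "unknown")
  expect_equal(parse_occupancy("WKK0KW"), c("W", "K", "K", "0", "K", "W"))
})
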