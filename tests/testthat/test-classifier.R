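# independent oracle for the flowchart, written directly from its rules:
# A none distinct; B only FO distinct (from both C and PO); C only PO
# distinct; D C distinct from both opens which match; E all distinct;
# subtype 1/2 by experimental marker status, A unsubtyped
flowchart_oracle <- function(dpo_c, dfo_c, dfo_po, exp_marker) {
  letter <- if (!dpo_c && !dfo_c && !dfo_po) "A"
  else if (!dpo_c && dfo_c && dfo_po) "B"
  else if (dpo_c && !dfo_c && dfo_po) "C"
  else if (dpo_c && dfo_c && !dfo_po) "D"
  else if (dpo_c && dfo_c && dfo_po) "E"
  else NA_character_
  if (is.na(letter)) return(NA_character_)
  if (letter == "A") "A" else paste0(letter, if (exp_marker) "2" else "1")
}

test_that("all regular patterns match a hand-enumerated truth table", {
  cases <- expand.grid(dpo_c = c(FALSE, TRUE), dfo_c = c(FALSE, TRUE),
                       dfo_po = c(FALSE, TRUE), exp_marker = c(FALSE, TRUE))
  n_regular <- 0L
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- classify_marker(cs$dpo_c, cs$dfo_c, cs$dfo_po, cs$exp_marker)
    want <- flowchart_oracle(cs$dpo_c, cs$dfo_c, cs$dfo_po, cs$exp_marker)
    if (!is.na(want)) {
      expect_equal(got$class, want)
      expect_false(got$irregular)
      n_regular <- n_regular + 1L
    } else {
      expect_true(got$irregular)
      expect_true(got$letter %in% c("A", "B", "C", "D", "E"))
    }
  }
  expect_equal(n_regular, 10L) # 5 patterns x 2 marker states
})

test_that("every boolean combination returns a class without error", {
  for (p1 in c(TRUE, FALSE)) for (p2 in c(TRUE, FALSE))
    for (p3 in c(TRUE, FALSE)) for (m in c(TRUE, FALSE)) {
      got <- classify_marker(p1, p2, p3, m)
      expect_match(got$class, "^(A|[BCDE][12])$")
      # purity: same inputs, same answer
      expect_identical(got, classify_marker(p1, p2, p3, m))
    }
})

test_that("class D never survives the open-vs-open discrimination filter", {
  # a passer has |FO-PO difference| above tolerance, so dfo_po is TRUE for
  # every passer under the tolerance rule; D requires dfo_po FALSE
  for (m in c(TRUE, FALSE)) {
    got <- classify_marker(TRUE, TRUE, TRUE, m)
    expect_false(got$letter == "D")
  }
  d <- classify_marker(TRUE, TRUE, FALSE, FALSE)
  expect_equal(d$letter, "D")
})

test_that("classify_all unions classes over methods per nucleus", {
  delta <- data.frame(residue_number = c(50L, 50L),
                      residue_type = "A", atom = "CA",
                      method = c("SPARTA+", "SHIFTX2"),
                      delta_po_center = c(0.9, 0.05),
                      delta_fo_center = c(0.9, 0.9),
                      stringsAsFactors = FALSE)
  disc <- data.frame(residue_number = c(50L, 50L), residue_type = "A",
                     atom = "CA", method = c("SPARTA+", "SHIFTX2"),
                     diff_center = c(0.8, 0.8), passes = TRUE,
                     stringsAsFactors = FALSE)
  markers <- data.frame(residue_number = 50L, residue_type = "A",
                        atom = "CA", exp_delta = 0.5,
                        stringsAsFactors = FALSE)
  got <- classify_all(delta, disc, markers)
  # SPARTA+: all distinct + marker -> E2; SHIFTX2: only FO distinct -> B2
  expect_equal(sort(got$per_method$class), c("B2", "E2"))
  expect_equal(got$per_nucleus$classes, "B2,E2")

  # agreeing methods give a single class
  delta$delta_po_center <- c(0.05, 0.05)
  got <- classify_all(delta, disc, markers)
  expect_equal(got$per_nucleus$classes, "B2")

  # a nucleus missing from the discrimination table is skipped with a log
  disc2 <- disc[disc$method == "SPARTA+", ]
  expect_message(got <- classify_all(delta, disc2, markers), "skipping")
  expect_equal(nrow(got$per_method), 1L)
})
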