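#' Simulated difference shift against the reference (closed) state
#'
#' Per-draw difference between a candidate state's distribution-mean draws
#' and the reference state's, with its credible interval. Working with
#' difference shifts cancels systematic prediction and referencing offsets:
#' adding a constant to every simulated shift leaves these differences
#' unchanged.
#'
#' @param mean_draws_x mean draws of the candidate state.
#' @param mean_draws_ref mean draws of the reference (closed) state.
#' @param mass credible mass.
#' @return list with `draws` and `ci` (a `credint`).
#' @export
delta_cs_sim <- function(mean_draws_x, mean_draws_ref, mass = 0.94) {
  n <- min(length(mean_draws_x), length(mean_draws_ref))
  d <- mean_draws_x[seq_len(n)] - mean_draws_ref[seq_len(n)]
  list(draws = d, ci = credible_interval(d, mass))
}

#' Experimental difference shift between conditions
#'
#' Activated-condition shift minus deactivated-condition shift for one
#' nucleus, in ppm.
#'
#' @param activated,deactivated scalar experimental shifts (ppm).
#' @return scalar difference.
#' @export
delta_cs_exp <- function(activated, deactivated) {
  stopifnot(length(activated) == 1L, length(deactivated) == 1L,
            is.finite(activated), is.finite(deactivated))
  activated - deactivated
}

#' Marker or spectator status of an experimental resonance
#'
#' A nucleus is an experimental *marker* when its shift difference between
#' the activated and deactivated conditions exceeds the per-isotope
#' tolerance in absolute value (strictly — a difference exactly at tolerance
#' is conservatively a spectator).
#'
#' @param exp_delta experimental difference shift (ppm).
#' @param atom atom name.
#' @param tol a [tolerance_config()].
#' @return `"marker"` or `"spectator"`.
#' @export
marker_status <- function(exp_delta, atom, tol = tolerance_config()) {
  ifelse(abs(exp_delta) > tolerance_for(atom, tol), "marker", "spectator")
}

#' State verdict for one discriminating nucleus
#'
#' Compares the credible-interval centers of the absolute discrepancies
#' |delta-delta-CS| for the two candidate states. If both centers are below
#' the per-isotope tolerance the nucleus cannot prefer a state
#' (`"undetermined"`); otherwise the state with the smaller discrepancy
#' center wins; an exact tie is `"undetermined"`.
#'
#' @param dd_po_ci,dd_fo_ci `credint`s of |delta-delta-CS| for the PO-like
#'   and FO-like candidates.
#' @param atom atom name.
#' @param tol a [tolerance_config()].
#' @param labels verdict labels for the two candidates, default
#'   `c("PO", "FO")`.
#' @return one of `labels` or `"undetermined"`.
#' @export
assign_state <- function(dd_po_ci, dd_fo_ci, atom, tol = tolerance_config(),
                         labels = c("PO", "FO")) {
  tl <- tolerance_for(atom, tol)
  a <- dd_po_ci$center
  b <- dd_fo_ci$center
  if (a < tl && b < tl) return("undetermined")
  if (a == b) return("undetermined")
  if (a < b) labels[1] else labels[2]
}

#' Assign states to all discriminating nuclei
#'
#' For every (nucleus, method) passing the discrimination filter, computes
#' the simulated difference shifts of both candidate states against the
#' reference state, the experimental difference shift, the per-draw absolute
#' discrepancy |delta-delta-CS| with its credible interval, the verdict, and
#' the experimental marker status.
#'
#' @param fits fit store from [fit_ensembles()].
#' @param discrimination output of [discriminate_states()].
#' @param experiments experimental-shift data.frame.
#' @param reference_state reference (closed) state label.
#' @param candidate_states the two candidate labels, PO-like first.
#' @param tol a [tolerance_config()].
#' @param only_passing restrict to discrimination passers (default TRUE).
#' @return data.frame of per-(nucleus, method) verdicts.
#' @export
assign_states <- function(fits, discrimination, experiments,
                          reference_state = "C",
                          candidate_states = c("PO", "FO"),
                          tol = tolerance_config(), only_passing = TRUE) {
  rows <- if (only_passing)
    discrimination[discrimination$passes, , drop = FALSE] else discrimination
  if (!nrow(rows)) return(data.frame())
  eid <- nucleus_id(experiments)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    id <- paste(r$residue_number, r$residue_type, r$atom, sep = "_")
    act <- experiments$shift_ppm[eid == id &
                                   experiments$condition == "activated"]
    deact <- experiments$shift_ppm[eid == id &
                                     experiments$condition == "deactivated"]
    if (length(act) != 1L || length(deact) != 1L) {
      message("skipping ", id, ": missing experimental condition")
      return(NULL)
    }
    fref <- fit_lookup(fits, r$residue_number, r$residue_type, r$atom,
                       reference_state, r$method)
    fpo <- fit_lookup(fits, r$residue_number, r$residue_type, r$atom,
                      candidate_states[1], r$method)
    ffo <- fit_lookup(fits, r$residue_number, r$residue_type, r$atom,
                      candidate_states[2], r$method)
    if (is.null(fref) || is.null(fpo) || is.null(ffo)) {
      message("skipping ", id, ": missing posterior for a state")
      return(NULL)
    }
    ed <- delta_cs_exp(act, deact)
    mref <- mean_draws(fref)
    d_po <- delta_cs_sim(mean_draws(fpo), mref, tol$ci_mass)
    d_fo <- delta_cs_sim(mean_draws(ffo), mref, tol$ci_mass)
    dd_po <- credible_interval(abs(d_po$draws - ed), tol$ci_mass)
    dd_fo <- credible_interval(abs(d_fo$draws - ed), tol$ci_mass)
    data.frame(
      residue_number = r$residue_number, residue_type = r$residue_type,
      atom = r$atom, method = r$method, exp_delta = ed,
      marker_status = marker_status(ed, r$atom, tol),
      delta_po_center = d_po$ci$center, delta_fo_center = d_fo$ci$center,
      dd_po_center = dd_po$center, dd_po_low = dd_po$lower,
      dd_po_high = dd_po$upper, dd_fo_center = dd_fo$center,
      dd_fo_low = dd_fo$lower, dd_fo_high = dd_fo$upper,
      verdict = assign_state(dd_po, dd_fo, r$atom, tol,
                             labels = candidate_states),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# combine the per-method verdicts of one nucleus: agreement keeps the state,
# any disagreement (including state vs undetermined) is undetermined
combine_method_verdicts <- function(verdicts) {
  u <- unique(verdicts)
  if (length(u) == 1L) u else "undetermined"
}

#' Tally verdicts at the nucleus or residue level
#'
#' Nucleus level: each (nucleus, method) verdict counts once and the
#' percentages of the two states and `"undetermined"` are reported. Residue
#' level: the per-method verdicts of a nucleus are first combined (agreement
#' keeps the state, disagreement is undetermined), then each residue takes
#' the majority vote over its nuclei (tie or all-undetermined is
#' undetermined), and percentages are over residues.
#'
#' @param verdicts data.frame from [assign_states()].
#' @param level `"nucleus"` or `"residue"`.
#' @param states the two candidate labels.
#' @return named numeric vector of percentages summing to 100.
#' @export
tally_verdicts <- function(verdicts, level = c("nucleus", "residue"),
                           states = c("PO", "FO")) {
  level <- match.arg(level)
  cats <- c(states, "undetermined")
  if (!nrow(verdicts))
    return(stats::setNames(rep(NaN, 3), cats))
  if (level == "nucleus") {
    v <- verdicts$verdict
  } else {
    nid <- nucleus_id(verdicts)
    per_nucleus <- vapply(split(verdicts$verdict, nid),
                          combine_method_verdicts, character(1))
    res_of <- vapply(strsplit(names(per_nucleus), "_"), `[`, character(1), 1)
    v <- vapply(split(per_nucleus, res_of), function(vs) {
      n1 <- sum(vs == states[1]); n2 <- sum(vs == states[2])
      if (n1 > n2) states[1] else if (n2 > n1) states[2] else "undetermined"
    }, character(1))
  }
  counts <- vapply(cats, function(cc) sum(v == cc), numeric(1))
  100 * counts / sum(counts)
}

#' Root mean squared error between absolute simulated and experimental shifts
#'
#' Point comparison of absolute shifts over the nuclei shared by both inputs.
#' Kept as a diagnostic: absolute-shift RMSE differences between candidate
#' states tend to sit within the experimental uncertainty, which is why the
#' pipeline decides on difference shifts instead.
#'
#' @param sim_means named numeric vector of simulated shift centers (names =
#'   nucleus ids).
#' @param exp_shifts named numeric vector of experimental shifts.
#' @return RMSE in ppm.
#' @export
rmse_absolute <- function(sim_means, exp_shifts) {
  shared <- intersect(names(sim_means), names(exp_shifts))
  if (!length(shared)) stop("no shared nuclei", call. = FALSE)
  sqrt(mean((sim_means[shared] - exp_shifts[shared])^2))
}

#' Remove the systematic center of simulated-minus-experimental differences
#'
#' Fits a Gaussian (maximum likelihood: sample mean and sd) to the per-
#' nucleus differences within each group and subtracts the fitted center, so
#' that a systematic prediction offset is removed before comparing absolute
#' shifts. Groups with fewer than `min_n` nuclei are skipped with a message
#' (their differences are returned uncorrected, center `NA`).
#'
#' @param diffs numeric vector of per-nucleus differences (sim - exp, ppm).
#' @param groups optional factor-like grouping (e.g. atom x method x state);
#'   default one group.
#' @param min_n minimum group size to fit (default 5).
#' @return list with `corrected` (numeric vector) and `centers` (data.frame
#'   of group, fitted center, fitted sd, n).
#' @export
recenter_bias <- function(diffs, groups = NULL, min_n = 5L) {
  if (is.null(groups)) groups <- rep("all", length(diffs))
  groups <- as.character(groups)
  corrected <- diffs
  centers <- do.call(rbind, lapply(unique(groups), function(g) {
    i <- groups == g
    if (sum(i) < min_n) {
      message("group ", g, ": fewer than ", min_n, " nuclei, not recentered")
      return(data.frame(group = g, center = NA_real_, sd = NA_real_,
                        n = sum(i), stringsAsFactors = FALSE))
    }
    ctr <- mean(diffs[i])
    corrected[i] <<- diffs[i] - ctr
    data.frame(group = g, center = ctr,
               sd = stats::sd(diffs[i]) * sqrt((sum(i) - 1) / sum(i)),
               n = sum(i), stringsAsFactors = FALSE)
  }))
  list(corrected = corrected, centers = centers)
}
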