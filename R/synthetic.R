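# population mean / variance of a (possibly two-component) skew-normal row;
# component 2 shares sigma/alpha and sits mix_delta ppm above component 1
row_pop_mean <- function(r) {
  m1 <- skewnorm_mean(r$mu, r$sigma, r$alpha)
  if (is.na(r$mix_weight)) return(m1)
  r$mix_weight * m1 + (1 - r$mix_weight) * (m1 + r$mix_delta)
}

row_pop_var <- function(r) {
  v1 <- skewnorm_var(r$mu, r$sigma, r$alpha)
  if (is.na(r$mix_weight)) return(v1)
  w <- r$mix_weight
  m1 <- skewnorm_mean(r$mu, r$sigma, r$alpha)
  m2 <- m1 + r$mix_delta
  m <- w * m1 + (1 - w) * m2
  w * (v1 + (m1 - m)^2) + (1 - w) * (v1 + (m2 - m)^2)
}

#' Ground-truth scenario for the synthetic chemical-shift generator
#'
#' A scenario fixes, per nucleus, state and prediction method, the
#' skew-normal parameters of the predicted-shift ensemble (optionally a
#' two-component mixture emulating conformational substates), the trajectory
#' size, the four exchangeable subunits, and which state truly generated the
#' experimental activated condition. From it, [sample_scenario()] emits
#' per-snapshot prediction records and [make_experimental_tables()] emits
#' the paired experimental assignment table, so the whole pipeline can be
#' exercised against a known answer.
#'
#' Planted marker classes are verified analytically at construction: the
#' population-mean gaps between states are compared against the per-isotope
#' tolerances (and the FO-vs-PO population effect size against the 0.5
#' threshold) and must reproduce the intended class of every nucleus.
#'
#' @param params data.frame with columns `residue_number`, `residue_type`,
#'   `atom`, `state`, `method`, `mu`, `sigma`, `alpha` and optionally
#'   `mix_weight` (in (0,1)) and `mix_delta` (ppm).
#' @param n_frames frames per subunit per state.
#' @param n_subunits number of chains (default 4).
#' @param true_state state whose population mean generates the activated
#'   experimental shift.
#' @param reference_state state generating the deactivated shift.
#' @param experimental_noise_sd sd of the noise added to experimental
#'   shifts (ppm); the 0.05 default is well below the tolerances so planted
#'   classes survive generation.
#' @param seed integer seed.
#' @param planted_class optional data.frame `residue_number`, `residue_type`,
#'   `atom`, `class`; verified analytically when given.
#' @param tol a [tolerance_config()] used for verification.
#' @return list of class `sn_scenario`.
#' @export
synthetic_scenario <- function(params, n_frames = 250L, n_subunits = 4L,
                               true_state = "PO", reference_state = "C",
                               experimental_noise_sd = 0.05, seed = 1L,
                               planted_class = NULL,
                               tol = tolerance_config()) {
  need <- c("residue_number", "residue_type", "atom", "state", "method",
            "mu", "sigma", "alpha")
  stopifnot(all(need %in% names(params)))
  if (!"mix_weight" %in% names(params)) params$mix_weight <- NA_real_
  if (!"mix_delta" %in% names(params)) params$mix_delta <- NA_real_
  stopifnot(all(params$sigma > 0), experimental_noise_sd >= 0,
            true_state %in% params$state, reference_state %in% params$state)
  mw <- params$mix_weight
  stopifnot(all(is.na(mw) | (mw > 0 & mw < 1)))
  sc <- structure(list(params = params, n_frames = as.integer(n_frames),
                       n_subunits = as.integer(n_subunits),
                       true_state = true_state,
                       reference_state = reference_state,
                       experimental_noise_sd = experimental_noise_sd,
                       seed = as.integer(seed),
                       planted_class = planted_class, tol = tol),
                  class = "sn_scenario")
  if (!is.null(planted_class)) verify_planted(sc)
  sc
}

# analytic check that each planted class is achievable: derive the class
# from population means/variances and compare
verify_planted <- function(sc) {
  derived <- analytic_classes(sc)
  want <- sc$planted_class
  wid <- nucleus_id(want)
  did <- nucleus_id(derived)
  for (i in seq_len(nrow(want))) {
    j <- match(wid[i], did)
    if (is.na(j) || !want$class[i] %in%
          strsplit(derived$classes[j], ",")[[1]])
      stop("planted class ", want$class[i], " for ", wid[i],
           " is not achievable with these parameters (analytic class: ",
           if (is.na(j)) "none" else derived$classes[j], ")", call. = FALSE)
  }
  invisible(TRUE)
}

# per-nucleus class set implied by the population parameters, per method
analytic_classes <- function(sc) {
  p <- sc$params
  tol <- sc$tol
  ids <- nucleus_id(p)
  combos <- unique(data.frame(id = ids, method = p$method,
                              stringsAsFactors = FALSE))
  rows <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- ids == combos$id[i] & p$method == combos$method[i]
    g <- p[sel, ]
    m <- vapply(split(g, g$state), function(r) row_pop_mean(r[1, ]),
                numeric(1))
    v <- vapply(split(g, g$state), function(r) row_pop_var(r[1, ]),
                numeric(1))
    atom <- g$atom[1]
    tl <- tolerance_for(atom, tol)
    dd <- abs(m["FO"] - m["PO"])
    es <- dd / sqrt((v["FO"] + v["PO"]) / 2)
    dpo_c <- abs(m["PO"] - m["C"]) > tl
    dfo_c <- abs(m["FO"] - m["C"]) > tl
    dfo_po <- dd > tl & es > tol$effect_size_threshold
    exp_delta <- m[sc$true_state] - m[sc$reference_state]
    mk <- marker_status(exp_delta, atom, tol) == "marker"
    cl <- classify_marker(dpo_c, dfo_c, dfo_po, mk)
    data.frame(residue_number = g$residue_number[1],
               residue_type = g$residue_type[1], atom = atom,
               method = combos$method[i], class = cl$class,
               stringsAsFactors = FALSE)
  }))
  ids2 <- nucleus_id(rows)
  out <- do.call(rbind, lapply(unique(ids2), function(id) {
    r <- rows[ids2 == id, ]
    data.frame(residue_number = r$residue_number[1],
               residue_type = r$residue_type[1], atom = r$atom[1],
               classes = paste(sort(unique(r$class)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# deterministic per-row seed, kept well inside 32-bit integer range
row_seed <- function(seed, i) (seed %% 100000L) * 10000L + i

#' Sample the predicted-shift ensemble of one nucleus/state/method
#'
#' Draws `n_subunits * n_frames` shifts from the scenario's skew-normal (or
#' two-component mixture) for the requested combination. Deterministic for a
#' fixed scenario seed.
#'
#' @param scenario an [synthetic_scenario()].
#' @param residue_number,atom,state,method selectors.
#' @return data.frame of shift records.
#' @export
sample_ensemble <- function(scenario, residue_number, atom, state, method) {
  p <- scenario$params
  i <- which(p$residue_number == residue_number & p$atom == atom &
               p$state == state & p$method == method)
  if (length(i) != 1L) stop("selector does not match exactly one row",
                            call. = FALSE)
  sample_param_row(scenario, i)
}

sample_param_row <- function(scenario, i) {
  r <- scenario$params[i, ]
  n <- scenario$n_frames * scenario$n_subunits
  set.seed(row_seed(scenario$seed, i))
  x <- rskewnorm(n, r$mu, r$sigma, r$alpha)
  if (!is.na(r$mix_weight)) {
    swap <- stats::runif(n) > r$mix_weight
    x[swap] <- x[swap] + r$mix_delta
  }
  data.frame(state = r$state, method = r$method,
             subunit = rep(LETTERS[seq_len(scenario$n_subunits)],
                           each = scenario$n_frames),
             frame = rep(seq_len(scenario$n_frames) - 1L,
                         scenario$n_subunits),
             residue_number = r$residue_number,
             residue_type = r$residue_type, atom = r$atom, shift_ppm = x,
             stringsAsFactors = FALSE)
}

#' Sample every ensemble of a scenario
#'
#' @param scenario an [synthetic_scenario()].
#' @return data.frame of shift records in the canonical long format.
#' @export
sample_scenario <- function(scenario) {
  out <- do.call(rbind, lapply(seq_len(nrow(scenario$params)), function(i)
    sample_param_row(scenario, i)))
  rownames(out) <- NULL
  out
}

#' Experimental assignment tables implied by a scenario
#'
#' The activated-condition shift of each nucleus is the population mean of
#' the scenario's true state (averaged over methods, which coincide in the
#' shipped presets) plus Gaussian noise; the deactivated shift comes from
#' the reference state the same way.
#'
#' @param scenario an [synthetic_scenario()].
#' @return data.frame of experimental shifts (both conditions).
#' @export
make_experimental_tables <- function(scenario) {
  p <- scenario$params
  ids <- nucleus_id(p)
  uid <- unique(ids)
  set.seed(row_seed(scenario$seed, nrow(p) + 1L))
  out <- do.call(rbind, lapply(uid, function(id) {
    g <- p[ids == id, ]
    pm <- function(st) {
      rows <- g[g$state == st, ]
      mean(vapply(seq_len(nrow(rows)), function(k) row_pop_mean(rows[k, ]),
                  numeric(1)))
    }
    act <- pm(scenario$true_state) +
      stats::rnorm(1, 0, scenario$experimental_noise_sd)
    deact <- pm(scenario$reference_state) +
      stats::rnorm(1, 0, scenario$experimental_noise_sd)
    data.frame(residue_number = g$residue_number[1],
               residue_type = g$residue_type[1], atom = g$atom[1],
               condition = c("activated", "deactivated"),
               shift_ppm = c(act, deact), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# plausible base shifts per atom type (ppm)
base_shift <- function(atom) {
  switch(atom, CA = 57, CB = 32, C = 176, N = 119,
         stop("unknown atom ", atom))
}

#' Named preset scenarios
#'
#' Ready-made ground-truth panels covering the behaviours the pipeline must
#' recover:
#' * `"spectator_only"` — all states share one distribution per nucleus;
#'   nothing discriminates, everything is class A.
#' * `"b1_panel"` — FO displaced by 3.5 tolerances from C = PO; experiment
#'   generated from the PO truth is unchanged between conditions (class B1).
#' * `"e2_panel"` — 20 nuclei with all three states mutually displaced by
#'   3.5 tolerances (population effect sizes > 2) and a PO-generated
#'   experiment (class E2); the pipeline must return a PO majority.
#' * `"fo_truth"` — the same panel with the experiment generated from FO.
#' * `"bimodal_stress"` — e2-like panel whose open-state ensembles are
#'   two-component mixtures (weight 0.5, 3-sigma gap).
#' * `"tie_stress"` — FO-vs-PO population gaps sitting exactly at the
#'   tolerance: with a strict threshold nothing may discriminate.
#'
#' @param name preset name.
#' @param n_frames frames per subunit (default 250; with 4 subunits, 1000
#'   points per nucleus).
#' @param methods prediction-method labels (parameters are shared across
#'   methods).
#' @param seed integer seed.
#' @return an [synthetic_scenario()].
#' @export
preset_scenario <- function(name = c("spectator_only", "b1_panel",
                                     "e2_panel", "fo_truth",
                                     "bimodal_stress", "tie_stress"),
                            n_frames = 250L, methods = "SPARTA+",
                            seed = 1L) {
  name <- match.arg(name)
  atoms <- c("CA", "CB", "C", "N")
  n_nuc <- if (name %in% c("spectator_only", "b1_panel")) 12L else 20L
  nuc <- data.frame(residue_number = 30L + 3L * seq_len(n_nuc),
                    residue_type = rep(c("A", "L", "T", "V", "S"),
                                       length.out = n_nuc),
                    atom = rep(atoms, length.out = n_nuc),
                    stringsAsFactors = FALSE)
  tolv <- tolerance_for(nuc$atom)
  # scale sigma with tolerance so nitrogen panels keep comparable effects
  sig <- 0.8 * tolv
  alpha <- 2
  gap <- switch(name, tie_stress = 1.0, 3.5) * tolv

  states <- c("C", "PO", "FO")
  offset_of <- function(state) switch(
    name,
    spectator_only = rep(0, n_nuc),
    b1_panel = if (state == "FO") gap else rep(0, n_nuc),
    tie_stress = switch(state, C = rep(0, n_nuc), PO = rep(0, n_nuc),
                        FO = gap),
    # e2_panel / fo_truth / bimodal_stress: all three states distinct
    switch(state, C = rep(0, n_nuc), PO = gap, FO = -gap)
  )
  params <- do.call(rbind, lapply(states, function(st) {
    do.call(rbind, lapply(methods, function(me) {
      data.frame(nuc, state = st, method = me,
                 mu = vapply(nuc$atom, base_shift, numeric(1)) +
                   offset_of(st),
                 sigma = sig, alpha = alpha,
                 mix_weight = NA_real_, mix_delta = NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (name == "bimodal_stress") {
    op <- params$state != "C"
    params$mix_weight[op] <- 0.5
    params$mix_delta[op] <- 3 * params$sigma[op]
  }
  true_state <- if (name == "fo_truth") "FO" else "PO"
  planted <- nuc
  planted$class <- switch(name,
                          spectator_only = "A",
                          b1_panel = "B1",
                          e2_panel = "E2",
                          bimodal_stress = "E2",
                          fo_truth = "E2",
                          tie_stress = "A")
  synthetic_scenario(params, n_frames = n_frames, true_state = true_state,
                     reference_state = "C", seed = seed,
                     planted_class = planted)
}

#' Write a scenario's tables to disk
#'
#' Emits the canonical long-format prediction TSV and the experimental TSV.
#'
#' @param scenario an [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two paths.
#' @export
write_scenario_tables <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pred <- file.path(dir, "predictions.tsv")
  expf <- file.path(dir, "experimental.tsv")
  write_shift_table(sample_scenario(scenario), pred)
  utils::write.table(make_experimental_tables(scenario), expf, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  message("scenario seed ", scenario$seed, ": wrote ", pred, " and ", expf)
  invisible(c(predictions = pred, experimental = expf))
}
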