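#' Sampler configuration
#'
#' @param method `"mcmc"` (canonical) or `"mle"` (fast deterministic
#'   approximation, see [snfit()]).
#' @param chains,iter,warmup MCMC geometry (defaults 4 x 1000 after 1000).
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(method = "mcmc", chains = 4L, iter = 1000L,
                           warmup = 1000L) {
  structure(list(method = method, chains = as.integer(chains),
                 iter = as.integer(iter), warmup = as.integer(warmup)),
            class = "sampler_config")
}

#' Fit the skew-normal model to every nucleus/state/method ensemble
#'
#' Groups the shift records and runs [snfit()] per group, with a per-group
#' seed derived deterministically from `seed` and the group's position in a
#' sorted index, so results are reproducible and independent of input row
#' order.
#'
#' @param records shift-record data.frame (pooled and subsampled).
#' @param keys optional data.frame (`residue_number`, `residue_type`,
#'   `atom`) restricting the nuclei fitted.
#' @param sampler a [sampler_config()].
#' @param seed integer base seed.
#' @return list of class `snfit_store` with `fits` (named list of [snfit]
#'   objects) and `index` (data.frame).
#' @export
fit_ensembles <- function(records, keys = NULL,
                          sampler = sampler_config(), seed = 1L) {
  records <- validate_shift_records(records)
  if (!is.null(keys))
    records <- records[nucleus_id(records) %in% nucleus_id(keys), ,
                       drop = FALSE]
  gid <- paste(nucleus_id(records), records$state, records$method,
               sep = "|")
  groups <- sort(unique(gid))
  fits <- vector("list", length(groups))
  names(fits) <- groups
  index <- do.call(rbind, lapply(seq_along(groups), function(i) {
    rows <- records[gid == groups[i], ]
    fit <- suppressWarnings(snfit(
      rows$shift_ppm, method = sampler$method, chains = sampler$chains,
      iter = sampler$iter, warmup = sampler$warmup,
      seed = (seed %% 100000L) * 10000L + i))
    fits[[i]] <<- fit
    data.frame(residue_number = rows$residue_number[1],
               residue_type = rows$residue_type[1], atom = rows$atom[1],
               state = rows$state[1], method = rows$method[1],
               n = nrow(rows),
               rhat_max = suppressWarnings(max(fit$diagnostics$rhat)),
               ess_min = suppressWarnings(min(fit$diagnostics$ess)),
               stringsAsFactors = FALSE)
  }))
  rownames(index) <- NULL
  structure(list(fits = fits, index = index, seed = seed,
                 sampler = sampler), class = "snfit_store")
}

fit_lookup <- function(store, residue_number, residue_type, atom, state,
                       method) {
  store$fits[[paste(paste(residue_number, residue_type, atom, sep = "_"),
                    state, method, sep = "|")]]
}

#' Flat summary of a fit store
#'
#' @param store an `snfit_store`.
#' @param mass credible mass for the reported interval of the distribution
#'   mean.
#' @return data.frame: nucleus, state, method, interval of the simulated
#'   peak position, convergence diagnostics.
#' @export
fit_summary_table <- function(store, mass = 0.94) {
  idx <- store$index
  cis <- lapply(seq_len(nrow(idx)), function(i)
    credible_interval(mean_draws(store$fits[[i]]), mass))
  cbind(idx,
        cs_center = vapply(cis, `[[`, numeric(1), "center"),
        cs_low = vapply(cis, `[[`, numeric(1), "lower"),
        cs_high = vapply(cis, `[[`, numeric(1), "upper"))
}

#' Run the full state-assignment pipeline
#'
#' Orchestrates: subunit pooling, per-nucleus subsampling, Bayesian
#' skew-normal fits for every nucleus/state/method, the discrimination
#' filter between the two candidate open states, delta-delta-CS state
#' assignment for the passers, marker classification of every assigned
#' nucleus, and nucleus-/residue-level tallies. Fully deterministic for a
#' fixed `seed`.
#'
#' @param predictions shift-record data.frame (or path to a canonical TSV).
#' @param experiments experimental-shift data.frame (or path to a TSV).
#' @param reference_state closed-reference label (default `"C"`).
#' @param candidate_states the two candidate open states, PO-like first.
#' @param tol a [tolerance_config()].
#' @param subsample_n per-nucleus sample size (default 2000).
#' @param sampler a [sampler_config()].
#' @param seed integer seed for subsampling and fitting.
#' @param out_dir optional directory: per-stage TSV artifacts and a JSON
#'   report are written there.
#' @return list of class `cs_run` with elements `keys`, `fits_summary`,
#'   `discrimination`, `verdicts`, `classes`, `tally_nucleus`,
#'   `tally_residue`, `report`.
#' @export
run_pipeline <- function(predictions, experiments, reference_state = "C",
                         candidate_states = c("PO", "FO"),
                         tol = tolerance_config(), subsample_n = 2000L,
                         sampler = sampler_config(), seed = 1L,
                         out_dir = NULL) {
  if (is.character(predictions))
    predictions <- read_prediction_table(predictions, "generic_long")
  if (is.character(experiments))
    experiments <- read_experimental_table(experiments)
  predictions <- validate_shift_records(predictions)
  states <- unique(predictions$state)
  missing_states <- setdiff(c(reference_state, candidate_states), states)
  if (length(missing_states))
    stop("predictions lack required state(s): ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  if (length(candidate_states) != 2L)
    stop("exactly two candidate states required", call. = FALSE)

  pooled <- pool_subunits(predictions)
  keys <- intersect_assigned(pooled, experiments)
  if (!nrow(keys))
    stop("no nucleus is predicted in all states and assigned in both ",
         "experimental conditions", call. = FALSE)
  sub <- suppressWarnings(subsample_shifts(pooled, subsample_n, seed = seed))
  fits <- fit_ensembles(sub, keys = keys, sampler = sampler, seed = seed)

  disc <- discriminate_states(fits, state_a = candidate_states[2],
                              state_b = candidate_states[1], tol = tol)
  verdicts <- assign_states(fits, disc, experiments,
                            reference_state = reference_state,
                            candidate_states = candidate_states, tol = tol)

  # delta table over ALL eligible nuclei (classification is not restricted
  # to discrimination passers)
  delta_all <- assign_states(fits, disc, experiments,
                             reference_state = reference_state,
                             candidate_states = candidate_states, tol = tol,
                             only_passing = FALSE)
  marker_tab <- unique(delta_all[, c("residue_number", "residue_type",
                                     "atom", "exp_delta")])
  classes <- classify_all(delta_all, disc, marker_tab, tol = tol)

  t_nuc <- tally_verdicts(verdicts, "nucleus", states = candidate_states)
  t_res <- tally_verdicts(verdicts, "residue", states = candidate_states)

  class_counts <- if (nrow(classes$per_method))
    table(classes$per_method$class) else table(character(0))
  report <- list(
    n_nuclei_eligible = nrow(keys),
    n_fits = nrow(fits$index),
    n_discriminating = if (nrow(disc)) sum(disc$passes) else 0L,
    n_verdicts = nrow(verdicts),
    tally_nucleus = as.list(t_nuc), tally_residue = as.list(t_res),
    class_counts = as.list(class_counts),
    max_rhat = suppressWarnings(max(fits$index$rhat_max)),
    min_ess = suppressWarnings(min(fits$index$ess_min)),
    seed = seed,
    sampler = unclass(fits$sampler), subsample_n = subsample_n)

  run <- structure(list(keys = keys, fits = fits,
                        fits_summary = fit_summary_table(fits, tol$ci_mass),
                        discrimination = disc, verdicts = verdicts,
                        classes = classes, tally_nucleus = t_nuc,
                        tally_residue = t_res, report = report, tol = tol,
                        candidate_states = candidate_states,
                        reference_state = reference_state),
                   class = "cs_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) utils::write.table(
    df, file.path(out_dir, file), sep = "\t", row.names = FALSE,
    quote = FALSE)
  wt(run$fits_summary, "fit_summary.tsv")
  if (nrow(run$discrimination)) wt(run$discrimination, "discrimination.tsv")
  if (nrow(run$verdicts)) wt(run$verdicts, "verdicts.tsv")
  if (nrow(run$classes$per_method)) {
    wt(run$classes$per_method, "classes_per_method.tsv")
    wt(run$classes$per_nucleus, "classes_per_nucleus.tsv")
  }
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cs_run <- function(x, ...) {
  r <- x$report
  cat("Chemical-shift state-assignment run\n")
  cat("  eligible nuclei:      ", r$n_nuclei_eligible, "\n")
  cat("  fits (nucleus x state x method):", r$n_fits, "\n")
  cat("  discriminating (", paste(x$candidate_states, collapse = " vs "),
      "): ", r$n_discriminating, "\n", sep = "")
  fmt <- function(t) paste(sprintf("%s %.0f%%", names(t), t),
                           collapse = ", ")
  if (r$n_verdicts > 0) {
    cat("  nucleus-level tally:  ", fmt(x$tally_nucleus), "\n")
    cat("  residue-level tally:  ", fmt(x$tally_residue), "\n")
  }
  if (length(r$class_counts))
    cat("  classes: ", paste(sprintf("%s:%d", names(r$class_counts),
                                     unlist(r$class_counts)),
                             collapse = " "), "\n")
  invisible(x)
}

#' Plot-ready tables for the two diagnostic figures
#'
#' Returns the data behind the two standard panels: the statistical-filter
#' panel (difference-in-means and effect-size credible intervals per nucleus
#' and method, with the tolerance band) and the discrepancy panel (the
#' |delta-delta-CS| credible intervals of both candidate states for every
#' discriminating nucleus; a method that fails the filter contributes no
#' bar).
#'
#' @param run a `cs_run`.
#' @return list with `filter_panel` and `ddcs_panel` data.frames.
#' @export
make_figure_tables <- function(run) {
  disc <- run$discrimination
  filter_panel <- if (nrow(disc)) {
    cbind(disc[, c("residue_number", "residue_type", "atom", "method",
                   "diff_center", "diff_low", "diff_high", "effect_center",
                   "effect_low", "effect_high", "passes")],
          tolerance = tolerance_for(disc$atom, run$tol),
          effect_threshold = run$tol$effect_size_threshold)
  } else data.frame()
  v <- run$verdicts
  ddcs_panel <- if (is.data.frame(v) && nrow(v)) {
    po <- v[, c("residue_number", "residue_type", "atom", "method",
                "dd_po_center", "dd_po_low", "dd_po_high")]
    names(po)[5:7] <- c("dd_center", "dd_low", "dd_high")
    po$state <- run$candidate_states[1]
    fo <- v[, c("residue_number", "residue_type", "atom", "method",
                "dd_fo_center", "dd_fo_low", "dd_fo_high")]
    names(fo)[5:7] <- c("dd_center", "dd_low", "dd_high")
    fo$state <- run$candidate_states[2]
    out <- rbind(po, fo)
    out$tolerance <- tolerance_for(out$atom, run$tol)
    out
  } else data.frame()
  list(filter_panel = filter_panel, ddcs_panel = ddcs_panel)
}

#' @export
plot.cs_run <- function(x, which = c("filter", "ddcs"), ...) {
  which <- match.arg(which)
  tabs <- make_figure_tables(x)
  if (which == "filter") {
    fp <- tabs$filter_panel
    if (!nrow(fp)) stop("empty run", call. = FALSE)
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    lab <- paste0(fp$residue_type, fp$residue_number, ":", fp$atom)
    y <- seq_len(nrow(fp))
    graphics::plot(fp$diff_center, y, xlim = range(fp$diff_low,
                                                   fp$diff_high),
                   xlab = "difference in means (ppm)", ylab = "",
                   yaxt = "n", pch = 19, ...)
    graphics::rect(-fp$tolerance[1], 0, fp$tolerance[1], nrow(fp) + 1,
                   col = grDevices::adjustcolor("darkgreen", 0.15),
                   border = NA)
    graphics::segments(fp$diff_low, y, fp$diff_high, y)
    graphics::axis(2, at = y, labels = lab, las = 2, cex.axis = 0.6)
    graphics::plot(fp$effect_center, y, xlim = range(fp$effect_low,
                                                     fp$effect_high),
                   xlab = "effect size", ylab = "", yaxt = "n", pch = 19)
    graphics::rect(-fp$effect_threshold[1], 0, fp$effect_threshold[1],
                   nrow(fp) + 1,
                   col = grDevices::adjustcolor("darkgreen", 0.15),
                   border = NA)
    graphics::segments(fp$effect_low, y, fp$effect_high, y)
  } else {
    dp <- tabs$ddcs_panel
    if (!nrow(dp)) stop("no discriminating nuclei to plot", call. = FALSE)
    lab <- paste0(dp$residue_type, dp$residue_number, ":", dp$atom, " (",
                  dp$method, ")")
    cols <- ifelse(dp$state == x$candidate_states[1], "steelblue",
                   "darkorange")
    o <- order(dp$residue_number, dp$atom, dp$method, dp$state)
    dp <- dp[o, ]; lab <- lab[o]; cols <- cols[o]
    bp <- graphics::barplot(dp$dd_center, col = cols, border = NA,
                            names.arg = lab, las = 2, cex.names = 0.5,
                            ylab = "|ddCS| (ppm)", ...)
    graphics::rect(0, 0, max(bp) + 1, dp$tolerance[1],
                   col = grDevices::adjustcolor("darkgreen", 0.15),
                   border = NA)
    graphics::segments(bp, dp$dd_low, bp, dp$dd_high)
    graphics::legend("topright", fill = c("steelblue", "darkorange"),
                     legend = x$candidate_states, bty = "n")
  }
  invisible(x)
}
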