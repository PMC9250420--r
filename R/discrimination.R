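#' Credible interval of the difference in distribution means
#'
#' Elementwise difference of the two states' posterior mean-draws
#' (conventionally FO minus PO). The two posteriors are independent, so the
#' index pairing is arbitrary but reproducible; unequal lengths are trimmed
#' to the shorter with a warning.
#'
#' @param mean_draws_a,mean_draws_b posterior mean draws ([mean_draws()]) of
#'   the two states; the difference is `a - b`.
#' @param mass credible mass.
#' @return A `credint` (see [credible_interval()]).
#' @export
difference_in_means <- function(mean_draws_a, mean_draws_b, mass = 0.94) {
  n <- min(length(mean_draws_a), length(mean_draws_b))
  if (length(mean_draws_a) != length(mean_draws_b))
    warning("draw arrays of unequal length; trimmed to ", n, call. = FALSE)
  credible_interval(mean_draws_a[seq_len(n)] - mean_draws_b[seq_len(n)], mass)
}

#' Credible interval of the effect size between two states
#'
#' Per-draw standardized difference
#' \deqn{(\mathrm{mean}_A - \mathrm{mean}_B) / s_{pool}, \quad
#'   s_{pool} = \sqrt{(\mathrm{var}_A + \mathrm{var}_B)/2}.}
#' The pooled standard deviation uses the *sum* of the two distribution
#' variances: a pooled dispersion must be an average of dispersions (a
#' difference could be negative under the radical). An absolute effect above
#' 0.5 is conventionally a medium effect.
#'
#' @param mean_draws_a,mean_draws_b posterior mean draws of the two states.
#' @param var_draws_a,var_draws_b posterior variance draws; all > 0.
#' @param mass credible mass.
#' @return A `credint`.
#' @export
effect_size <- function(mean_draws_a, mean_draws_b, var_draws_a, var_draws_b,
                        mass = 0.94) {
  if (any(var_draws_a <= 0) || any(var_draws_b <= 0))
    stop("variance draws must be strictly positive", call. = FALSE)
  n <- min(length(mean_draws_a), length(mean_draws_b),
           length(var_draws_a), length(var_draws_b))
  i <- seq_len(n)
  s_pool <- sqrt((var_draws_a[i] + var_draws_b[i]) / 2)
  credible_interval((mean_draws_a[i] - mean_draws_b[i]) / s_pool, mass)
}

#' Discrimination-power decision for one nucleus and method
#'
#' A nucleus (for a given prediction method) can discriminate two candidate
#' states when *both* hold:
#' * the center of the difference-in-means credible interval exceeds the
#'   per-isotope experimental tolerance in absolute value (0.2 ppm for C,
#'   CA, CB; 0.5 ppm for N), and
#' * the center of the effect-size credible interval exceeds 0.5 in absolute
#'   value.
#'
#' Only the interval *centers* enter the decision. Both sub-criteria are
#' recorded separately for reporting.
#'
#' @param diff_ci `credint` of the difference in means (ppm).
#' @param effect_ci `credint` of the effect size.
#' @param atom atom name (`"N"`, `"C"`, `"CA"`, `"CB"`).
#' @param tol a [tolerance_config()].
#' @return list with `passes`, `passes_diff`, `passes_effect`, the two
#'   intervals and the tolerance applied.
#' @export
has_discrimination_power <- function(diff_ci, effect_ci, atom,
                                     tol = tolerance_config()) {
  tl <- tolerance_for(atom, tol)
  passes_diff <- abs(diff_ci$center) > tl
  passes_effect <- abs(effect_ci$center) > tol$effect_size_threshold
  list(passes = passes_diff && passes_effect, passes_diff = passes_diff,
       passes_effect = passes_effect, diff_ci = diff_ci,
       effect_ci = effect_ci, tolerance = tl)
}

#' Discrimination filter over a table of fitted nuclei
#'
#' Applies [difference_in_means()], [effect_size()] and
#' [has_discrimination_power()] to every nucleus/method in a fit store (see
#' [fit_ensembles()]), comparing the two candidate open states.
#'
#' @param fits fit store returned by [fit_ensembles()].
#' @param state_a,state_b candidate state labels (difference is `a - b`;
#'   conventionally FO and PO).
#' @param tol a [tolerance_config()].
#' @return data.frame: one row per (nucleus, method) with interval bounds,
#'   sub-criteria and the `passes` flag.
#' @export
discriminate_states <- function(fits, state_a = "FO", state_b = "PO",
                                tol = tolerance_config()) {
  idx <- fits$index
  rows <- idx[idx$state == state_a, c("residue_number", "residue_type",
                                      "atom", "method")]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    fa <- fit_lookup(fits, r$residue_number, r$residue_type, r$atom,
                     state_a, r$method)
    fb <- fit_lookup(fits, r$residue_number, r$residue_type, r$atom,
                     state_b, r$method)
    if (is.null(fa) || is.null(fb)) return(NULL)
    dci <- difference_in_means(mean_draws(fa), mean_draws(fb), tol$ci_mass)
    eci <- effect_size(mean_draws(fa), mean_draws(fb),
                       variance_draws(fa), variance_draws(fb), tol$ci_mass)
    dec <- has_discrimination_power(dci, eci, r$atom, tol)
    data.frame(r, diff_center = dci$center, diff_low = dci$lower,
               diff_high = dci$upper, effect_center = eci$center,
               effect_low = eci$lower, effect_high = eci$upper,
               passes_diff = dec$passes_diff,
               passes_effect = dec$passes_effect, passes = dec$passes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
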