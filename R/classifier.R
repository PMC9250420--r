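#' Marker-class flowchart for one nucleus
#'
#' Sorts a nucleus into one of five letter classes from the three pairwise
#' simulated distinguishabilities (PO vs C, FO vs C, FO vs PO — each a
#' boolean "the shift difference exceeds the per-isotope tolerance"):
#'
#' * **A** — none distinguishable (simulated spectator);
#' * **B** — FO distinct from both C and PO, which match each other;
#' * **C** — PO distinct from both FO and C, which match each other;
#' * **D** — C distinct from both open states, which match each other
#'   (hypothetical: eliminated upstream by the FO-vs-PO filter);
#' * **E** — all three states mutually distinct.
#'
#' The subtype is **1** when the experimental resonance is a spectator and
#' **2** when it is a marker; class A carries no subtype. Three boolean
#' patterns match no class (exactly one distinguishable pair — geometrically
#' near-impossible, but reachable with noisy centers); these are mapped to
#' the closest regular pattern by Hamming distance (precedence E, B, C, D, A
#' on ties) and flagged `irregular`.
#'
#' @param dpo_c logical: PO distinguishable from C.
#' @param dfo_c logical: FO distinguishable from C.
#' @param dfo_po logical: FO distinguishable from PO.
#' @param exp_marker logical: experimental marker status.
#' @return list with `class` (e.g. `"B1"`, `"A"`), `letter`, `subtype`
#'   (`NA` for A) and `irregular`.
#' @export
classify_marker <- function(dpo_c, dfo_c, dfo_po, exp_marker) {
  stopifnot(is.logical(dpo_c), is.logical(dfo_c), is.logical(dfo_po),
            is.logical(exp_marker))
  patterns <- list(A = c(FALSE, FALSE, FALSE), B = c(FALSE, TRUE, TRUE),
                   C = c(TRUE, FALSE, TRUE), D = c(TRUE, TRUE, FALSE),
                   E = c(TRUE, TRUE, TRUE))
  p <- c(dpo_c, dfo_c, dfo_po)
  dists <- vapply(patterns, function(q) sum(q != p), numeric(1))
  irregular <- min(dists) > 0L
  if (irregular) {
    precedence <- c("E", "B", "C", "D", "A")
    cand <- names(dists)[dists == min(dists)]
    letter <- precedence[precedence %in% cand][1]
  } else {
    letter <- names(dists)[dists == 0L]
  }
  subtype <- if (letter == "A") NA_integer_ else if (exp_marker) 2L else 1L
  cls <- if (letter == "A") "A" else paste0(letter, subtype)
  list(class = cls, letter = letter, subtype = subtype,
       irregular = irregular)
}

#' Classify every assigned nucleus for every prediction method
#'
#' Builds the three distinguishability booleans from credible-interval
#' centers (simulated difference shifts of each open state against the
#' reference, and the open-vs-open difference in means), takes the
#' experimental marker status, and applies [classify_marker()] per (nucleus,
#' method). The per-nucleus class set is the union over methods — two
#' prediction tools that disagree give a nucleus two classes.
#'
#' @param delta_table data.frame with `residue_number`, `residue_type`,
#'   `atom`, `method`, `delta_po_center`, `delta_fo_center` (simulated
#'   difference-shift CI centers vs the reference state, ppm).
#' @param discrimination_table output of [discriminate_states()] (supplies
#'   the FO-vs-PO difference center and, optionally, the filter flag).
#' @param marker_table data.frame with `residue_number`, `residue_type`,
#'   `atom`, `exp_delta` (experimental difference shift, ppm).
#' @param tol a [tolerance_config()].
#' @param fo_po_rule `"tolerance"` (default; FO-vs-PO boolean is the
#'   difference-in-means center vs tolerance, the same rule as the other two
#'   booleans) or `"filter"` (use the discrimination filter's `passes` flag,
#'   which also demands the effect size).
#' @return list with `per_method` (data.frame: one row per nucleus-method
#'   with booleans, class, irregular flag) and `per_nucleus` (data.frame of
#'   the class-set union per nucleus).
#' @export
classify_all <- function(delta_table, discrimination_table, marker_table,
                         tol = tolerance_config(),
                         fo_po_rule = c("tolerance", "filter")) {
  fo_po_rule <- match.arg(fo_po_rule)
  did <- paste(nucleus_id(discrimination_table),
               discrimination_table$method)
  mid <- nucleus_id(marker_table)
  per_method <- do.call(rbind, lapply(seq_len(nrow(delta_table)),
                                      function(i) {
    r <- delta_table[i, ]
    id <- paste(r$residue_number, r$residue_type, r$atom, sep = "_")
    j <- match(paste(id, r$method), did)
    k <- match(id, mid)
    if (is.na(j) || is.na(k)) {
      message("skipping ", id, " (", r$method, "): missing input row")
      return(NULL)
    }
    tl <- tolerance_for(r$atom, tol)
    dpo_c <- abs(r$delta_po_center) > tl
    dfo_c <- abs(r$delta_fo_center) > tl
    dfo_po <- if (fo_po_rule == "tolerance")
      abs(discrimination_table$diff_center[j]) > tl
    else discrimination_table$passes[j]
    mk <- marker_status(marker_table$exp_delta[k], r$atom, tol) == "marker"
    cl <- classify_marker(dpo_c, dfo_c, dfo_po, mk)
    data.frame(residue_number = r$residue_number,
               residue_type = r$residue_type, atom = r$atom,
               method = r$method, dpo_c = dpo_c, dfo_c = dfo_c,
               dfo_po = dfo_po, exp_marker = mk, class = cl$class,
               irregular = cl$irregular, stringsAsFactors = FALSE)
  }))
  if (is.null(per_method))
    return(list(per_method = data.frame(), per_nucleus = data.frame()))
  rownames(per_method) <- NULL
  ids <- nucleus_id(per_method)
  per_nucleus <- do.call(rbind, lapply(unique(ids), function(id) {
    rows <- per_method[ids == id, ]
    data.frame(residue_number = rows$residue_number[1],
               residue_type = rows$residue_type[1], atom = rows$atom[1],
               classes = paste(sort(unique(rows$class)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(per_nucleus) <- NULL
  list(per_method = per_method, per_nucleus = per_nucleus)
}
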