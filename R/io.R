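#' Tolerance and threshold configuration
#'
#' Bundles the experimental tolerances and statistical thresholds used across
#' the pipeline: 0.2 ppm for carbon nuclei (C, CA, CB), 0.5 ppm for nitrogen,
#' a 0.5 effect-size threshold (a "medium" effect by the usual convention),
#' and the 0.94 credible mass.
#'
#' @param carbon_tol tolerance for 13C nuclei (ppm).
#' @param nitrogen_tol tolerance for 15N nuclei (ppm).
#' @param effect_size_threshold dimensionless effect-size cutoff.
#' @param ci_mass credible mass in (0, 1).
#' @return list of class `tolerance_config`.
#' @export
tolerance_config <- function(carbon_tol = 0.2, nitrogen_tol = 0.5,
                             effect_size_threshold = 0.5, ci_mass = 0.94) {
  stopifnot(carbon_tol > 0, nitrogen_tol > 0, effect_size_threshold > 0,
            ci_mass > 0, ci_mass < 1)
  structure(list(carbon_tol = carbon_tol, nitrogen_tol = nitrogen_tol,
                 effect_size_threshold = effect_size_threshold,
                 ci_mass = ci_mass),
            class = "tolerance_config")
}

#' @rdname tolerance_config
#' @param atom atom name(s): one of `"N"`, `"C"`, `"CA"`, `"CB"`.
#' @param tol a `tolerance_config`.
#' @export
tolerance_for <- function(atom, tol = tolerance_config()) {
  ifelse(atom == "N", tol$nitrogen_tol, tol$carbon_tol)
}

SUPPORTED_ATOMS <- c("N", "C", "CA", "CB")

# canonical nucleus identifier used to join tables
nucleus_id <- function(df) {
  paste(df$residue_number, df$residue_type, df$atom, sep = "_")
}

validate_shift_records <- function(df) {
  need <- c("state", "method", "subunit", "frame", "residue_number",
            "residue_type", "atom", "shift_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("shift table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) && !all(is.finite(df$shift_ppm)))
    stop("non-finite shift values in table", call. = FALSE)
  df$residue_number <- as.integer(df$residue_number)
  df$frame <- as.integer(df$frame)
  df[need]
}

#' Read a table of per-snapshot predicted chemical shifts
#'
#' Parses one of three dialects into the canonical long format with columns
#' `state, method, subunit, frame, residue_number, residue_type, atom,
#' shift_ppm`:
#'
#' * `"sparta_plus"`: whitespace-delimited with columns `RESID`, `RESNAME`,
#'   `ATOMNAME`, `SHIFT` (a `VARS`/`FORMAT` preamble and `REMARK`/`DATA`
#'   lines are accepted and skipped). Optional `FRAME` and `CHAIN` columns;
#'   otherwise the `frame`/`subunit` arguments stamp the whole file.
#' * `"shiftx2"`: comma-separated with columns `NUM`, `RES`, `ATOMNAME`,
#'   `SHIFT`, optional `FRAME` and `CHAIN`.
#' * `"generic_long"`: tab-separated canonical interchange format (header
#'   exactly the canonical columns); `state`/`method` arguments, when given,
#'   override the file's columns.
#'
#' Only backbone N, C (carbonyl), CA and CB nuclei are retained; rows for
#' other atoms are dropped with a message reporting the count. Glycine CB
#' rows, which should not exist, are dropped with a warning. Residue
#' numbering is taken verbatim from the file.
#'
#' @param path file path.
#' @param dialect one of `"sparta_plus"`, `"shiftx2"`, `"generic_long"`.
#' @param state state label stamped on the records (e.g. `"PO"`).
#' @param method prediction-method label (e.g. `"SPARTA+"`).
#' @param frame frame index used when the file has no frame column.
#' @param subunit chain id used when the file has no chain column.
#' @return data.frame of shift records.
#' @export
read_prediction_table <- function(path, dialect = c("generic_long",
                                                    "sparta_plus", "shiftx2"),
                                  state = NULL, method = NULL, frame = 0L,
                                  subunit = "A") {
  dialect <- tryCatch(match.arg(dialect), error = function(e)
    stop("unknown dialect", call. = FALSE))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  df <- switch(dialect,
    generic_long = {
      # label columns must never be type-guessed: residue type "T" is not
      # a logical
      out <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c(state = "character",
                                              method = "character",
                                              subunit = "character",
                                              residue_type = "character",
                                              atom = "character"))
      if (!is.null(state)) out$state <- state
      if (!is.null(method)) out$method <- method
      out
    },
    sparta_plus = read_sparta_plus(path, state, method, frame, subunit),
    shiftx2 = read_shiftx2(path, state, method, frame, subunit)
  )
  df <- validate_shift_records(df)

  bad <- !(df$atom %in% SUPPORTED_ATOMS)
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with unsupported atoms (",
            paste(unique(df$atom[bad]), collapse = ", "), ")")
    df <- df[!bad, , drop = FALSE]
  }
  gly_cb <- df$atom == "CB" & toupper(df$residue_type) %in% c("G", "GLY")
  if (any(gly_cb)) {
    warning("dropped ", sum(gly_cb), " glycine CB row(s)", call. = FALSE)
    df <- df[!gly_cb, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

read_sparta_plus <- function(path, state, method, frame, subunit) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*($|REMARK|DATA|FORMAT)", lines)
  vars_line <- grep("^\\s*VARS\\b", lines, value = TRUE)
  if (length(vars_line)) {
    cols <- strsplit(trimws(sub("^\\s*VARS\\s+", "", vars_line[1])),
                     "\\s+")[[1]]
    body <- lines[keep & !grepl("^\\s*VARS\\b", lines)]
    cls <- c(RESNAME = "character", ATOMNAME = "character",
             CHAIN = "character")
    cls <- cls[names(cls) %in% cols]
    df <- tryCatch(
      utils::read.table(text = body, col.names = cols,
                        stringsAsFactors = FALSE, colClasses = cls),
      error = function(e) stop("cannot parse SPARTA+ table ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  } else {
    hdr <- names(utils::read.table(path, header = TRUE, nrows = 1))
    cls <- c(RESNAME = "character", ATOMNAME = "character",
             CHAIN = "character")
    df <- tryCatch(
      utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = cls[names(cls) %in% hdr]),
      error = function(e) stop("cannot parse SPARTA+ table ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  for (nm in c("RESID", "RESNAME", "ATOMNAME", "SHIFT"))
    if (!nm %in% names(df))
      stop("SPARTA+ table ", path, " lacks column ", nm, call. = FALSE)
  data.frame(
    state = if (is.null(state)) "state" else state,
    method = if (is.null(method)) "SPARTA+" else method,
    subunit = if ("CHAIN" %in% names(df)) df$CHAIN else subunit,
    frame = if ("FRAME" %in% names(df)) df$FRAME else frame,
    residue_number = df$RESID, residue_type = df$RESNAME,
    atom = df$ATOMNAME, shift_ppm = df$SHIFT,
    stringsAsFactors = FALSE)
}

read_shiftx2 <- function(path, state, method, frame, subunit) {
  hdr <- names(utils::read.csv(path, nrows = 1))
  cls <- c(RES = "character", ATOMNAME = "character", CHAIN = "character")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = cls[names(cls) %in% hdr]),
                 error = function(e) stop("cannot parse SHIFTX2 table ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  for (nm in c("NUM", "RES", "ATOMNAME", "SHIFT"))
    if (!nm %in% names(df))
      stop("SHIFTX2 table ", path, " lacks column ", nm, call. = FALSE)
  data.frame(
    state = if (is.null(state)) "state" else state,
    method = if (is.null(method)) "SHIFTX2" else method,
    subunit = if ("CHAIN" %in% names(df)) df$CHAIN else subunit,
    frame = if ("FRAME" %in% names(df)) df$FRAME else frame,
    residue_number = df$NUM, residue_type = df$RES,
    atom = df$ATOMNAME, shift_ppm = df$SHIFT,
    stringsAsFactors = FALSE)
}

#' Write shift records in the canonical long format
#'
#' @param records shift-record data.frame.
#' @param path output path (TSV).
#' @export
write_shift_table <- function(records, path) {
  records <- validate_shift_records(records)
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Concatenate the equivalent subunits of a homo-oligomer
#'
#' The four subunits of a homotetramer sample the same conformational
#' ensemble, so their per-nucleus shift predictions are concatenated after
#' prediction, quadrupling the sample size per nucleus. The record count is
#' unchanged; only the `subunit` label is collapsed.
#'
#' @param records shift-record data.frame (one state and method, or several —
#'   pooling is per record and does not mix them).
#' @param label pooled subunit label.
#' @return the records with `subunit` set to `label`.
#' @export
pool_subunits <- function(records, label = "pooled") {
  records <- validate_shift_records(records)
  if (nrow(records)) records$subunit <- label
  records
}

#' Randomly subsample shift records per nucleus
#'
#' For each (state, method, subunit, nucleus) group, selects `n` records
#' uniformly without replacement (all of them, with a warning, if fewer than
#' `n` are available — discarding would bias small ensembles). Deterministic
#' for a fixed seed.
#'
#' @param records shift-record data.frame.
#' @param n target sample size per nucleus (the study used 2000).
#' @param seed integer seed.
#' @return subsampled records.
#' @export
subsample_shifts <- function(records, n = 2000L, seed = NULL) {
  records <- validate_shift_records(records)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(records)) return(records)
  grp <- paste(records$state, records$method, records$subunit,
               nucleus_id(records), sep = "\r")
  short <- 0L
  idx <- unlist(lapply(split(seq_len(nrow(records)), grp), function(i) {
    if (length(i) <= n) {
      if (length(i) < n) short <<- short + 1L
      i
    } else {
      sort(sample(i, n))
    }
  }), use.names = FALSE)
  if (short > 0L)
    warning(short, " group(s) had fewer than ", n,
            " records; kept all available", call. = FALSE)
  out <- records[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an experimental assignment table
#'
#' Tab-separated with columns `residue_number, residue_type, atom, condition,
#' shift_ppm`; `condition` is `"activated"` (low pH) or `"deactivated"`
#' (neutral pH). Duplicate (nucleus, condition) rows are an error naming the
#' nucleus; rows with a missing shift are skipped with a message.
#'
#' @param path file path.
#' @return data.frame of experimental shifts.
#' @export
read_experimental_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(residue_type = "character",
                                         atom = "character",
                                         condition = "character"))
  need <- c("residue_number", "residue_type", "atom", "condition",
            "shift_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("experimental table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad_cond <- !df$condition %in% c("activated", "deactivated")
  if (any(bad_cond))
    stop("unknown condition label(s): ",
         paste(unique(df$condition[bad_cond]), collapse = ", "),
         call. = FALSE)
  na_shift <- is.na(df$shift_ppm)
  if (any(na_shift)) {
    message("skipped ", sum(na_shift), " row(s) with missing shift value")
    df <- df[!na_shift, , drop = FALSE]
  }
  key <- paste(nucleus_id(df), df$condition)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate experimental assignment for ", dup, call. = FALSE)
  }
  df$residue_number <- as.integer(df$residue_number)
  rownames(df) <- NULL
  df[need]
}

#' Nuclei usable for state assignment
#'
#' Returns the nuclei that are predicted in *every* simulated state present
#' in `predictions` and experimentally assigned under *both* conditions —
#' only those can enter the difference-shift comparison.
#'
#' @param predictions shift-record data.frame.
#' @param experiments experimental-shift data.frame.
#' @return data.frame with `residue_number`, `residue_type`, `atom` (one row
#'   per eligible nucleus).
#' @export
intersect_assigned <- function(predictions, experiments) {
  empty <- data.frame(residue_number = integer(0),
                      residue_type = character(0), atom = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(predictions) || !nrow(experiments)) return(empty)
  predictions <- validate_shift_records(predictions)
  states <- unique(predictions$state)
  pid <- nucleus_id(predictions)
  by_state <- lapply(states, function(s) unique(pid[predictions$state == s]))
  in_all_states <- Reduce(intersect, by_state)
  eid <- nucleus_id(experiments)
  act <- unique(eid[experiments$condition == "activated"])
  deact <- unique(eid[experiments$condition == "deactivated"])
  keep <- intersect(in_all_states, intersect(act, deact))
  if (!length(keep)) return(empty)
  k <- predictions[!duplicated(pid) & pid %in% keep,
                   c("residue_number", "residue_type", "atom")]
  k <- k[order(k$residue_number, k$atom), , drop = FALSE]
  rownames(k) <- NULL
  k
}
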