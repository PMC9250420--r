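#' Inner-gate cross-bundle distance of a tetrameric channel
#'
#' Measures the opening of the intracellular gate as the Calpha-Calpha
#' distance between a gate residue (T112 in the study construct) of
#' *opposing* subunits. With four chains there are three ways to split them
#' into two pairs; the diagonal pairing is the one maximizing the summed
#' pair distances, which is robust to arbitrary chain naming. Both diagonal
#' distances are returned (they can differ in asymmetric gates) along with
#' their mean.
#'
#' @param structure a `bio3d` `pdb` object or a path to a PDB file.
#' @param residue_number residue to measure at.
#' @param atom_name atom name (default `"CA"`).
#' @return list with `mean` (angstrom), `diagonals` (length 2), `pairs`
#'   (2x2 matrix of chain ids).
#' @export
gate_distance <- function(structure, residue_number, atom_name = "CA") {
  pdb <- if (inherits(structure, "pdb")) structure else
    bio3d::read.pdb(structure)
  a <- pdb$atom
  sel <- a$resno == residue_number & trimws(a$elety) == atom_name
  sel[is.na(sel)] <- FALSE
  hit <- a[sel, , drop = FALSE]
  hit <- hit[!duplicated(hit$chain), , drop = FALSE]
  if (nrow(hit) < 4L) {
    have <- unique(hit$chain)
    stop("need the atom in >= 4 chains; found it only in chain(s): ",
         if (length(have)) paste(have, collapse = ", ") else "(none)",
         call. = FALSE)
  }
  hit <- hit[seq_len(4L), ]
  xyz <- as.matrix(hit[, c("x", "y", "z")])
  pairings <- list(rbind(c(1, 2), c(3, 4)), rbind(c(1, 3), c(2, 4)),
                   rbind(c(1, 4), c(2, 3)))
  dsum <- vapply(pairings, function(p) {
    sum(vapply(1:2, function(r)
      sqrt(sum((xyz[p[r, 1], ] - xyz[p[r, 2], ])^2)), numeric(1)))
  }, numeric(1))
  best <- pairings[[which.max(dsum)]]
  diag_d <- vapply(1:2, function(r)
    sqrt(sum((xyz[best[r, 1], ] - xyz[best[r, 2], ])^2)), numeric(1))
  pairs <- rbind(hit$chain[best[1, ]], hit$chain[best[2, ]])
  list(mean = mean(diag_d), diagonals = diag_d, pairs = pairs)
}

#' Half-open frame window
#'
#' @param start,end integers with `0 <= start < end`; the window is
#'   `[start, end)`.
#' @return list of class `frame_window`.
#' @export
frame_window <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid frame window [", start, ", ", end, ")", call. = FALSE)
  structure(list(start = start, end = end), class = "frame_window")
}

#' @export
print.frame_window <- function(x, ...) {
  cat("frames [", x$start, ", ", x$end, ")\n", sep = "")
  invisible(x)
}

#' Usable window before water enters the selectivity filter
#'
#' Water penetration into the selectivity filter marks the onset of
#' inactivation, so frames from the entry event onward are discarded.
#'
#' @param water_entry_frame frame of the entry event, or `NULL`/`NA` if none.
#' @param n_frames trajectory length in frames.
#' @return a [frame_window()]: `[0, entry)` if an event exists, else
#'   `[0, n_frames)`.
#' @export
exclude_after_water_entry <- function(water_entry_frame, n_frames) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 1L)
  if (is.null(water_entry_frame) || is.na(water_entry_frame))
    return(frame_window(0L, n_frames))
  entry <- as.integer(water_entry_frame)
  if (entry >= n_frames) {
    warning("water entry at frame ", entry, " is at/after the end (",
            n_frames, " frames); keeping the full window", call. = FALSE)
    return(frame_window(0L, n_frames))
  }
  if (entry == 0L)
    stop("water entered the selectivity filter at frame 0: no usable data",
         call. = FALSE)
  frame_window(0L, entry)
}

#' Gate-distance time series
#'
#' @param time numeric vector (ns).
#' @param distance numeric vector of gate distances (angstrom; e.g. the mean
#'   of the two diagonals), same length, all positive.
#' @param diagonal_labels optional labels of the two diagonal pairs.
#' @return list of class `gate_series`.
#' @export
gate_series <- function(time, distance, diagonal_labels = NULL) {
  stopifnot(length(time) == length(distance), all(distance > 0))
  structure(list(time = as.numeric(time), distance = as.numeric(distance),
                 diagonal_labels = diagonal_labels), class = "gate_series")
}

#' Frame window in which the inner gate is stable
#'
#' Either passes an explicit time window through verbatim (converted to
#' frame indices) or finds, heuristically, the longest window obtained by
#' truncating initial frames such that the rolling mean of the gate distance
#' drifts by no more than `max_drift` over the remainder — the usual way of
#' discarding an unstable initial opening.
#'
#' @param series a [gate_series()].
#' @param explicit optional numeric `c(t_start, t_end)` in time units; the
#'   returned window spans frames with `t_start <= time < t_end`.
#' @param window_length rolling-mean window in frames (heuristic mode).
#' @param max_drift maximum allowed range of the rolling mean (angstrom).
#' @param min_frames minimum span a stable window must cover (default twice
#'   the rolling window; a shorter tail is not evidence of stability).
#' @return a [frame_window()].
#' @export
stable_gate_window <- function(series, explicit = NULL, window_length = 10L,
                               max_drift = 0.5,
                               min_frames = 2L * window_length) {
  stopifnot(inherits(series, "gate_series"), length(series$time) > 0L)
  if (!is.null(explicit)) {
    stopifnot(length(explicit) == 2L, explicit[1] < explicit[2])
    i <- which(series$time >= explicit[1] & series$time < explicit[2])
    if (!length(i)) stop("no frames inside the explicit window",
                         call. = FALSE)
    return(frame_window(min(i) - 1L, max(i)))
  }
  n <- length(series$distance)
  w <- min(as.integer(window_length), n)
  roll <- stats::filter(series$distance, rep(1 / w, w), sides = 1)
  roll <- roll[!is.na(roll)] # rolling mean at frames w..n
  m <- length(roll)
  # smallest truncation k such that max-min of roll[k..m] <= max_drift
  suf_max <- rev(cummax(rev(roll)))
  suf_min <- rev(cummin(rev(roll)))
  ok <- which(suf_max - suf_min <= max_drift)
  if (length(ok) && n - (ok[1] - 1L) < min_frames) ok <- integer(0)
  if (!length(ok)) stop("no stable window found under drift bound ",
                        max_drift, call. = FALSE)
  # roll[k] summarizes frames (k .. k+w-1) of the series; start the window
  # at the first frame entering that rolling mean
  frame_window(ok[1] - 1L, n)
}

#' Selectivity-filter occupancy string
#'
#' Encodes the per-site occupancy of the selectivity filter (sites S0 to the
#' cavity site) as a string of symbols: `W` water, `K` potassium ion, `0`
#' empty — e.g. `"WKK0KW"`.
#'
#' @param site_states character vector over the tracked sites.
#' @param n_sites expected number of sites (default 6).
#' @return the concatenated string.
#' @export
occupancy_string <- function(site_states, n_sites = 6L) {
  site_states <- as.character(site_states)
  if (length(site_states) != n_sites)
    stop("expected ", n_sites, " sites, got ", length(site_states),
         call. = FALSE)
  bad <- !site_states %in% c("W", "K", "0")
  if (any(bad))
    stop("unknown occupancy symbol(s): ",
         paste(unique(site_states[bad]), collapse = ", "), call. = FALSE)
  paste(site_states, collapse = "")
}

#' @rdname occupancy_string
#' @param string an occupancy string.
#' @export
parse_occupancy <- function(string, n_sites = 6L) {
  s <- strsplit(string, "")[[1]]
  occupancy_string(s, n_sites) # validates
  s
}
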