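# build an snfit-like object from explicit parameter draws, for tests that
# need exact control over the posterior
fake_fit <- function(mu, sigma, alpha, ci_mass = 0.94) {
  n <- max(length(mu), length(sigma), length(alpha))
  structure(list(draws = data.frame(chain = 1L, mu = rep_len(mu, n),
                                    sigma = rep_len(sigma, n),
                                    alpha = rep_len(alpha, n)),
                 ci_mass = ci_mass, data = numeric(0), method = "fake"),
            class = "snfit")
}

# a fit store with one nucleus per entry; entries is a data.frame with
# residue_number, residue_type, atom, state, method and a list-column `fit`
fake_store <- function(entries) {
  ids <- paste(paste(entries$residue_number, entries$residue_type,
                     entries$atom, sep = "_"),
               entries$state, entries$method, sep = "|")
  fits <- entries$fit
  names(fits) <- ids
  structure(list(fits = fits,
                 index = entries[, c("residue_number", "residue_type",
                                     "atom", "state", "method")]),
            class = "snfit_store")
}

# canonical shift-record rows
shift_rows <- function(residue_number = 96L, residue_type = "M",
                       atom = "CA", state = "PO", method = "SPARTA+",
                       subunit = "A", frame = 0L, shift = 55) {
  data.frame(state = state, method = method, subunit = subunit,
             frame = frame, residue_number = residue_number,
             residue_type = residue_type, atom = atom, shift_ppm = shift,
             stringsAsFactors = FALSE)
}

# independent brute-force shortest-interval oracle over sorted draws
hdi_bruteforce <- function(draws, mass) {
  s <- sort(draws)
  n <- length(s)
  k <- max(1L, ceiling(mass * n))
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k)) {
    if (s[i + k] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + k])
  }
  best
}
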