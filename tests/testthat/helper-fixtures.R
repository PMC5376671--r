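# Small networks and brute-force oracles shared across tests.

# one self-less species relaxing toward F(basal)
single_species_spec <- function(gamma = 2, sigma = 10, basal = 0.3) {
  network_spec(
    species = "x", gamma = c(x = gamma), sigma = sigma, basal = c(x = basal),
    omega = matrix(0, 1, 3, dimnames = list("x", c("x", "RA", "FGF")))
  )
}

# two-species chain m -> p with morphogen input on m
chain_spec <- function(w_in = 1, w_tr = 1, gamma = c(m = 5, p = 2),
                       sigma = 10, basal = c(m = -0.3, p = -0.5)) {
  omega <- matrix(0, 2, 4, dimnames = list(c("m", "p"), c("m", "p", "RA", "FGF")))
  omega["m", "RA"] <- w_in
  omega["p", "m"] <- w_tr
  network_spec(c("m", "p"), gamma, sigma, basal, omega)
}

# brute-force transition zone / boundary scan used as the independent oracle
brute_zone <- function(occ, pos, lo = 0.15, hi = 0.85) {
  idx <- integer()
  for (i in seq_along(occ)) {
    if (occ[i] > lo && occ[i] < hi) idx <- c(idx, i)
  }
  spacing <- if (length(pos) > 1) pos[2] - pos[1] else 1
  if (!length(idx)) {
    list(width = 0, empty = TRUE, start = NA_real_, end = NA_real_)
  } else {
    list(
      width = pos[max(idx)] - pos[min(idx)] + spacing, empty = FALSE,
      start = pos[min(idx)], end = pos[max(idx)]
    )
  }
}

brute_boundary <- function(occ, pos, lo = 0.15, hi = 0.85) {
  z <- brute_zone(occ, pos, lo, hi)
  if (!any(occ >= hi) || !any(occ <= lo)) {
    return(NA_real_)
  }
  if (!z$empty) {
    return((z$start + z$end) / 2)
  }
  high <- occ >= hi
  for (i in seq_len(length(occ) - 1)) {
    if (high[i] != high[i + 1]) {
      return((pos[i] + pos[i + 1]) / 2)
    }
  }
  NA_real_
}
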