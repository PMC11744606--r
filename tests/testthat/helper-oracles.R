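# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles are deliberately literal (elementwise loops) so they stay
# independent of the vectorized implementations they check.

canberra_loop <- function(a, b) {
  total <- 0
  for (i in seq_along(a)) {
    den <- abs(a[i]) + abs(b[i])
    if (den > 0) total <- total + abs(a[i] - b[i]) / den
  }
  total
}

euclidean_loop <- function(a, b) {
  total <- 0
  for (i in seq_along(a)) total <- total + (a[i] - b[i])^2
  sqrt(total)
}

# Two-sided Monte-Carlo permutation p-value for the rank-sum statistic.
permutation_rank_p <- function(a, b, nperm = 10000L) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- sum(rank(pooled)[seq_len(na)])
  center <- na * (length(pooled) + 1) / 2
  stat <- replicate(nperm, sum(rank(pooled)[sample(length(pooled), na)]))
  mean(abs(stat - center) >= abs(obs - center) - 1e-12)
}

# Minimal two-atom PQR fixture: N (charge -0.3) and CA (+0.3) of ALA 1,
# chain C.
two_atom_pqr <- function() {
  c("ATOM 1 N ALA C 1 1.000 2.000 3.000 -0.3000 1.5000",
    "ATOM 2 CA ALA C 1 2.000 2.500 3.500 0.3000 1.7000")
}

# Synthetic multi-chain PQR text: chains with the given residue counts, one
# single-charge atom per residue.
chains_pqr <- function(counts, chains = LETTERS[seq_along(counts)]) {
  lines <- character(0)
  serial <- 0L
  for (ci in seq_along(counts)) {
    for (r in seq_len(counts[ci])) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM %d CA GLY %s %d %.3f %.3f %.3f 0.0000 1.5000",
        serial, chains[ci], r, r * 1.0, ci * 10.0, 0))
    }
  }
  lines
}

# Write a small RGBA PNG with constant channels; returns the path.
write_const_png <- function(r, g, b, a = NULL, w = 2L, h = 2L,
                            path = tempfile(fileext = ".png")) {
  nc <- if (is.null(a)) 3L else 4L
  arr <- array(0, dim = c(h, w, nc))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  if (!is.null(a)) arr[, , 4] <- a
  png::writePNG(arr, path)
  path
}

# Small residue table fixture shaped like aggregate_residues() output.
toy_residue_table <- function(epi_charges = rep(0, 9), n_hla = 12L) {
  hla <- data.frame(
    role = "HLA", residue_number = seq_len(n_hla), residue_name = "GLY",
    x = seq_len(n_hla), y = 0, z = 0, charge = 0, radius = 1.5,
    stringsAsFactors = FALSE
  )
  epi <- data.frame(
    role = "EPITOPE", residue_number = 1:9, residue_name = "ALA",
    x = 1:9, y = 1, z = 2, charge = epi_charges, radius = 1.6,
    stringsAsFactors = FALSE
  )
  rbind(hla, epi)
}

fast_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, image_size = c(64L, 48L), ...)
}
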