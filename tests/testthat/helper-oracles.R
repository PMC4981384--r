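# Independent oracles used across the suite.

# Gotoh affine-gap global alignment score (end gaps penalized): a gap of
# length k costs open + k * ext. Brute-force three-matrix DP, independent
# of the alignment backend.
affine_dp_score <- function(a, b, submat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[ca[i], cb[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Minimal substitutions from a codon to an amino acid: brute-force hamming
# distance over the target's codons.
hamming_min_to_aa <- function(codon, aa, code = Biostrings::GENETIC_CODE) {
  targets <- names(code)[code == aa]
  cc <- strsplit(codon, "")[[1]]
  min(vapply(targets, function(t)
    sum(strsplit(t, "")[[1]] != cc), integer(1)))
}

random_peptide <- function(len, residues = strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Uniform-terminus pKa table: Bjellqvist side chains with position-
# independent terminal pKs (used for model properties that require fixed
# terminal groups).
uniform_pka <- list(
  cterm = c(), cterm_default = 3.55,
  nterm = c(), nterm_default = 7.50,
  negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  positive = c(H = 5.98, K = 10.00, R = 12.00))
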