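# ORF calling, translation and physicochemical profiling.

# ExPASy-style average (isotopically averaged) residue masses, Da.
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy scale.
.KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

# Bjellqvist (ExPASy Compute pI/MW) pKa set. Side chains of D, E, C, Y, K, R,
# H; position-specific N-terminal alpha-amino pKa; the C-terminal carboxyl
# pKa depends on the C-terminal residue (Asp 4.55, Glu 4.75, else 3.55).
.BJELLQVIST <- list(
  cterm = c(D = 4.55, E = 4.75),
  cterm_default = 3.55,
  nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
            E = 7.70, G = 7.50),
  nterm_default = 7.50,
  negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  positive = c(H = 5.98, K = 10.00, R = 12.00))

#' Translate a coding sequence with the standard genetic code
#'
#' Translation stops at (and does not emit) the first stop codon; any codon
#' containing `N` is emitted as `X`.
#'
#' @param cds DNA string whose length is a multiple of 3.
#' @param code Named codon-to-residue table; default the standard nuclear
#'   genetic code (`Biostrings::GENETIC_CODE`, stops as `"*"`).
#' @return Protein string.
#' @examples
#' translate_cds("ATGTAA")     # "M"
#' translate_cds("ATGNNNTAA")  # "MX"
#' @export
translate_cds <- function(cds, code = Biostrings::GENETIC_CODE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

#' Find the longest ATG-initiated open reading frame
#'
#' Scans the forward strand only (inputs are assembled, oriented transcripts).
#' An ORF runs from an `ATG` to the first in-frame stop codon, stop included;
#' the longest such ORF wins, ties broken by the smallest start. Reported
#' coordinates are 0-based half-open offsets into the transcript, so
#' `length_bp = end - start` includes the stop codon and the protein length
#' is `length_bp/3 - 1`.
#'
#' @param record One-row nucleotide record data frame (or a list with `id`
#'   and `sequence`).
#' @return List of class `orf_call`: `transcript_id`, `start`, `end`,
#'   `frame`, `length_bp`, `protein` (one-row protein record).
#' @examples
#' orf <- find_orf(list(id = "t", sequence = "ATGAAATAA"))
#' orf$length_bp                 # 9
#' orf$protein$sequence          # "MK"
#' @export
find_orf <- function(record) {
  seq <- toupper(record$sequence[[1]])
  id <- record$id[[1]]
  n <- nchar(seq)
  if (n < 6L) stop("sequence '", id, "' too short to contain an ORF")
  chars <- strsplit(seq, "")[[1]]
  codon_at <- function(i) paste(chars[i:(i + 2L)], collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    for (a in atg) {
      s_after <- stp[stp > a]
      if (!length(s_after)) next
      s <- s_after[1]
      len <- (s - a + 1L) * 3L
      start0 <- starts[a] - 1L
      if (is.null(best) || len > best$length_bp ||
          (len == best$length_bp && start0 < best$start)) {
        best <- list(start = start0, end = start0 + len, frame = frame,
                     length_bp = len)
      }
    }
  }
  if (is.null(best))
    stop("no ATG-initiated, stop-terminated ORF in '", id, "'")
  cds <- substring(seq, best$start + 1L, best$end)
  prot <- translate_cds(cds)
  structure(list(transcript_id = id, start = best$start, end = best$end,
                 frame = best$frame, length_bp = best$length_bp,
                 cds = cds,
                 protein = data.frame(id = id, description = "",
                                      sequence = prot,
                                      stringsAsFactors = FALSE)),
            class = "orf_call")
}

#' Average-isotopic protein molecular weight
#'
#' Sum of average residue masses plus one water (18.01524 Da), matching the
#' ExPASy Compute pI/MW mass scale.
#'
#' @param protein Protein string (standard residues only; `X` is an error).
#' @return Mass in Da.
#' @examples
#' compute_mw("G")  # 75.0671
#' @export
compute_mw <- function(protein) {
  if (!nzchar(protein)) stop("empty protein")
  chars <- strsplit(toupper(protein), "")[[1]]
  bad <- which(!(chars %in% names(.RESIDUE_MASS)))
  if (length(bad))
    stop("cannot compute mass for residue '", chars[bad[1]],
         "' at position ", bad[1])
  sum(.RESIDUE_MASS[chars]) + .WATER_MASS
}

# Net charge of a peptide at a given pH under Henderson-Hasselbalch,
# Bjellqvist-style pKa table.
.net_charge <- function(counts, nterm_res, cterm_res, pH, pka) {
  pos_pk <- pka$positive
  neg_pk <- pka$negative
  q <- 0
  nt_pk <- if (nterm_res %in% names(pka$nterm)) pka$nterm[[nterm_res]] else pka$nterm_default
  ct_pk <- if (cterm_res %in% names(pka$cterm)) pka$cterm[[cterm_res]] else pka$cterm_default
  q <- q + 1 / (1 + 10^(pH - nt_pk))                       # N-terminus
  q <- q - 1 / (1 + 10^(ct_pk - pH))                       # C-terminus
  for (r in names(pos_pk))
    q <- q + counts[[r]] / (1 + 10^(pH - pos_pk[[r]]))
  for (r in names(neg_pk))
    q <- q - counts[[r]] / (1 + 10^(neg_pk[[r]] - pH))
  q
}

#' Isoelectric point by bisection (Bjellqvist pKa set)
#'
#' Solves `Q(pH) = 0` where `Q` sums Henderson-Hasselbalch terms over the
#' ionizable side chains (D, E, C, Y, H, K, R) and both termini. Bisection on
#' `[0, 14]` runs until `|Q| < 1e-4`. The default pKa table is the
#' Bjellqvist set used by the ExPASy Compute pI/MW service; an alternative
#' set with the same structure can be injected, since computed pI values are
#' pKa-set-dependent.
#'
#' @param protein Protein string (`X` allowed, ignored: not ionizable).
#' @param pka_set Named list with `cterm`, `nterm`, `nterm_default`,
#'   `negative`, `positive` (see `crucarb:::.BJELLQVIST`).
#' @return pI in pH units.
#' @export
compute_pi <- function(protein, pka_set = .BJELLQVIST) {
  if (!nzchar(protein)) stop("empty protein")
  chars <- strsplit(toupper(protein), "")[[1]]
  bad <- which(!(chars %in% .AA_ALPHABET))
  if (length(bad)) stop("illegal residue '", chars[bad[1]], "'")
  ion <- c(names(pka_set$negative), names(pka_set$positive))
  counts <- as.list(setNames(vapply(ion, function(r) sum(chars == r),
                                    numeric(1)), ion))
  lo <- 0; hi <- 14
  while ((hi - lo) > 1e-7) {
    mid <- (lo + hi) / 2
    q <- .net_charge(counts, chars[1], chars[length(chars)], mid, pka_set)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-residue Kyte-Doolittle hydropathy profile
#'
#' @param protein Protein string (`X` scores 0).
#' @return Numeric vector, one value per residue.
#' @export
kd_profile <- function(protein) {
  chars <- strsplit(toupper(protein), "")[[1]]
  unname(.KD_SCALE[chars])
}

#' Count N-glycosylation sequons
#'
#' Counts `N-X-S/T` windows with `X != P`, the classical sequon. This is a
#' declared motif proxy for glycosylation potential, not a reproduction of
#' neural-network site predictors.
#'
#' @param protein Protein string.
#' @return Integer count.
#' @examples
#' scan_sequons("NGS")  # 1
#' scan_sequons("NPS")  # 0
#' @export
scan_sequons <- function(protein) {
  chars <- strsplit(toupper(protein), "")[[1]]
  n <- length(chars)
  if (n < 3L) return(0L)
  i <- seq_len(n - 2L)
  sum(chars[i] == "N" & chars[i + 1L] != "P" & chars[i + 2L] %in% c("S", "T"))
}

#' Naive phospho-acceptor inventory
#'
#' Counts of serine, threonine and tyrosine residues: an upper bound on
#' phosphorylatable sites, again a declared proxy rather than a predictor.
#'
#' @param protein Protein string.
#' @return Named integer vector `c(S=, T=, Y=)`.
#' @export
count_sty <- function(protein) {
  chars <- strsplit(toupper(protein), "")[[1]]
  c(S = sum(chars == "S"), T = sum(chars == "T"), Y = sum(chars == "Y"))
}

#' Physicochemical profile of one protein
#'
#' @param protein Protein string.
#' @return List of class `physchem_profile`: `length_aa`, `mw_kda`, `pi`,
#'   `kd_profile`, `n_glyc_sequons`, `st_y_sites`.
#' @export
physchem_profile <- function(protein) {
  structure(list(
    length_aa = nchar(protein),
    mw_kda = compute_mw(protein) / 1000,
    pi = compute_pi(protein),
    kd_profile = kd_profile(protein),
    n_glyc_sequons = scan_sequons(protein),
    st_y_sites = count_sty(protein)), class = "physchem_profile")
}

#' ORF and physicochemical table for a set of transcripts
#'
#' Runs [find_orf()] and [physchem_profile()] on every nucleotide record and
#' assembles the per-isozyme characteristics table (ORF coordinates and
#' length, protein length, molecular weight in kDa, pI, sequon count).
#'
#' @param nt_records Nucleotide record data frame from [read_fasta()].
#' @return Data frame, one row per transcript, with 1-based inclusive
#'   `orf_start`/`orf_end`.
#' @export
physchem_table <- function(nt_records) {
  rows <- lapply(seq_len(nrow(nt_records)), function(i) {
    orf <- find_orf(nt_records[i, ])
    p <- orf$protein$sequence
    prof <- physchem_profile(p)
    data.frame(id = orf$transcript_id,
               orf_start = orf$start + 1L, orf_end = orf$end,
               orf_bp = orf$length_bp,
               length_aa = prof$length_aa,
               mw_kda = round(prof$mw_kda, 2),
               pi = round(prof$pi, 2),
               n_glyc_sequons = prof$n_glyc_sequons,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
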