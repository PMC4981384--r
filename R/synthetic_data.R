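# Seed-deterministic generators producing inputs with the structure the
# pipeline assumes, together with per-record ground truth, so every stage is
# testable without external data.
#
# Protein records are built on the bundled human CAII backbone: canonical
# active-site positions are planted per configuration, all other positions
# are randomly substituted at a controlled rate drawn from a polar residue
# alphabet (so random drift cannot create the hydrophobic signatures the
# localization heuristics look for), and class-specific N-/C-terminal
# elements (signal peptide, transmembrane tail, GPI tail) are appended in a
# form the detectors provably recognize. CDSs are back-translations with
# uniform synonymous codon choice, framed ATG..stop and flanked by
# pyrimidine-only UTR noise (which cannot contain an upstream ATG).

# Residues used for random substitutions: polar/charged only, no Cys (bridge
# columns stay meaningful), no strongly hydrophobic residues (localization
# signals stay where they were planted).
.SUB_ALPHABET <- c("D", "E", "G", "K", "N", "P", "Q", "R", "S", "T")

# Signal-peptide prefix recognized by detect_signal_peptide() with cleavage
# after its 16th residue: Met + neutral n-region, Leu core, Ala-Ser-Ala end.
.SP_PREFIX <- "MKKLLLLLLLLLLASA"

.CODON_TABLE <- NULL
.codons_for <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  names(code)[code == aa]
}

.back_translate <- function(protein, planted = list()) {
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(seq_along(chars), function(i) {
    if (!is.null(planted[[as.character(i)]])) return(planted[[as.character(i)]])
    syn <- .codons_for(chars[i])
    syn[sample.int(length(syn), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

.utr_noise <- function(len) {
  paste(sample(c("C", "T"), len, replace = TRUE), collapse = "")
}

#' Generate CA-like coding sequences with planted features and ground truth
#'
#' Each record is a mutated copy of the CAII backbone with, per
#' configuration: a subcellular-localization class realized through planted
#' N-/C-terminal elements, a zinc-binding triad that is either catalytic
#' (`H-H-H`) or a CARP substitution (e.g. `R-H-Q`, optionally with explicit
#' planted codons), a proton-shuttle and gatekeeper residue choice,
#' disulfide-bridge cysteines at the homologous bridge columns, and the
#' conserved QSPID motif. Proteins are back-translated to a CDS (uniform
#' synonymous codons except planted ones), framed `ATG..stop`, and flanked
#' by UTR noise free of upstream ATGs.
#'
#' @param n Number of records (config vectors are recycled to `n`).
#' @param config List of per-record settings, all optional:
#'   `class` (default `"secreted"`), `triad` (triplet string `"H-H-H"` etc.,
#'   default catalytic), `triad_codons` (comma-separated codons or `NA`),
#'   `shuttle` (default `"H"`), `gatekeeper_199` (default `"T"`),
#'   `bridge_canonical` (default `TRUE` for non-cytosolic),
#'   `bridge_cnidarian` (default `FALSE`), `qspid` (default `TRUE`),
#'   `sp`, `gpi` (normally implied by `class`; an explicit `gpi = TRUE`
#'   with `sp = FALSE` is contradictory and raises an error),
#'   `mutation_rate` (scalar, default 0.30), `ids` (default `synCA<i>`).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List: `nt` (nucleotide records), `aa` (protein records), `truth`
#'   (data frame of planted ground truth per record).
#' @export
generate_ca_cds <- function(n, config = list(), seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  ref <- caii_reference()
  pos <- ref$canonical_positions
  backbone0 <- strsplit(ref$sequence, "")[[1]]
  cfg <- function(name, default) {
    v <- if (is.null(config[[name]])) default else config[[name]]
    rep(v, length.out = n)
  }
  classes <- cfg("class", "secreted")
  ok_classes <- c("cytosolic", "secreted", "membrane_bound_tm",
                  "membrane_bound_gpi")
  if (!all(classes %in% ok_classes))
    stop("unknown class in config; allowed: ",
         paste(ok_classes, collapse = ", "))
  sp_flags <- cfg("sp", classes != "cytosolic")
  gpi_flags <- cfg("gpi", classes == "membrane_bound_gpi")
  if (any(gpi_flags & !sp_flags))
    stop("contradictory config: GPI anchor without a signal peptide")
  triads <- cfg("triad", "H-H-H")
  triad_codons <- cfg("triad_codons", NA_character_)
  shuttles <- cfg("shuttle", "H")
  gk199 <- cfg("gatekeeper_199", "T")
  br_can <- cfg("bridge_canonical", classes != "cytosolic")
  br_cni <- cfg("bridge_cnidarian", FALSE)
  qspid <- cfg("qspid", TRUE)
  rate <- if (is.null(config$mutation_rate)) 0.30 else config$mutation_rate
  ids <- cfg("ids", paste0("synCA", seq_len(n)))

  protected <- sort(unique(c(pos$triad, pos$shuttle,
                             unname(pos$gatekeepers), 28:33,
                             pos$bridge_canonical, pos$bridge_cnidarian, 1L)))
  nt <- aa <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    bb <- backbone0
    tri <- strsplit(triads[i], "-")[[1]]
    if (length(tri) != 3L) stop("triad must be a 3-letter triplet string")
    bb[pos$triad] <- tri
    bb[pos$shuttle] <- shuttles[i]
    bb[pos$gatekeepers["thr"]] <- gk199[i]
    if (qspid[i]) bb[28:33] <- strsplit("QSPIDI", "")[[1]]
    if (br_can[i]) bb[pos$bridge_canonical] <- "C"
    if (br_cni[i]) bb[pos$bridge_cnidarian] <- "C"
    mutable <- setdiff(seq_along(bb), protected)
    n_mut <- round(rate * length(mutable))
    sites <- sample(mutable, n_mut)
    bb[sites] <- sample(.SUB_ALPHABET, n_mut, replace = TRUE)

    prefix <- if (sp_flags[i]) .SP_PREFIX else ""
    suffix <- ""
    if (gpi_flags[i]) {
      suffix <- paste0("GSA", strrep("L", 18))
    } else if (classes[i] == "membrane_bound_tm") {
      suffix <- paste0("QQ", strrep("I", 21), "KKRR")
      # no omega-site candidates may sit 15-35 residues from the new
      # C-terminus, or the GPI detector would fire on the TM tail
      ltot <- nchar(prefix) + length(bb) + nchar(suffix)
      band <- which((ltot - (nchar(prefix) + seq_along(bb))) %in% 15:35)
      bb[band][bb[band] %in% c("A", "C", "D", "G", "N", "S")] <- "Q"
    }
    protein <- paste0(prefix, paste(bb, collapse = ""), suffix)
    off <- nchar(prefix)
    planted <- list()
    if (!is.na(triad_codons[i])) {
      tcod <- strsplit(triad_codons[i], ",")[[1]]
      if (length(tcod) != 3L) stop("triad_codons needs 3 codons")
      for (k in 1:3) {
        if (Biostrings::GENETIC_CODE[[tcod[k]]] != tri[k])
          stop("planted codon ", tcod[k], " does not encode ", tri[k])
        planted[[as.character(off + pos$triad[k])]] <- tcod[k]
      }
    }
    cds <- paste0(.back_translate(protein, planted),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    utr5 <- .utr_noise(sample(20:60, 1L))
    utr3 <- .utr_noise(sample(20:60, 1L))
    transcript <- paste0(utr5, cds, utr3)
    ltot <- nchar(protein)
    planted_codons <- vapply(1:3, function(k) {
      qp <- off + pos$triad[k]
      substring(cds, 3L * qp - 2L, 3L * qp)
    }, character(1))
    truth[[i]] <- data.frame(
      id = ids[i], class = classes[i],
      cleavage_pos = if (sp_flags[i]) nchar(.SP_PREFIX) else NA_integer_,
      omega_site = if (gpi_flags[i]) ltot - 18L else NA_integer_,
      triplet = triads[i],
      triad_codons = paste(planted_codons, collapse = ","),
      triad_query_pos = paste(off + pos$triad, collapse = ","),
      is_carp = any(tri != "H"),
      shuttle = shuttles[i], gatekeeper_199 = gk199[i],
      bridge_canonical = br_can[i], bridge_cnidarian = br_cni[i],
      orf_start_0based = nchar(utr5), orf_bp = nchar(cds),
      stringsAsFactors = FALSE)
    nt[[i]] <- data.frame(id = ids[i], description = "synthetic transcript",
                          sequence = transcript, stringsAsFactors = FALSE)
    aa[[i]] <- data.frame(id = ids[i], description = "synthetic protein",
                          sequence = protein, stringsAsFactors = FALSE)
  }
  list(nt = do.call(rbind, nt), aa = do.call(rbind, aa),
       truth = do.call(rbind, truth))
}

#' The six-isozyme synthetic study set
#'
#' A fixed configuration of [generate_ca_cds()] emulating the structure of
#' the red-coral alpha-CA repertoire: six isozymes comprising one cytosolic
#' catalytic CA (no bridges, substituted shuttle), one secreted CARP with a
#' `Y-R-H` triad (two non-His slots), a proline in place of the Thr199
#' gatekeeper, a conserved shuttle and both disulfide bridges, three further
#' secreted catalytic CAs, and one GPI-anchored membrane-bound CA. Shuttle
#' residues across the set are Lys/His/Asn/Ser/Arg/His, so the shuttle is
#' conserved in exactly two isozymes (#2 and #6).
#'
#' @param seed Integer seed.
#' @return As [generate_ca_cds()].
#' @export
synthetic_study_set <- function(seed = 1L) {
  generate_ca_cds(6L, config = list(
    class = c("secreted", "secreted", "cytosolic", "secreted",
              "membrane_bound_gpi", "secreted"),
    triad = c("H-H-H", "Y-R-H", "H-H-H", "H-H-H", "H-H-H", "H-H-H"),
    triad_codons = c(NA, "TAC,CGC,CAC", NA, NA, NA, NA),
    shuttle = c("K", "H", "N", "S", "R", "H"),
    gatekeeper_199 = c("T", "P", "T", "T", "T", "T"),
    bridge_canonical = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    bridge_cnidarian = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    seed = seed)
}

#' Generate synthetic qPCR Ct tables with known efficiencies and folds
#'
#' Ct values follow the standard-curve model
#' `Ct = intercept + slope * log10(quantity)` with `slope = -1/log10(E)`,
#' plus Gaussian cycle noise. Per-gene 10-fold dilution series (for curve
#' fitting) and a full fractions x biological x technical replicate design
#' are emitted, together with the planted truth.
#'
#' @param genes Data frame with columns `gene`, `efficiency` (`E > 1`),
#'   optionally `intercept` (default 25).
#' @param folds Numeric matrix `genes x fractions` of true expression fold
#'   changes relative to the control fraction (reference/housekeeping genes
#'   have fold 1 everywhere).
#' @param design List: `fractions` (default `c("total", "calcifying",
#'   "polyps")`, first is the control), `n_bio` (default 3), `n_tech`
#'   (default 3), `dilutions` (default `0:-4`).
#' @param noise_sd Gaussian Ct noise, cycles (default 0.15).
#' @param seed Integer seed.
#' @return List: `ct` (Ct table), `dilution_series` (named list of data
#'   frames), `truth` (data frame `gene`, `efficiency`, one `fold_<fraction>`
#'   column per fraction).
#' @export
generate_qpcr <- function(genes, folds,
                          design = list(), noise_sd = 0.15, seed = 1L) {
  set.seed(seed)
  if (any(genes$efficiency <= 1)) stop("efficiency must exceed 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  fractions <- design$fractions %||% c("total", "calcifying", "polyps")
  n_bio <- design$n_bio %||% 3L
  n_tech <- design$n_tech %||% 3L
  dil <- design$dilutions %||% (0:-4)
  if (is.null(genes$intercept)) genes$intercept <- 25
  if (is.null(dim(folds)))
    folds <- matrix(folds, nrow = nrow(genes), ncol = length(fractions))
  rows <- list()
  series <- list()
  for (g in seq_len(nrow(genes))) {
    slope <- -1 / log10(genes$efficiency[g])
    series[[genes$gene[g]]] <- data.frame(
      log10_dilution = dil,
      ct = genes$intercept[g] + slope * dil +
        stats::rnorm(length(dil), 0, noise_sd))
    for (f in seq_along(fractions)) {
      for (b in seq_len(n_bio)) {
        ct0 <- genes$intercept[g] + slope * log10(folds[g, f])
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes$gene[g], fraction = fractions[f],
          bio_rep = paste0("b", b), tech_rep = paste0("t", seq_len(n_tech)),
          ct = ct0 + stats::rnorm(n_tech, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- data.frame(gene = genes$gene, efficiency = genes$efficiency,
                      stringsAsFactors = FALSE)
  for (f in seq_along(fractions))
    truth[[paste0("fold_", fractions[f])]] <- folds[, f]
  list(ct = do.call(rbind, rows), dilution_series = series, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
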