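# Codon-level analysis of how the zinc-binding histidines mutate in CARPs:
# single-substitution neighborhoods, transition/transversion classes,
# minimal mutational paths, and the observed triad codons.

.BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

#' Classify a single-nucleotide substitution
#'
#' @param from,to Single bases.
#' @return `"transition"` (purine-purine or pyrimidine-pyrimidine) or
#'   `"transversion"`.
#' @export
mutation_class <- function(from, to) {
  if (from == to) stop("not a substitution")
  if ((from %in% .PURINES) == (to %in% .PURINES)) "transition" else "transversion"
}

#' Single-substitution neighborhood of a codon
#'
#' Enumerates all nine single-nucleotide variants of a codon; every codon
#' has exactly three transition neighbors and six transversion neighbors.
#' His is encoded by `CAC`/`CAT`, so this neighborhood describes which
#' residues a zinc-binding histidine can reach in one mutational step.
#'
#' @param codon DNA triplet over `A/C/G/T`.
#' @param code Genetic-code table (default standard).
#' @return List of class `codon_neighborhood`: `codon`, `aa`, `neighbors`
#'   (data frame `codon`, `position`, `mutation_class`, `aa`, `synonymous`).
#' @examples
#' nb <- codon_neighborhood("CAC")
#' sort(unique(nb$neighbors$aa[nb$neighbors$aa != "H"]))  # 7 residues + stop-free
#' @export
codon_neighborhood <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  chars <- strsplit(codon, "")[[1]]
  if (length(chars) != 3L || !all(chars %in% .BASES))
    stop("codon must be a triplet over A/C/G/T: ", codon)
  aa0 <- unname(code[codon])
  rows <- list()
  for (p in 1:3) {
    for (b in setdiff(.BASES, chars[p])) {
      mut <- chars; mut[p] <- b
      mcodon <- paste(mut, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        codon = mcodon, position = p,
        mutation_class = mutation_class(chars[p], b),
        aa = unname(code[mcodon]),
        synonymous = unname(code[mcodon]) == aa0,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(codon = codon, aa = aa0, neighbors = do.call(rbind, rows)),
            class = "codon_neighborhood")
}

#' Minimal mutational path from a codon to an amino acid
#'
#' Breadth-first search over the 64-codon graph whose edges are single
#' nucleotide substitutions, stopping at the first level containing a codon
#' of the target residue. Returns the minimal substitution count (0-3) and
#' all codons of the target reachable at that distance.
#'
#' @param from_codon Starting DNA triplet.
#' @param to_aa Target residue (1-letter) or `"*"` for stop.
#' @param code Genetic-code table.
#' @return List of class `mutation_path`: `from_codon`, `to_aa`,
#'   `min_substitutions`, `witness_codons`.
#' @examples
#' min_path("CAC", "Q")$witness_codons  # CAA, CAG at distance 1
#' @export
min_path <- function(from_codon, to_aa, code = Biostrings::GENETIC_CODE) {
  from_codon <- toupper(from_codon)
  to_aa <- toupper(to_aa)
  if (!(to_aa %in% c(unique(unname(code)))))
    stop("unknown residue: ", to_aa)
  frontier <- from_codon
  seen <- from_codon
  dist <- 0L
  repeat {
    hits <- frontier[unname(code[frontier]) == to_aa]
    if (length(hits))
      return(structure(list(from_codon = from_codon, to_aa = to_aa,
                            min_substitutions = dist,
                            witness_codons = sort(hits)),
                       class = "mutation_path"))
    nxt <- unique(unlist(lapply(frontier, function(cd)
      codon_neighborhood(cd, code)$neighbors$codon)))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    dist <- dist + 1L
    if (dist > 3L) stop("BFS exceeded codon-space diameter")  # unreachable
  }
}

# Distance from the His codon family {CAC, CAT} to a residue, with the
# closest family member and the ti/tv composition of one minimal set of
# changes from it.
.from_his_family <- function(codon, code = Biostrings::GENETIC_CODE) {
  fam <- c("CAC", "CAT")
  chars <- strsplit(codon, "")[[1]]
  per <- lapply(fam, function(h) {
    hc <- strsplit(h, "")[[1]]
    diff <- which(hc != chars)
    list(from = h, n = length(diff),
         classes = vapply(diff, function(p) mutation_class(hc[p], chars[p]),
                          character(1)))
  })
  best <- per[[which.min(vapply(per, `[[`, integer(1), "n"))]]
  best
}

#' Observed triad codons of CARPs
#'
#' For every CARP in the input set, reads the actual codons at the three
#' zinc-binding triad slots from its CDS, measures how far each observed
#' codon lies from the ancestral His codon family (`CAC`/`CAT`): minimal
#' substitution count, and the transition/transversion composition of the
#' changes from the closest His codon. Flags the `R-H-Q` signature and the
#' permissive variant (`R/H/Y`, `H/R`, `Q/H`) observed across metazoan
#' CARPs. Catalytic (non-CARP) records produce no rows.
#'
#' @param cds_set List of entries, each a list with `protein` (one-row
#'   protein record), `cds` (ORF nucleotide string, with or without the
#'   stop codon) and `profile` (`active_site_profile`).
#' @return Data frame with one row per CARP triad slot, plus per-isozyme
#'   columns `triplet`, `rhq`, `rhq_permissive`.
#' @export
triplet_codon_report <- function(cds_set) {
  rows <- list()
  for (entry in cds_set) {
    prot <- entry$protein$sequence[[1]]
    id <- entry$protein$id[[1]]
    profile <- entry$profile
    cds <- toupper(entry$cds)
    translated <- translate_cds(cds)
    if (translated != prot)
      stop("CDS does not translate to the protein for '", id, "'")
    if (!profile$is_carp) next
    triad <- profile$triad
    slot_aa <- ifelse(is.na(triad$residue), "-", triad$residue)
    rhq <- identical(unname(slot_aa), c("R", "H", "Q"))
    rhq_perm <- slot_aa[1] %in% c("R", "H", "Y") &&
      slot_aa[2] %in% c("H", "R") && slot_aa[3] %in% c("Q", "H")
    for (k in 1:3) {
      qp <- triad$query_pos[k]
      if (is.na(qp)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, slot = k, caii_pos = triad$caii_pos[k],
          residue = NA_character_, codon = NA_character_,
          min_substitutions = NA_integer_, nearest_his_codon = NA_character_,
          n_transitions = NA_integer_, n_transversions = NA_integer_,
          triplet = profile$triplet, rhq = rhq, rhq_permissive = rhq_perm,
          stringsAsFactors = FALSE)
        next
      }
      codon <- substring(cds, 3L * qp - 2L, 3L * qp)
      fh <- .from_his_family(codon)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, slot = k, caii_pos = triad$caii_pos[k],
        residue = triad$residue[k], codon = codon,
        min_substitutions = fh$n, nearest_his_codon = fh$from,
        n_transitions = sum(fh$classes == "transition"),
        n_transversions = sum(fh$classes == "transversion"),
        triplet = profile$triplet, rhq = rhq, rhq_permissive = rhq_perm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id = character(), slot = integer(),
                      caii_pos = integer(), residue = character(),
                      codon = character(), min_substitutions = integer(),
                      nearest_his_codon = character(),
                      n_transitions = integer(), n_transversions = integer(),
                      triplet = character(), rhq = logical(),
                      rhq_permissive = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
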