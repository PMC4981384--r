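# Mapping isozymes onto CAII residue numbering and calling the active site.
#
# The coordinate frame for every catalytic call is the bundled human CAII
# chain (see caii_reference()). Each query is mapped onto it by one pairwise
# global alignment, which replaces a multiple alignment: it is deterministic
# and sufficient to read six canonical positions.

#' Global alignment of a query protein against a reference
#'
#' Needleman-Wunsch global alignment with affine gaps (end gaps penalized),
#' BLOSUM62 scoring, default gap open 11 / extend 1. Returns the residue map
#' between the two coordinate systems: one `(query_pos, ref_pos)` pair per
#' aligned (non-gap) column, strictly increasing in both coordinates.
#'
#' @param query Protein string.
#' @param reference Protein string (defaults to the bundled CAII chain).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param matrix Substitution matrix name (a matrix bundled with Biostrings).
#' @return List of class `residue_map`: `query_id` (`NA` unless set by the
#'   caller), `pairs` (data frame `query_pos`, `ref_pos`, `query_res`,
#'   `ref_res`), `alignment_score`, `percent_identity` (fraction of
#'   identical columns over the full alignment length).
#' @export
align_global <- function(query, reference = caii_reference()$sequence,
                         gap_open = 11, gap_extend = 1, matrix = "BLOSUM62") {
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  submat <- get(utils::data(list = matrix, package = "Biostrings",
                            envir = environment()))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(pat != "-")
  rpos <- cumsum(sub != "-")
  keep <- pat != "-" & sub != "-"
  pairs <- data.frame(query_pos = qpos[keep], ref_pos = rpos[keep],
                      query_res = pat[keep], ref_res = sub[keep],
                      stringsAsFactors = FALSE)
  structure(list(query_id = NA_character_, pairs = pairs,
                 alignment_score = Biostrings::score(aln),
                 percent_identity = sum(pat == sub & keep) / length(pat)),
            class = "residue_map")
}

# Query position homologous to a reference position, NA if that reference
# column is unaligned (deleted in the query).
.map_ref_pos <- function(map, ref_pos) {
  hit <- match(ref_pos, map$pairs$ref_pos)
  ifelse(is.na(hit), NA_integer_, map$pairs$query_pos[hit])
}

#' Call the active-site profile of one isozyme
#'
#' Reads the query residues homologous to CAII 94/96/119 (zinc-binding
#' triad), 64 (proton shuttle) and 106/199 (gatekeepers) through the residue
#' map; assembles the three-letter triad signature (e.g. `"H-H-H"`,
#' `"R-H-Q"`); flags the record as a CARP when at least one triad slot is
#' not histidine (an unaligned/deleted slot also breaks zinc coordination
#' and counts as non-His); scans for the conserved `QSP[ID][DN]I` motif; and
#' calls the two disulfide-bridge cysteine pairs by column homology at the
#' bundled bridge anchors (canonical extracellular bridge; cnidarian-specific
#' secreted-cluster bridge). If any of the six canonical positions is
#' unaligned the corresponding slot is `NA` and the profile is flagged
#' `partial`.
#'
#' @param query One-row protein record data frame (or list with `id`,
#'   `sequence`).
#' @param map `residue_map` of the query against the bundled CAII reference
#'   (computed if missing).
#' @param positions Canonical position list, default
#'   `caii_reference()$canonical_positions`.
#' @return List of class `active_site_profile`: `id`, `triad` (data frame
#'   `caii_pos`, `query_pos`, `residue`), `shuttle`, `gatekeepers`,
#'   `triplet`, `is_carp`, `qspid_present`, `cys_bridge_canonical`,
#'   `cys_bridge_cnidarian`, `partial`, `percent_identity`.
#' @export
call_active_site <- function(query, map = NULL, positions = NULL) {
  seq <- query$sequence[[1]]
  id <- query$id[[1]]
  ref <- caii_reference()
  if (is.null(positions)) positions <- ref$canonical_positions
  if (is.null(map)) map <- align_global(seq, ref$sequence)
  res_at <- function(qp) ifelse(is.na(qp), NA_character_,
                                substring(seq, qp, qp))
  triad_q <- .map_ref_pos(map, positions$triad)
  triad <- data.frame(caii_pos = positions$triad, query_pos = triad_q,
                      residue = res_at(triad_q), stringsAsFactors = FALSE)
  shuttle_q <- .map_ref_pos(map, positions$shuttle)
  gk_q <- .map_ref_pos(map, positions$gatekeepers)
  gatekeepers <- data.frame(caii_pos = unname(positions$gatekeepers),
                            query_pos = gk_q, residue = res_at(gk_q),
                            role = c("glu106", "thr199"),
                            stringsAsFactors = FALSE)
  triplet <- paste(ifelse(is.na(triad$residue), "-", triad$residue),
                   collapse = "-")
  is_carp <- any(is.na(triad$residue) | triad$residue != "H")
  bridge <- function(cols) {
    qp <- .map_ref_pos(map, cols)
    all(!is.na(qp)) && all(substring(seq, qp, qp) == "C")
  }
  canonical6 <- c(triad_q, shuttle_q, gk_q)
  structure(list(
    id = id, triad = triad,
    shuttle = list(caii_pos = positions$shuttle, query_pos = shuttle_q,
                   residue = res_at(shuttle_q)),
    gatekeepers = gatekeepers,
    triplet = triplet, is_carp = is_carp,
    qspid_present = grepl("QSP[ID][DN]I", seq),
    cys_bridge_canonical = bridge(positions$bridge_canonical),
    cys_bridge_cnidarian = bridge(positions$bridge_cnidarian),
    partial = any(is.na(canonical6)),
    percent_identity = map$percent_identity), class = "active_site_profile")
}

#' Proton-shuttle status of an active-site profile
#'
#' The His64 shuttle transfers protons from the zinc-bound water; isozymes
#' lacking it have much lower hydrase efficiency.
#'
#' @param profile `active_site_profile` from [call_active_site()].
#' @return List: `status` (`"conserved"` or `"substituted"`), `residue`,
#'   `query_pos`.
#' @export
call_shuttle <- function(profile) {
  r <- profile$shuttle$residue
  if (is.na(r)) stop("profile for '", profile$id,
                     "' is incomplete at the shuttle position")
  list(status = if (r == "H") "conserved" else "substituted",
       residue = r, query_pos = profile$shuttle$query_pos)
}

#' Combined per-isozyme summary
#'
#' Joins active-site profiles, localization calls and physicochemical rows
#' by id into a single characteristics table, plus aggregate counts.
#'
#' @param profiles List of `active_site_profile`s.
#' @param localizations Data frame from [localize_table()].
#' @param physchem Data frame from [physchem_table()].
#' @return List: `table` (one row per isozyme) and `counts` (named list:
#'   `n`, `n_complete_triad`, `n_carp`, `n_signal_peptide`, and `n_per_class`).
#' @export
summarize_isozymes <- function(profiles, localizations, physchem) {
  ids <- vapply(profiles, `[[`, character(1), "id")
  if (!length(ids))
    return(list(table = data.frame(), counts = list(
      n = 0L, n_complete_triad = 0L, n_carp = 0L, n_signal_peptide = 0L,
      n_per_class = integer())))
  orphans <- c(setdiff(ids, localizations$id), setdiff(localizations$id, ids),
               setdiff(ids, physchem$id), setdiff(physchem$id, ids))
  if (length(orphans))
    stop("id sets differ across inputs; orphans: ",
         paste(unique(orphans), collapse = ", "))
  rows <- lapply(profiles, function(p) {
    loc <- localizations[localizations$id == p$id, ]
    phy <- physchem[physchem$id == p$id, ]
    sh <- call_shuttle(p)
    data.frame(id = p$id, class = loc$class, triplet = p$triplet,
               is_carp = p$is_carp,
               shuttle = sh$residue, shuttle_status = sh$status,
               gatekeeper_106 = p$gatekeepers$residue[1],
               gatekeeper_199 = p$gatekeepers$residue[2],
               qspid = p$qspid_present,
               bridge_canonical = p$cys_bridge_canonical,
               bridge_cnidarian = p$cys_bridge_cnidarian,
               sp_present = loc$sp_present, gpi_present = loc$gpi_present,
               orf_bp = phy$orf_bp, length_aa = phy$length_aa,
               mw_kda = phy$mw_kda, pi = phy$pi,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  complete_triad <- vapply(profiles, function(p)
    all(!is.na(p$triad$residue) & p$triad$residue == "H"), logical(1))
  list(table = tab,
       counts = list(n = nrow(tab),
                     n_complete_triad = sum(complete_triad),
                     n_carp = sum(tab$is_carp),
                     n_signal_peptide = sum(tab$sp_present),
                     n_per_class = table(tab$class)))
}

#' Active-site annotation table for a set of proteins
#'
#' @param aa_records Protein record data frame.
#' @param positions Optional canonical-position override.
#' @return List of `active_site_profile`s, named by id.
#' @export
annotate_isozymes <- function(aa_records, positions = NULL) {
  ref <- caii_reference()
  out <- lapply(seq_len(nrow(aa_records)), function(i) {
    map <- align_global(aa_records$sequence[i], ref$sequence)
    map$query_id <- aa_records$id[i]
    call_active_site(aa_records[i, ], map, positions)
  })
  names(out) <- aa_records$id
  out
}

#' Flatten active-site profiles into a table
#'
#' @param profiles List of `active_site_profile`s.
#' @return Data frame, one row per isozyme.
#' @export
profiles_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    data.frame(id = p$id, triplet = p$triplet, is_carp = p$is_carp,
               triad_94 = p$triad$residue[1], triad_94_pos = p$triad$query_pos[1],
               triad_96 = p$triad$residue[2], triad_96_pos = p$triad$query_pos[2],
               triad_119 = p$triad$residue[3], triad_119_pos = p$triad$query_pos[3],
               shuttle = p$shuttle$residue, shuttle_pos = p$shuttle$query_pos,
               gatekeeper_106 = p$gatekeepers$residue[1],
               gatekeeper_199 = p$gatekeepers$residue[2],
               gatekeeper_199_pos = p$gatekeepers$query_pos[2],
               qspid = p$qspid_present,
               bridge_canonical = p$cys_bridge_canonical,
               bridge_cnidarian = p$cys_bridge_cnidarian,
               partial = p$partial, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
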