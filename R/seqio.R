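# FASTA and table I/O, plus the bundled human CAII reference frame.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Read a FASTA file into a record data frame
#'
#' Records are returned as a plain data frame with one row per sequence:
#' `id` (first whitespace-delimited token of the header), `description`
#' (remainder of the header, `""` if none) and `sequence` (uppercased).
#' Sequences are validated against the requested alphabet: `A/C/G/T/N` for
#' `"dna"`, the 20 standard residues plus `X` for `"protein"`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return Data frame with columns `id`, `description`, `sequence`.
#' @examples
#' caii <- read_fasta(system.file("extdata", "CAII_human_P00918.fasta",
#'                                package = "crucarb"), "protein")
#' nchar(caii$sequence)  # 260
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (length(ids) && anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  allowed <- if (alphabet == "dna") .DNA_ALPHABET else .AA_ALPHABET
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for record '", ids[i], "'")
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad))
      stop("illegal ", alphabet, " character '", chars[bad[1]],
           "' in record '", ids[i], "' at position ", bad[1])
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' Headers are `id` or `id description`; sequences are wrapped at 60 columns.
#'
#' @param records Data frame with columns `id`, `description`, `sequence`
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Write and read result tables
#'
#' Thin wrappers fixing the dialects used throughout the pipeline (header
#' row, no row names, quoting as needed so embedded delimiters round-trip).
#' All coordinates in emitted tables are 1-based inclusive unless a column
#' name is suffixed `_0based`.
#'
#' @param rows Data frame.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `write_table()` invisibly returns `path`; `read_table()` returns a
#'   data frame.
#' @export
write_table <- function(rows, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(rows, file = path, sep = sep, quote = TRUE,
                     row.names = FALSE, col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' The bundled human CAII reference
#'
#' Human carbonic anhydrase II (UniProt P00918, 260 aa) is the universal
#' coordinate frame for alpha-CA active-site positions ("CAII numbering"):
#' zinc-binding triad His94/His96/His119, proton shuttle His64, gatekeepers
#' Glu106 and Thr199. CAII numbering is defined *by this fixture*: 1-based
#' positions on the bundled chain, shipped together with an explicit position
#' index (`canonical_positions`), not recomputed. The index also carries the
#' two disulfide-bridge column anchors used for cysteine-pair calls
#' (`bridge_canonical`, `bridge_cnidarian`); these columns are package
#' estimates for the extracellular-CA bridge positions, config-injectable in
#' [call_active_site()].
#'
#' The six catalytic positions are asserted on load; a corrupted fixture
#' raises an error.
#'
#' @return List with `record` (one-row protein record data frame),
#'   `sequence` (character scalar) and `canonical_positions` (named list:
#'   `triad`, `shuttle`, `gatekeepers`, `bridge_canonical`,
#'   `bridge_cnidarian`).
#' @examples
#' ref <- caii_reference()
#' substring(ref$sequence, 94, 94)  # "H"
#' @export
caii_reference <- function() {
  fa <- system.file("extdata", "CAII_human_P00918.fasta", package = "crucarb")
  idx <- system.file("extdata", "caii_positions.tsv", package = "crucarb")
  rec <- read_fasta(fa, "protein")
  pos <- utils::read.delim(idx, stringsAsFactors = FALSE)
  seq <- rec$sequence[1]
  at <- function(role) pos$caii_pos[pos$role == role]
  canonical <- list(
    triad = c(at("triad_1"), at("triad_2"), at("triad_3")),
    shuttle = at("proton_shuttle"),
    gatekeepers = c(glu = at("gatekeeper_glu"), thr = at("gatekeeper_thr")),
    bridge_canonical = c(at("bridge_canonical_1"), at("bridge_canonical_2")),
    bridge_cnidarian = c(at("bridge_cnidarian_1"), at("bridge_cnidarian_2"))
  )
  check <- pos[pos$role %in% c("triad_1", "triad_2", "triad_3",
                               "proton_shuttle", "gatekeeper_glu",
                               "gatekeeper_thr"), ]
  got <- substring(seq, check$caii_pos, check$caii_pos)
  if (!all(got == check$expected_residue))
    stop("CAII reference fixture failed its active-site invariants")
  list(record = rec, sequence = seq, canonical_positions = canonical)
}
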