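# Heuristic subcellular-localization calls: signal peptide, transmembrane
# segments, GPI anchor, and the three-way secretory classification.
#
# These detectors are declared, tunable hydropathy heuristics standing behind
# a stable interface; a side-channel table of precomputed external
# predictions can override them (see localize_table()).

#' Default localization heuristic parameters
#'
#' All thresholds of the three detectors in one place: Kyte-Doolittle (KD)
#' window means of 1.6 (signal-peptide core and transmembrane) and 1.0 (GPI
#' tail), window lengths 7 / 19 / 11, the n-region cap, the omega-residue
#' set and its distance band from the C-terminus.
#'
#' @return Named list of defaults.
#' @export
localization_params <- function() {
  list(sp_window = 7L, sp_kd_threshold = 1.6, sp_max_n_region = 12L,
       sp_search_end = 45L,
       small_m1 = c("A", "G", "S", "C", "T"),
       small_m3 = c("A", "G", "S", "C", "T", "V"),
       tm_window = 19L, tm_kd_threshold = 1.6,
       gpi_tail = 25L, gpi_window = 11L, gpi_kd_threshold = 1.0,
       omega_residues = c("A", "C", "D", "G", "N", "S"),
       omega_min_from_cterm = 15L, omega_max_from_cterm = 35L)
}

#' Detect an N-terminal signal peptide
#'
#' A von-Heijne-style tripartite heuristic: a positively-or-neutrally charged
#' n-region (at most `sp_max_n_region` residues, net charge K+R-D-E >= 0)
#' followed by a hydrophobic core (first window of `sp_window` residues with
#' mean KD >= `sp_kd_threshold`, fully within the first `sp_search_end`
#' residues), followed by a cleavage site obeying the (-3,-1) small-residue
#' rule: the last signal residue (-1) in `{A,G,S,C,T}` and the residue at
#' -3 in `{A,G,S,C,T,V}`. The cleavage position is the first downstream
#' position (up to residue 45) satisfying the rule. All three elements are
#' required for a positive call; the call is deterministic for fixed
#' parameters.
#'
#' @param protein Protein string (length >= 30).
#' @param params Parameter list, see [localization_params()].
#' @return List of class `sp_call`: `present`, `cleavage_pos` (1-based index
#'   of the last signal residue, `NA` if absent), `core_start`, `core_end`,
#'   `core_mean_kd`.
#' @export
detect_signal_peptide <- function(protein, params = localization_params()) {
  absent <- structure(list(present = FALSE, cleavage_pos = NA_integer_,
                           core_start = NA_integer_, core_end = NA_integer_,
                           core_mean_kd = NA_real_), class = "sp_call")
  n <- nchar(protein)
  if (n < 30L) return(absent)
  chars <- strsplit(toupper(protein), "")[[1]]
  kd <- kd_profile(protein)
  w <- params$sp_window
  last_start <- min(params$sp_search_end - w + 1L, n - w + 1L)
  if (last_start < 1L) return(absent)
  core_start <- NA_integer_
  for (s in seq_len(last_start)) {
    if (mean(kd[s:(s + w - 1L)]) >= params$sp_kd_threshold) {
      core_start <- s; break
    }
  }
  if (is.na(core_start)) return(absent)
  core_end <- core_start + w - 1L
  n_region <- chars[seq_len(core_start - 1L)]
  if (length(n_region) > params$sp_max_n_region) return(absent)
  net <- sum(n_region %in% c("K", "R")) - sum(n_region %in% c("D", "E"))
  if (net < 0) return(absent)
  cleave <- NA_integer_
  for (p in seq(core_end + 1L, min(params$sp_search_end, n))) {
    if (p - 2L < 1L) next
    if (chars[p] %in% params$small_m1 && chars[p - 2L] %in% params$small_m3) {
      cleave <- p; break
    }
  }
  if (is.na(cleave)) return(absent)
  structure(list(present = TRUE, cleavage_pos = cleave,
                 core_start = core_start, core_end = core_end,
                 core_mean_kd = mean(kd[core_start:core_end])),
            class = "sp_call")
}

#' Detect transmembrane segments in the mature chain
#'
#' Greedy left-to-right scan of the mature chain (residues after
#' `mature_from`): whenever a window of `tm_window` residues has mean KD >=
#' `tm_kd_threshold`, the window is extended rightwards while the running
#' mean stays at or above the threshold, emitted as a segment, and the scan
#' resumes after it. Segments are therefore maximal and non-overlapping.
#'
#' @param protein Protein string.
#' @param mature_from 1-based index of the first mature residue (1 if no
#'   signal peptide; `cleavage_pos + 1` otherwise).
#' @param params Parameter list, see [localization_params()].
#' @return Data frame with `start`, `end` (1-based, whole-protein
#'   coordinates) and `mean_kd`; zero rows if none.
#' @export
detect_tm_segments <- function(protein, mature_from = 1L,
                               params = localization_params()) {
  kd <- kd_profile(protein)
  n <- length(kd)
  w <- params$tm_window
  out <- list()
  i <- mature_from
  while (i + w - 1L <= n) {
    win_sum <- sum(kd[i:(i + w - 1L)])
    if (win_sum / w >= params$tm_kd_threshold) {
      end <- i + w - 1L
      while (end + 1L <= n &&
             (win_sum + kd[end + 1L]) / (end + 2L - i) >= params$tm_kd_threshold) {
        end <- end + 1L
        win_sum <- win_sum + kd[end]
      }
      out[[length(out) + 1L]] <- data.frame(start = i, end = end,
                                            mean_kd = win_sum / (end - i + 1L))
      i <- end + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      mean_kd = numeric()))
  do.call(rbind, out)
}

#' Detect a C-terminal GPI-anchor signal
#'
#' Positive iff the C-terminal `gpi_tail` residues contain a window of
#' `gpi_window` residues with mean KD >= `gpi_kd_threshold` (the hydrophobic
#' tail that is cleaved off), and a candidate omega residue (small residues
#' `{A,C,D,G,N,S}`) lies 15-35 residues from the C-terminus. The most
#' C-terminal candidate in the band is reported as the omega site.
#'
#' @param protein Protein string (length >= 50 required for a call).
#' @param params Parameter list, see [localization_params()].
#' @return List of class `gpi_call`: `present`, `omega_site` (1-based or
#'   `NA`), `cterm_hydrophobic_len` (longest terminal-window run with mean
#'   KD above threshold, 0 if none).
#' @export
detect_gpi <- function(protein, params = localization_params()) {
  absent <- structure(list(present = FALSE, omega_site = NA_integer_,
                           cterm_hydrophobic_len = 0L), class = "gpi_call")
  n <- nchar(protein)
  if (n < 50L) return(absent)
  chars <- strsplit(toupper(protein), "")[[1]]
  kd <- kd_profile(protein)
  tail_start <- n - params$gpi_tail + 1L
  w <- params$gpi_window
  best_len <- 0L
  for (s in seq(tail_start, n - w + 1L)) {
    if (mean(kd[s:(s + w - 1L)]) >= params$gpi_kd_threshold) {
      end <- s + w - 1L
      run_sum <- sum(kd[s:end])
      while (end + 1L <= n &&
             (run_sum + kd[end + 1L]) / (end + 2L - s) >= params$gpi_kd_threshold) {
        end <- end + 1L
        run_sum <- run_sum + kd[end]
      }
      best_len <- max(best_len, end - s + 1L)
    }
  }
  dist <- n - seq_len(n)  # residues C-terminal to each position
  cand <- which(chars %in% params$omega_residues &
                dist >= params$omega_min_from_cterm &
                dist <= params$omega_max_from_cterm)
  if (best_len < w || !length(cand)) {
    absent$cterm_hydrophobic_len <- best_len
    return(absent)
  }
  structure(list(present = TRUE, omega_site = max(cand),
                 cterm_hydrophobic_len = best_len), class = "gpi_call")
}

#' Classify subcellular localization from the three detector calls
#'
#' The classification applies the secretory-pathway logic used to sort
#' alpha-CA isozymes: GPI anchor on a signal-peptide-bearing chain means
#' membrane-bound via GPI; a transmembrane segment in the mature chain of a
#' signal-peptide-bearing chain means membrane-bound via TM; a signal
#' peptide alone means secreted; none of the three means cytosolic. A TM or
#' GPI signature without a signal peptide is biologically incoherent for
#' this family and is classified cytosolic with `warning_flag = TRUE`.
#'
#' @param sp `sp_call` from [detect_signal_peptide()].
#' @param tm_segments Data frame from [detect_tm_segments()].
#' @param gpi `gpi_call` from [detect_gpi()].
#' @return List of class `localization_call`: `sp`, `tm_segments`, `gpi`,
#'   `klass` (one of `cytosolic`, `secreted`, `membrane_bound_tm`,
#'   `membrane_bound_gpi`), `warning_flag`.
#' @export
classify_localization <- function(sp, tm_segments, gpi) {
  has_tm <- nrow(tm_segments) > 0L
  warning_flag <- FALSE
  if (sp$present && gpi$present) {
    klass <- "membrane_bound_gpi"
  } else if (sp$present && has_tm) {
    klass <- "membrane_bound_tm"
  } else if (sp$present) {
    klass <- "secreted"
  } else {
    klass <- "cytosolic"
    if (has_tm || gpi$present) warning_flag <- TRUE
  }
  structure(list(sp = sp, tm_segments = tm_segments, gpi = gpi,
                 klass = klass, warning_flag = warning_flag),
            class = "localization_call")
}

#' Run the three localization detectors on one protein
#'
#' @param protein Protein string.
#' @param params Parameter list, see [localization_params()].
#' @return A `localization_call` (see [classify_localization()]).
#' @export
localize_protein <- function(protein, params = localization_params()) {
  sp <- detect_signal_peptide(protein, params)
  mature_from <- if (sp$present) sp$cleavage_pos + 1L else 1L
  tm <- detect_tm_segments(protein, mature_from, params)
  gpi <- detect_gpi(protein, params)
  classify_localization(sp, tm, gpi)
}

#' Localization table for a set of proteins
#'
#' One row per protein with the detector evidence and the class. If
#' `external` is supplied (a data frame with columns `id`, `sp_present`,
#' `cleavage_pos`, `n_tm`, `gpi_present`, `omega_site` from external
#' predictors such as dedicated signal-peptide/TM/GPI servers), its rows
#' override the heuristic calls for matching ids and the class is recomputed
#' from the overridden evidence.
#'
#' @param aa_records Protein record data frame from [read_fasta()].
#' @param params Parameter list, see [localization_params()].
#' @param external Optional override data frame.
#' @return Data frame with columns `id`, `sp_present`, `cleavage_pos`,
#'   `n_tm`, `gpi_present`, `omega_site`, `class`, `warning_flag`.
#' @export
localize_table <- function(aa_records, params = localization_params(),
                           external = NULL) {
  rows <- lapply(seq_len(nrow(aa_records)), function(i) {
    id <- aa_records$id[i]
    loc <- localize_protein(aa_records$sequence[i], params)
    row <- data.frame(id = id,
                      sp_present = loc$sp$present,
                      cleavage_pos = loc$sp$cleavage_pos,
                      n_tm = nrow(loc$tm_segments),
                      gpi_present = loc$gpi$present,
                      omega_site = loc$gpi$omega_site,
                      class = loc$klass,
                      warning_flag = loc$warning_flag,
                      stringsAsFactors = FALSE)
    if (!is.null(external) && id %in% external$id) {
      ov <- external[external$id == id, , drop = FALSE][1, ]
      for (col in intersect(names(ov), c("sp_present", "cleavage_pos",
                                         "n_tm", "gpi_present",
                                         "omega_site")))
        row[[col]] <- ov[[col]]
      sp <- list(present = isTRUE(row$sp_present))
      gpi <- list(present = isTRUE(row$gpi_present))
      tm <- if (row$n_tm > 0) data.frame(start = NA) else data.frame()
      cl <- classify_localization(
        structure(sp, class = "sp_call"),
        if (row$n_tm > 0) data.frame(start = 1, end = 1, mean_kd = NA)
        else data.frame(start = integer(), end = integer(),
                        mean_kd = numeric()),
        structure(c(gpi, list(omega_site = row$omega_site,
                              cterm_hydrophobic_len = NA_integer_)),
                  class = "gpi_call"))
      row$class <- cl$klass
      row$warning_flag <- cl$warning_flag
    }
    row
  })
  do.call(rbind, rows)
}
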