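# Efficiency-corrected relative qPCR expression.
#
# Two quantities are computed per gene: (1) expression relative to a
# housekeeping reference within one fraction, rel = E_t^(-Ct_t) / E_r^(-Ct_r)
# (efficiency-adjusted 2^-dCt); (2) the Pfaffl between-fraction ratio,
# E_t^(dCt_t) / E_r^(dCt_r) with dCt = Ct_control - Ct_sample. At E = 2 the
# Pfaffl ratio reduces to the classic 2^-ddCt.

.check_ct <- function(ct) {
  need <- c("gene", "fraction", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0 | ct$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  invisible(ct)
}

# Collapse technical replicates: one Ct per (gene, fraction, bio_rep).
.collapse_tech <- function(ct, fun = mean) {
  .check_ct(ct)
  stats::aggregate(ct ~ gene + fraction + bio_rep, data = ct, FUN = fun)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 of the template dilution; the
#' amplification efficiency is `E = 10^(-1/slope)` (E = 2 means perfect
#' doubling each cycle, reached at slope -3.3219).
#'
#' @param dilution_series Data frame with columns `log10_dilution` and `ct`
#'   (at least 3 distinct dilution points).
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r2`.
#' @examples
#' d <- data.frame(log10_dilution = 0:-4, ct = 18 + 3.3219 * (0:4))
#' fit_standard_curve(d)$efficiency  # 2
#' @export
fit_standard_curve <- function(dilution_series) {
  if (nrow(dilution_series) < 3L ||
      length(unique(dilution_series$log10_dilution)) < 3L)
    stop("standard curve needs at least 3 distinct dilution points")
  fit <- stats::lm(ct ~ log10_dilution, data = dilution_series)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) stop("singular standard-curve fit")
  e <- 10^(-1 / slope)
  if (e <= 1 || e > 2.2)
    warning("efficiency ", round(e, 3), " outside the usable range (1, 2.2]")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dilution_series$ct - mean(dilution_series$ct))^2)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 efficiency = e,
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "standard_curve")
}

# Efficiency for one gene from a curves object: either a named numeric
# vector of efficiencies or a named list of standard_curve fits.
.efficiency_of <- function(curves, gene) {
  if (is.null(curves[[gene]])) stop("no efficiency/curve for gene '", gene, "'")
  e <- curves[[gene]]
  if (inherits(e, "standard_curve")) e <- e$efficiency
  as.numeric(e)
}

#' Relative expression within fractions (efficiency-adjusted dCt)
#'
#' Technical replicates are collapsed by `collapse` per (gene, fraction,
#' biological replicate); per biological replicate the expression of
#' `target` relative to `reference` is `E_t^(-Ct_t) / E_r^(-Ct_r)`; the
#' mean and SEM across biological replicates are reported per fraction.
#'
#' @param ct Ct table: data frame with columns `gene`, `fraction`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @param target,reference Gene names.
#' @param curves Named list/vector of efficiencies or `standard_curve`s.
#' @param collapse Function collapsing technical replicates (default mean;
#'   `median` is the conventional alternative).
#' @return Data frame: `gene`, `fraction`, `rel_expr`, `sem`, `n_bio`.
#' @export
relative_expression_method1 <- function(ct, target, reference, curves,
                                        collapse = mean) {
  m <- .collapse_tech(ct, collapse)
  et <- .efficiency_of(curves, target)
  er <- .efficiency_of(curves, reference)
  out <- list()
  for (f in unique(m$fraction)) {
    t_rows <- m[m$gene == target & m$fraction == f, ]
    r_rows <- m[m$gene == reference & m$fraction == f, ]
    if (!nrow(r_rows))
      stop("reference gene '", reference, "' missing in fraction '", f, "'")
    if (!nrow(t_rows))
      stop("target gene '", target, "' missing in fraction '", f, "'")
    common <- intersect(t_rows$bio_rep, r_rows$bio_rep)
    rel <- vapply(common, function(b) {
      et^(-t_rows$ct[t_rows$bio_rep == b]) /
        er^(-r_rows$ct[r_rows$bio_rep == b])
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      gene = target, fraction = f, rel_expr = mean(rel),
      sem = if (length(rel) > 1) stats::sd(rel) / sqrt(length(rel)) else NA_real_,
      n_bio = length(rel), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pfaffl efficiency-corrected between-fraction ratio
#'
#' `ratio = E_t^(Ct_t,control - Ct_t,sample) / E_r^(Ct_r,control - Ct_r,sample)`,
#' computed per biological replicate (replicates pair fractions from the
#' same colony) and averaged; reported with SEM.
#'
#' @inheritParams relative_expression_method1
#' @param control_fraction,sample_fraction Fraction names; the ratio is
#'   expression in `sample_fraction` relative to `control_fraction`.
#' @return Data frame: `gene`, `sample_fraction`, `control_fraction`,
#'   `ratio`, `sem`, `n_bio`.
#' @export
pfaffl_ratio <- function(ct, target, reference, curves,
                         control_fraction, sample_fraction,
                         collapse = mean) {
  m <- .collapse_tech(ct, collapse)
  et <- .efficiency_of(curves, target)
  er <- .efficiency_of(curves, reference)
  pick <- function(g, f) m[m$gene == g & m$fraction == f, ]
  tc <- pick(target, control_fraction); ts <- pick(target, sample_fraction)
  rc <- pick(reference, control_fraction); rs <- pick(reference, sample_fraction)
  if (!nrow(tc) || !nrow(ts))
    stop("target '", target, "' missing in a fraction")
  if (!nrow(rc) || !nrow(rs))
    stop("reference '", reference, "' missing in a fraction")
  common <- Reduce(intersect, list(tc$bio_rep, ts$bio_rep, rc$bio_rep,
                                   rs$bio_rep))
  if (!length(common)) stop("no shared biological replicates across fractions")
  ratio <- vapply(common, function(b) {
    dct_t <- tc$ct[tc$bio_rep == b] - ts$ct[ts$bio_rep == b]
    dct_r <- rc$ct[rc$bio_rep == b] - rs$ct[rs$bio_rep == b]
    et^dct_t / er^dct_r
  }, numeric(1))
  data.frame(gene = target, sample_fraction = sample_fraction,
             control_fraction = control_fraction,
             ratio = mean(ratio),
             sem = if (length(ratio) > 1)
               stats::sd(ratio) / sqrt(length(ratio)) else NA_real_,
             n_bio = length(ratio), stringsAsFactors = FALSE)
}

#' Rank housekeeping candidates by expression stability
#'
#' The most usable reference gene is the one whose per-fraction mean Ct
#' varies least across fractions; candidates are ranked by the coefficient
#' of variation (sd/mean) of the per-fraction mean Ct, lower = more stable.
#'
#' @param ct Ct table (see [relative_expression_method1()]).
#' @param candidates Character vector of at least two gene names; the table
#'   must span at least two fractions.
#' @return Data frame sorted by increasing CV: `gene`, `cv`, `rank`.
#' @export
housekeeping_stability <- function(ct, candidates) {
  if (length(candidates) < 2L) stop("need at least two candidate genes")
  m <- .collapse_tech(ct)
  if (length(unique(m$fraction)) < 2L)
    stop("stability screening needs at least two fractions")
  cv <- vapply(candidates, function(g) {
    rows <- m[m$gene == g, ]
    if (!nrow(rows)) stop("candidate '", g, "' not in the Ct table")
    per_frac <- tapply(rows$ct, rows$fraction, mean)
    stats::sd(per_frac) / mean(per_frac)
  }, numeric(1))
  out <- data.frame(gene = candidates, cv = unname(cv),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cv), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classical group comparisons for expression values
#'
#' Two groups: two-sided Student t test with pooled (equal) variance.
#' Three or more: one-way ANOVA F test. Significance is conventionally read
#' at P < 0.05; no multiple-testing correction is applied.
#'
#' @param values Named list of numeric vectors, one per group (>= 2
#'   replicates each).
#' @return List: `method` (`"t"` or `"anova"`), `statistic`, `p_value`, `df`.
#' @export
group_tests <- function(values) {
  if (length(values) < 2L) stop("need at least two groups")
  if (any(vapply(values, length, integer(1)) < 2L))
    stop("need at least two replicates per group")
  pooled <- unlist(values)
  if (stats::sd(pooled) == 0 && length(values) == 2L) {
    # identical constant groups: t = 0 by convention
    return(list(method = "t", statistic = 0, p_value = 1,
                df = length(pooled) - 2L))
  }
  if (length(values) == 2L) {
    if (stats::sd(values[[1]]) == 0 && stats::sd(values[[2]]) == 0 &&
        mean(values[[1]]) != mean(values[[2]]))
      stop("degenerate (zero) within-group variance")
    tt <- stats::t.test(values[[1]], values[[2]], var.equal = TRUE)
    list(method = "t", statistic = unname(tt$statistic),
         p_value = tt$p.value, df = unname(tt$parameter))
  } else {
    g <- factor(rep(names(values), vapply(values, length, integer(1))),
                levels = names(values))
    fit <- stats::aov(unlist(values) ~ g)
    a <- stats::anova(fit)
    f <- a$`F value`[1]
    if (!is.finite(f)) f <- 0
    list(method = "anova", statistic = f,
         p_value = if (f == 0) 1 else a$`Pr(>F)`[1],
         df = a$Df)
  }
}
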