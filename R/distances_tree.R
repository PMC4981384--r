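# Pairwise identity / p-distance / Poisson-corrected distance matrices and
# neighbor-joining trees with Newick output.

# Comparable columns of a prealigned pair: both non-gap.
.pair_columns <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb))
    stop("prealigned sequences differ in length")
  keep <- ca != "-" & cb != "-"
  list(a = ca[keep], b = cb[keep])
}

#' Pairwise proportion of differing sites (p-distance)
#'
#' `p = mismatches / compared sites`, where compared sites exclude every
#' column containing a gap in either sequence (complete deletion at the
#' pair level). In `"pairwise_align"` mode the two sequences are first
#' aligned globally ([align_global()]); `"prealigned"` mode expects
#' equal-length rows of an existing alignment.
#'
#' @param a,b Protein strings (aligned rows may contain `-`).
#' @param mode `"pairwise_align"` or `"prealigned"`.
#' @return Proportion in `[0, 1]`.
#' @examples
#' pairwise_p_distance("AA-A", "AATA", mode = "prealigned")  # 0
#' @export
pairwise_p_distance <- function(a, b, mode = c("pairwise_align", "prealigned")) {
  mode <- match.arg(mode)
  if (mode == "pairwise_align") {
    map <- align_global(a, b)
    cols <- list(a = map$pairs$query_res, b = map$pairs$ref_res)
  } else {
    cols <- .pair_columns(toupper(a), toupper(b))
  }
  n <- length(cols$a)
  if (n == 0L) stop("zero comparable sites")
  sum(cols$a != cols$b) / n
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)`: the expected number of substitutions per site under a
#' Poisson model of repeated hits, inflating the observed proportion of
#' differences. Defined for `0 <= p < 1`; `p = 1` is saturation.
#'
#' @param p Proportion(s) of differing sites.
#' @return Substitutions per site, `d >= p`.
#' @examples
#' poisson_correct(0.5)  # 0.6931
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1))
    stop("p must lie in [0, 1); p = 1 is saturated")
  -log(1 - p)
}

#' Pairwise distance (or identity) matrix for a protein set
#'
#' @param aa_records Protein record data frame; in `"prealigned"` mode the
#'   sequences are equal-length alignment rows.
#' @param kind `"identity"` (fraction identical over compared sites),
#'   `"p_distance"` or `"poisson"`.
#' @param mode Passed to [pairwise_p_distance()].
#' @param min_site_coverage Optional column filter for prealigned input:
#'   columns with less than this fraction of non-gap residues across the
#'   whole set are removed before pair comparisons (e.g. `0.95`). `NULL`
#'   disables the filter.
#' @return List of class `distance_matrix`: `labels`, `values` (symmetric
#'   matrix), `kind`.
#' @export
distance_matrix <- function(aa_records,
                            kind = c("p_distance", "poisson", "identity"),
                            mode = c("pairwise_align", "prealigned"),
                            min_site_coverage = NULL) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  seqs <- aa_records$sequence
  labels <- aa_records$id
  if (mode == "prealigned" && !is.null(min_site_coverage)) {
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    cover <- colMeans(mat != "-")
    mat <- mat[, cover >= min_site_coverage, drop = FALSE]
    seqs <- apply(mat, 1, paste, collapse = "")
  }
  n <- length(seqs)
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      p <- pairwise_p_distance(seqs[i], seqs[j], mode)
      val <- switch(kind,
                    identity = 1 - p,
                    p_distance = p,
                    poisson = poisson_correct(p))
      v[i, j] <- v[j, i] <- val
    }
  }
  if (kind == "identity") diag(v) <- 1
  structure(list(labels = labels, values = v, kind = kind),
            class = "distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a symmetric distance
#' matrix; negative branch-length estimates are clamped to zero and the
#' tree is flagged. The tree is unrooted with leaf set equal to the matrix
#' labels, and round-trips through Newick.
#'
#' @param dm `distance_matrix` (kind `p_distance` or `poisson`) or a plain
#'   symmetric numeric matrix with dimnames.
#' @return List of class `nj_tree`: `phylo` (an \pkg{ape} tree),
#'   `clamped` (TRUE if any negative branch length was clamped).
#' @export
neighbor_joining <- function(dm) {
  v <- if (inherits(dm, "distance_matrix")) dm$values else dm
  if (inherits(dm, "distance_matrix") && dm$kind == "identity")
    stop("neighbor joining needs a distance kind, not identity")
  if (!isSymmetric(unname(v), tol = 1e-8)) stop("distance matrix is asymmetric")
  if (nrow(v) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(v)
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  structure(list(phylo = tr, clamped = clamped), class = "nj_tree")
}

#' Write / read a tree in Newick format
#'
#' @param tree `nj_tree` or an \pkg{ape} `phylo`.
#' @param path File path.
#' @return `write_newick()` invisibly returns `path`; `read_newick()`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ph <- if (inherits(tree, "nj_tree")) tree$phylo else tree
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
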