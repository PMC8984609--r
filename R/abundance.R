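# Relative-abundance bookkeeping: normalisation, heatmap filtering,
# trait-weighted site comparison, analytic rarefaction.

as_abundance_matrix <- function(x, field = "table") {
  if (is.data.frame(x)) {
    if ("genome_id" %in% names(x)) {
      rn <- as.character(x$genome_id)
      x <- as.matrix(x[setdiff(names(x), "genome_id")])
      rownames(x) <- rn
    } else x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop_field(field, "must be a numeric matrix or data.frame")
  if (is.null(rownames(x)))
    stop_field(field, "must have genome ids as row names (or a genome_id column)")
  if (any(x < 0)) stop_field(field, "must be non-negative")
  x
}

#' Per-sample relative abundance
#'
#' Normalises a genome-by-sample coverage table so each sample column sums
#' to 100 (percent).
#'
#' @param coverage numeric matrix (genomes x samples) with genome ids as
#'   row names, or a data.frame with a `genome_id` column.
#' @return matrix of relative abundances (percent); columns sum to 100.
#' @export
relative_abundance <- function(coverage) {
  cov <- as_abundance_matrix(coverage, "coverage")
  tot <- colSums(cov)
  zero <- colnames(cov)[tot == 0]
  if (length(zero))
    stop(sprintf("sample(s) with zero total coverage: %s",
                 paste(zero, collapse = ", ")), call. = FALSE)
  sweep(cov, 2L, tot / 100, "/")
}

#' Cumulative-abundance filter for heatmaps
#'
#' Keeps genomes whose cumulative abundance — the SUM of their relative
#' abundance across all samples — is strictly greater than `threshold`
#' percent. A genome summing to exactly the threshold is dropped.
#'
#' @param table relative-abundance matrix (see [relative_abundance()]).
#' @param threshold cumulative-percent cutoff, default 1.
#' @return character vector of retained genome ids.
#' @export
cumulative_filter <- function(table, threshold = 1) {
  ab <- as_abundance_matrix(table)
  check_number(threshold, "threshold", allow_vector = FALSE)
  rownames(ab)[rowSums(ab) > threshold]
}

#' Infer sample groups from sample names
#'
#' Samples named `<GROUP>-<replicate>` (e.g. `RZ-A`, `ND-C`) are grouped
#' by the prefix before the first hyphen.
#'
#' @param samples character vector of sample names.
#' @return named character vector mapping sample to group.
#' @export
sample_groups_from_names <- function(samples) {
  setNames(sub("-.*$", "", samples), samples)
}

#' Trait-weighted relative abundance of a sample group
#'
#' Summed relative abundance of the genomes assigned to at least one of
#' `module_ids`, averaged (unweighted mean) over the samples of `group` —
#' the statistic behind site-level comparisons such as "the relative
#' abundance of MAGs with this metabolic potential was higher at site X".
#'
#' @param table relative-abundance matrix (percent).
#' @param matrix long-form assignment matrix from [build_matrix()].
#' @param module_ids module ids defining the trait.
#' @param group group label to summarise.
#' @param groups named character vector mapping sample name to group;
#'   defaults to [sample_groups_from_names()] on the table's columns.
#' @return mean percent abundance of trait carriers in the group.
#' @export
trait_weighted_abundance <- function(table, matrix, module_ids, group,
                                     groups = NULL) {
  ab <- as_abundance_matrix(table)
  groups <- groups %||% sample_groups_from_names(colnames(ab))
  unknown <- setdiff(module_ids, unique(matrix$module_id))
  if (length(unknown))
    stop(sprintf("unknown module id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  samples <- names(groups)[groups == group]
  samples <- intersect(samples, colnames(ab))
  if (length(samples) == 0L)
    stop(sprintf("no samples in group '%s'", group), call. = FALSE)
  carriers <- unique(matrix$genome_id[matrix$assigned &
                                        matrix$module_id %in% module_ids])
  carriers <- intersect(rownames(ab), carriers)
  persample <- colSums(ab[carriers, samples, drop = FALSE])
  mean(persample)
}

#' Analytic rarefaction curve
#'
#' Expected taxon richness in random subsamples of a count vector,
#' evaluated at `n = step, 2*step, ...` and at the full depth `N`:
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N - N_i}{n} / \binom{N}{n}\right]}
#' computed with log-binomials (`lchoose`) so large depths do not
#' overflow. The final point (`n = N`) equals the observed richness.
#'
#' @param counts non-negative integer vector of per-taxon counts for one
#'   sample (zeros are ignored).
#' @param step subsample-size increment, default 2000.
#' @return data.frame with columns `n` and `expected_richness`.
#' @export
#' @examples
#' rarefaction_curve(c(A = 2, B = 2), step = 1)
rarefaction_curve <- function(counts, step = 2000) {
  check_number(counts, "counts", 0)
  check_number(step, "step", 1, allow_vector = FALSE)
  if (any(counts != floor(counts)))
    stop_field("counts", "must be whole numbers")
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 1) stop_field("counts", "must contain at least one observation")
  sizes <- unique(c(seq(step, N, by = step), N))
  rich <- vapply(sizes, function(n) {
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, 0)
  data.frame(n = sizes, expected_richness = rich)
}

#' Binned-community coverage fraction
#'
#' Given the genome (MAG) coverage table and the per-sample unbinned
#' coverage remainder, reports what fraction of the community the binned
#' genomes represent — a coverage-based proxy for marker-gene recovery
#' estimates.
#'
#' @param coverage genome-by-sample coverage matrix.
#' @param unbinned numeric vector of unbinned coverage per sample (same
#'   order/names as the table's columns).
#' @return list with `per_sample` (named percent vector) and `overall`
#'   (percent of total coverage that is binned).
#' @export
community_recovery <- function(coverage, unbinned) {
  cov <- as_abundance_matrix(coverage, "coverage")
  check_number(unbinned, "unbinned", 0)
  if (length(unbinned) != ncol(cov))
    stop_field("unbinned", "must have one value per sample")
  binned <- colSums(cov)
  list(per_sample = setNames(100 * binned / (binned + unbinned), colnames(cov)),
       overall = 100 * sum(binned) / (sum(binned) + sum(unbinned)))
}
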