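# Genome quality gates.
#
# Two gates are applied in sequence, mirroring standard MAG workflows:
#   1. bin refinement: completeness > 50% AND contamination < 10% (strict);
#   2. tree inclusion: quality = completeness - 5 * contamination, genomes
#      with quality < 40 removed (quality exactly 40 is kept).

#' Genome quality score
#'
#' Computes the single-number quality score used to decide which
#' metagenome-assembled genomes enter the phylogenetic tree:
#' \deqn{Quality = completeness - 5 \times contamination}
#' Both inputs are CheckM-style percentages. The score may be negative for
#' heavily contaminated bins.
#'
#' @param completeness completeness percentage in `[0, 100]`.
#' @param contamination contamination percentage, `>= 0`.
#' @return numeric vector of quality scores (percent scale).
#' @export
#' @examples
#' quality_score(100, 0)   # 100
#' quality_score(50, 10)   # 0
#' quality_score(75.05, 4.74)
quality_score <- function(completeness, contamination) {
  check_number(completeness, "completeness", 0, 100)
  check_number(contamination, "contamination", 0)
  completeness - 5 * contamination
}

validate_genomes <- function(genomes) {
  if (!is.data.frame(genomes))
    stop_field("genomes", "must be a data.frame")
  need <- c("genome_id", "completeness", "contamination")
  miss <- setdiff(need, names(genomes))
  if (length(miss))
    stop_field("genomes", paste("missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(genomes$genome_id))
    stop_field("genome_id", "must be unique within a dataset")
  check_number(genomes$completeness, "completeness", 0, 100)
  check_number(genomes$contamination, "contamination", 0)
  invisible(genomes)
}

#' Bin-refinement filter
#'
#' Keeps genomes passing the draft-genome refinement gate:
#' completeness strictly greater than 50% and contamination strictly less
#' than 10%. Boundary values (`completeness == 50`, `contamination == 10`)
#' are dropped.
#'
#' @param genomes data.frame with columns `genome_id`, `completeness`,
#'   `contamination` (and any others, preserved).
#' @return the filtered data.frame.
#' @export
filter_refined <- function(genomes) {
  validate_genomes(genomes)
  keep <- genomes$completeness > 50 & genomes$contamination < 10
  genomes[keep, , drop = FALSE]
}

#' Tree-inclusion filter
#'
#' Keeps genomes whose [quality_score()] is at least `min_quality`
#' (default 40): genomes with quality strictly below the threshold are
#' removed, so a quality of exactly 40 passes.
#'
#' @inheritParams filter_refined
#' @param min_quality minimum quality score retained (percent scale).
#' @return the filtered data.frame.
#' @export
filter_for_tree <- function(genomes, min_quality = 40) {
  validate_genomes(genomes)
  check_number(min_quality, "min_quality", allow_vector = FALSE)
  q <- quality_score(genomes$completeness, genomes$contamination)
  genomes[q >= min_quality, , drop = FALSE]
}

#' Per-genome quality report
#'
#' Scores every genome and records both gates. The gates are sequential: a
#' genome failing refinement never reaches the tree set, so
#' `passed_tree_filter` implies `passed_refinement`.
#'
#' @inheritParams filter_for_tree
#' @return data.frame with columns `genome_id`, `quality_score`,
#'   `passed_refinement`, `passed_tree_filter`.
#' @export
quality_report <- function(genomes, min_quality = 40) {
  validate_genomes(genomes)
  q <- quality_score(genomes$completeness, genomes$contamination)
  refined <- genomes$completeness > 50 & genomes$contamination < 10
  data.frame(
    genome_id = genomes$genome_id,
    quality_score = q,
    passed_refinement = refined,
    passed_tree_filter = refined & q >= min_quality,
    stringsAsFactors = FALSE
  )
}
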