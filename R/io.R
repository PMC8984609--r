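# Tabular file interfaces (TSV throughout).

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a genome table
#'
#' Expects a TSV with columns `genome_id`, `completeness`, `contamination`
#' and optionally `taxonomy`; validates ranges and id uniqueness.
#'
#' @param path file path.
#' @return data.frame of genome records.
#' @export
read_genomes <- function(path) {
  g <- read_tsv(path)
  validate_genomes(g)
  g
}

#' Read a long-form annotation table
#'
#' Expects a TSV with columns `genome_id` and `ko_id`, one identifier per
#' row.
#'
#' @param path file path.
#' @return data.frame with `genome_id`, `ko_id`.
#' @export
read_annotations <- function(path) {
  a <- read_tsv(path)
  miss <- setdiff(c("genome_id", "ko_id"), names(a))
  if (length(miss))
    stop_field("annotations", paste("missing column(s):",
                                    paste(miss, collapse = ", ")))
  a
}

#' Collect per-genome identifier sets from annotations
#'
#' Deduplicates (presence/absence only). Genomes listed in `genome_ids`
#' but absent from the annotation table get an empty set.
#'
#' @param annotations data.frame with `genome_id`, `ko_id`.
#' @param genome_ids optional character vector of all genome ids.
#' @return named list of character vectors.
#' @export
ko_sets_from_annotations <- function(annotations, genome_ids = NULL) {
  sets <- lapply(split(as.character(annotations$ko_id),
                       as.character(annotations$genome_id)), unique)
  if (!is.null(genome_ids)) {
    extra <- setdiff(genome_ids, names(sets))
    sets <- c(sets, setNames(rep(list(character()), length(extra)), extra))
    sets <- sets[as.character(genome_ids)]
  }
  sets
}

#' Read a coverage table
#'
#' Expects a TSV whose first column is `genome_id` and remaining columns
#' are samples.
#'
#' @param path file path.
#' @return numeric matrix (genomes x samples).
#' @export
read_coverage <- function(path) {
  as_abundance_matrix(read_tsv(path), "coverage")
}
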