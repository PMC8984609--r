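# Pathway assignment: module completeness + key-enzyme gating.
#
# Decision rule: a module is assigned to a genome when
#   (satisfied steps / total steps) >= threshold   (default 0.6)  AND
#   every key clause has at least one alternative fully present.
# Step satisfaction is binary (no partial credit inside a complex) and the
# completeness ratio is kept exact, never compared as a rounded percent.

#' Is a reaction step satisfied by a KO set?
#'
#' A step is a list of alternative complexes; it is satisfied when some
#' alternative has all of its identifiers present in `ko_set`.
#'
#' @param step list of character vectors (alternatives), or a grammar
#'   string like `"K00001,K00003+K00004"`.
#' @param ko_set character vector of identifiers carried by the genome.
#' @return logical flag.
#' @export
step_satisfied <- function(step, ko_set) {
  if (is.character(step) && length(step) == 1L) step <- parse_alternatives(step)
  if (length(step) == 0L) stop_field("step", "must have at least one alternative")
  any(vapply(step, function(alt) all(alt %in% ko_set), NA))
}

#' Module completeness of a genome
#'
#' The fraction of the module's steps satisfied by the genome's identifier
#' set (default), or optionally the raw fraction of the module's
#' identifiers present (`method = "ko_fraction"`).
#'
#' @param definition a `module_def`.
#' @param ko_set character vector of identifiers.
#' @param method `"steps"` (satisfied steps / total steps, the default) or
#'   `"ko_fraction"` (identifiers present / identifiers in module).
#' @return completeness fraction in `[0, 1]`.
#' @export
module_completeness <- function(definition, ko_set, method = c("steps", "ko_fraction")) {
  method <- match.arg(method)
  if (method == "ko_fraction") {
    ids <- module_identifiers(definition)
    return(sum(ids %in% ko_set) / length(ids))
  }
  sat <- vapply(definition$steps, step_satisfied, NA, ko_set = ko_set)
  sum(sat) / length(sat)
}

#' Are all key enzymes present?
#'
#' TRUE iff every key clause of the module has at least one alternative
#' whose identifiers are all in `ko_set`; vacuously TRUE for modules
#' without key clauses.
#'
#' @inheritParams module_completeness
#' @return logical flag.
#' @export
keys_present <- function(definition, ko_set) {
  all(vapply(definition$keys, step_satisfied, NA, ko_set = ko_set))
}

#' Assign a single module to a genome
#'
#' @inheritParams module_completeness
#' @param threshold minimum completeness fraction, in `(0, 1]`; the
#'   comparison is inclusive (a module exactly at the threshold passes).
#' @return one-row data.frame with `completeness`, `keys_present`,
#'   `assigned`.
#' @export
#' @examples
#' cat <- builtin_catalog()
#' assign_module(cat$CUST_DNRA, c("napA", "napB", "nirB", "nirD"))
assign_module <- function(definition, ko_set, threshold = 0.6) {
  check_number(threshold, "threshold", allow_vector = FALSE)
  if (threshold <= 0 || threshold > 1)
    stop_field("threshold", "must lie in (0, 1]")
  sat <- vapply(definition$steps, step_satisfied, NA, ko_set = ko_set)
  n <- length(sat)
  keys <- keys_present(definition, ko_set)
  # compare on counts (exact rationals) with a tiny slack so that exactly
  # 60% of, say, 5 steps is never lost to binary-float representation
  assigned <- keys && (sum(sat) >= threshold * n - 1e-9)
  data.frame(completeness = sum(sat) / n, keys_present = keys,
             assigned = assigned)
}

#' Build the genome-by-module assignment matrix
#'
#' Evaluates every genome against every module of the catalog. The result
#' is long-form, one row per (genome, module) cell, the shape written to
#' `matrix.tsv` by the command-line interface.
#'
#' @param genomes data.frame with at least `genome_id` (unique).
#' @param ko_sets named list mapping genome_id to its character vector of
#'   identifiers; see [ko_sets_from_annotations()]. Genomes absent from
#'   `ko_sets` are treated as carrying no identifiers.
#' @param catalog a `module_catalog`.
#' @param threshold completeness threshold, default 0.6.
#' @param aliases optional named character vector applied to both the
#'   catalog and the KO sets before matching (see [builtin_aliases()]).
#' @return data.frame with columns `genome_id`, `module_id`,
#'   `completeness`, `keys_present`, `assigned`.
#' @export
build_matrix <- function(genomes, ko_sets, catalog, threshold = 0.6,
                         aliases = NULL) {
  if (!is.data.frame(genomes) || !"genome_id" %in% names(genomes))
    stop_field("genomes", "must be a data.frame with a genome_id column")
  if (anyDuplicated(genomes$genome_id))
    stop_field("genome_id", "must be unique")
  validate_catalog(catalog)
  if (!is.null(aliases)) {
    catalog <- apply_aliases(catalog, aliases)
    ko_sets <- lapply(ko_sets, apply_aliases, aliases = aliases)
  }
  gids <- as.character(genomes$genome_id)
  mids <- names(catalog)
  if (length(gids) == 0L || length(mids) == 0L)
    return(data.frame(genome_id = character(), module_id = character(),
                      completeness = numeric(), keys_present = logical(),
                      assigned = logical()))
  rows <- lapply(gids, function(g) {
    kos <- ko_sets[[g]] %||% character()
    cells <- do.call(rbind, lapply(catalog, assign_module, ko_set = kos,
                                   threshold = threshold))
    data.frame(genome_id = g, module_id = mids, cells, row.names = NULL)
  })
  do.call(rbind, rows)
}

GTDB_RANKS <- c(domain = "d__", phylum = "p__", class = "c__", order = "o__",
                family = "f__", genus = "g__", species = "s__")

#' Extract one rank from GTDB-style taxonomy strings
#'
#' Taxonomy strings are 7-rank, semicolon-separated with GTDB prefixes
#' (`d__;p__;c__;o__;f__;g__;s__`). Records whose string is malformed at
#' the requested rank (wrong number of fields, missing prefix, or an empty
#' name) are returned as `"unclassified"` with one warning.
#'
#' @param taxonomy character vector of taxonomy strings.
#' @param rank one of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @return character vector of taxon names (without the rank prefix).
#' @export
parse_taxonomy <- function(taxonomy, rank = "phylum") {
  rank <- match.arg(rank, names(GTDB_RANKS))
  idx <- match(rank, names(GTDB_RANKS))
  prefix <- GTDB_RANKS[[rank]]
  parts <- strsplit(as.character(taxonomy), ";", fixed = TRUE)
  bad <- 0L
  out <- vapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) < idx || !startsWith(p[[idx]], prefix)) {
      bad <<- bad + 1L
      return("unclassified")
    }
    name <- sub(prefix, "", p[[idx]], fixed = TRUE)
    if (!nzchar(name)) "unclassified" else name
  }, "")
  if (bad > 0L)
    warning(sprintf("%d malformed taxonomy string(s) grouped as 'unclassified'", bad),
            call. = FALSE)
  out
}

#' Count assigned genomes per taxon and module
#'
#' Aggregates an assignment matrix at a chosen taxonomic rank, the way
#' genome-centric studies report "phylum X (n MAGs) contained gene Y".
#'
#' @param matrix long-form assignment matrix from [build_matrix()].
#' @param genomes data.frame with `genome_id` and `taxonomy` columns.
#' @param rank taxonomic rank to aggregate at (see [parse_taxonomy()]).
#' @return data.frame with columns `taxon`, `module_id`, `n_assigned`,
#'   `n_genomes` (genomes of that taxon evaluated).
#' @export
aggregate_by_taxon <- function(matrix, genomes, rank = "phylum") {
  if (nrow(matrix) == 0L)
    return(data.frame(taxon = character(), module_id = character(),
                      n_assigned = integer(), n_genomes = integer()))
  taxa <- setNames(parse_taxonomy(genomes$taxonomy, rank),
                   as.character(genomes$genome_id))
  m <- matrix
  m$taxon <- unname(taxa[m$genome_id])
  m$taxon[is.na(m$taxon)] <- "unclassified"
  agg <- stats::aggregate(cbind(n_assigned = m$assigned) ~ taxon + module_id,
                          data = m, FUN = sum)
  sizes <- stats::aggregate(cbind(n_genomes = m$assigned) ~ taxon + module_id,
                            data = m, FUN = length)
  out <- merge(agg, sizes, by = c("taxon", "module_id"), sort = TRUE)
  out$n_assigned <- as.integer(out$n_assigned)
  out$n_genomes <- as.integer(out$n_genomes)
  out[order(out$taxon, out$module_id), , drop = FALSE]
}
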