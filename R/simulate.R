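# Synthetic community generator.
#
# Emits every input the pipeline consumes, with known ground truth: genomes
# carrying trait blocks of identifiers, KO dropout proportional to genome
# incompleteness, KO gain from contamination, GTDB-style taxonomy strings,
# random rooted trees with exponential branch lengths, and lognormal
# per-sample coverages. The noise model is a documented stand-in (i.i.d.
# Bernoulli dropout; contamination sampled from a disjoint background
# pool), not a fit to real data.

derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults emulate a
#' two-site, six-sample phycosphere survey of roughly 200 recovered
#' genomes whose completeness and contamination lie inside the
#' bin-refinement gate.
#'
#' @param n_genomes number of genomes to simulate (>= 1).
#' @param n_samples number of coverage samples; 6 gives the two-site
#'   design `RZ-A..ND-C`.
#' @param seed master seed; fixes every artifact bit-for-bit. Separate
#'   sub-streams are derived for genomes, tree and coverages, so changing
#'   `n_samples` never perturbs the simulated genomes.
#' @param trait_assignment named list mapping a genome-group label to the
#'   module ids that group truly carries; default
#'   [default_trait_assignment()].
#' @param completeness_range,contamination_range percent intervals the
#'   per-genome completeness/contamination are drawn from (uniform).
#' @param background_ko_pool identifiers contamination can introduce;
#'   defaults to 500 synthetic K-numbers disjoint from the catalog.
#' @param lognormal_mu,lognormal_sigma meanlog/sdlog of the per-cell
#'   lognormal coverage draw.
#' @param branch_rate rate of the exponential branch-length distribution.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 200, n_samples = 6, seed = 1,
                       trait_assignment = NULL,
                       completeness_range = c(50, 100),
                       contamination_range = c(0, 10),
                       background_ko_pool = NULL,
                       lognormal_mu = 0, lognormal_sigma = 1.5,
                       branch_rate = 1) {
  check_number(n_genomes, "n_genomes", 1, allow_vector = FALSE)
  check_number(n_samples, "n_samples", 1, allow_vector = FALSE)
  check_number(seed, "seed", allow_vector = FALSE)
  check_number(completeness_range, "completeness_range", 0, 100)
  check_number(contamination_range, "contamination_range", 0, 100)
  if (length(completeness_range) != 2L || diff(completeness_range) < 0)
    stop_field("completeness_range", "must be an increasing length-2 interval")
  if (length(contamination_range) != 2L || diff(contamination_range) < 0)
    stop_field("contamination_range", "must be an increasing length-2 interval")
  check_number(lognormal_sigma, "lognormal_sigma", 0, allow_vector = FALSE)
  check_number(branch_rate, "branch_rate", allow_vector = FALSE)
  if (branch_rate <= 0) stop_field("branch_rate", "must be positive")
  structure(list(
    n_genomes = as.integer(n_genomes), n_samples = as.integer(n_samples),
    seed = as.integer(seed), trait_assignment = trait_assignment,
    completeness_range = completeness_range,
    contamination_range = contamination_range,
    background_ko_pool = background_ko_pool,
    lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
    branch_rate = branch_rate
  ), class = "sim_config")
}

#' Default genome-group to module-id trait assignment
#'
#' Eleven functional guilds over the shipped catalog (autotrophs, nitrate
#' reducers, denitrifiers, taurine degraders, thiosulfate oxidisers,
#' cobalamin producers and consumers, auxin producers, ACC degraders,
#' phosphatase carriers). The guilds' module blocks are mutually
#' non-triggering: no guild's full identifier set assigns a module outside
#' its own list, so ground-truth recovery is exact at full completeness.
#'
#' @param catalog catalog the module ids must exist in.
#' @return named list of character vectors of module ids.
#' @export
default_trait_assignment <- function(catalog = builtin_catalog()) {
  ta <- list(
    cbb_autotroph = "M00165",
    nitrate_assimilator = "CUST_ANRA",
    dnra_reducer = "CUST_DNRA",
    denitrifier = "CUST_DENITRIFICATION",
    taurine_degrader = c("CUST_TAURINE", "CUST_SULFITE_OX"),
    sox_oxidizer = "CUST_SOX",
    b12_producer = c("CUST_B12_AEROBIC", "CUST_DMB"),
    b12_consumer = c("CUST_B12_TRANSPORT", "CUST_METH"),
    auxin_producer = c("CUST_TAM", "CUST_IAM"),
    acc_degrader = c("CUST_ACC_DEAM", "CUST_AP"),
    phosphatase_carrier = "CUST_AP"
  )
  missing <- setdiff(unlist(ta), names(catalog))
  if (length(missing))
    stop(sprintf("trait modules absent from catalog: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ta
}

# lineage templates loosely following the phylum census of a phycosphere
# MAG survey (Bacteroidota-dominated, one archaeon)
LINEAGE_TEMPLATES <- list(
  list(w = 100, ranks = c("d__Bacteria", "p__Bacteroidota", "c__Bacteroidia",
                          "o__Flavobacteriales", "f__Flavobacteriaceae")),
  list(w = 34, ranks = c("d__Bacteria", "p__Proteobacteria",
                         "c__Alphaproteobacteria", "o__Rhodobacterales",
                         "f__Rhodobacteraceae")),
  list(w = 20, ranks = c("d__Bacteria", "p__Proteobacteria",
                         "c__Gammaproteobacteria", "o__Granulosicoccales",
                         "f__Granulosicoccaceae")),
  list(w = 15, ranks = c("d__Bacteria", "p__Patescibacteria", "c__Paceibacteria",
                         "o__UBA9983", "f__UBA9983")),
  list(w = 12, ranks = c("d__Bacteria", "p__Actinobacteriota", "c__Acidimicrobiia",
                         "o__Acidimicrobiales", "f__Ilumatobacteraceae")),
  list(w = 6, ranks = c("d__Bacteria", "p__Chloroflexota", "c__Anaerolineae",
                        "o__Anaerolineales", "f__Anaerolineaceae")),
  list(w = 5, ranks = c("d__Bacteria", "p__Bdellovibrionota", "c__Bdellovibrionia",
                        "o__Bdellovibrionales", "f__Bdellovibrionaceae")),
  list(w = 5, ranks = c("d__Bacteria", "p__Verrucomicrobiota", "c__Verrucomicrobiae",
                        "o__Opitutales", "f__Puniceicoccaceae")),
  list(w = 4, ranks = c("d__Bacteria", "p__Myxococcota", "c__Myxococcia",
                        "o__Myxococcales", "f__Myxococcaceae")),
  list(w = 1, ranks = c("d__Archaea", "p__Crenarchaeota", "c__Nitrososphaeria",
                        "o__Nitrosopumilales", "f__Nitrosopumilaceae"))
)

simulate_taxonomy <- function(n) {
  w <- vapply(LINEAGE_TEMPLATES, function(t) t$w, 0)
  pick <- sample.int(length(LINEAGE_TEMPLATES), n, replace = TRUE, prob = w)
  vapply(seq_len(n), function(i) {
    tpl <- LINEAGE_TEMPLATES[[pick[i]]]
    genus <- sprintf("g__%s-G%02d", sub("^f__", "", tpl$ranks[5]),
                     sample.int(20, 1))
    species <- sprintf("s__%s sp%06d", sub("^g__", "", genus),
                       sample.int(999999, 1))
    paste(c(tpl$ranks, genus, species), collapse = ";")
  }, "")
}

default_background_pool <- function(catalog) {
  pool <- sprintf("K9%04d", seq_len(500))
  setdiff(pool, unique(unlist(lapply(catalog, module_identifiers))))
}

#' Simulate genomes with known trait ground truth
#'
#' Each genome belongs to one trait group and truly carries every
#' identifier of that group's modules. The observed KO set applies two
#' error processes:
#'
#' * dropout — each true identifier is retained independently with
#'   probability `completeness / 100`;
#' * contamination — `round(contamination / 100 * |true set|)` foreign
#'   identifiers are added, sampled without replacement from the
#'   background pool (which is disjoint from all trait blocks).
#'
#' @param config a [sim_config()].
#' @param catalog module catalog providing the trait blocks; must be
#'   non-empty.
#' @return list with `genomes` (data.frame: genome_id, taxonomy,
#'   completeness, contamination), `ko_sets` (named list of observed
#'   identifier sets) and `truth` (list with `modules` and `kos`, the true
#'   per-genome module ids and pre-dropout identifier sets).
#' @export
simulate_genomes <- function(config, catalog = builtin_catalog()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (length(catalog) == 0L)
    stop("catalog must be non-empty", call. = FALSE)
  validate_catalog(catalog)
  ta <- config$trait_assignment %||% default_trait_assignment(catalog)
  missing <- setdiff(unlist(ta), names(catalog))
  if (length(missing))
    stop(sprintf("trait modules absent from catalog: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  pool <- config$background_ko_pool %||% default_background_pool(catalog)
  n <- config$n_genomes
  withr::with_seed(derive_seeds(config$seed, 3)[1], {
    ids <- sprintf("MAG-%d", seq_len(n))
    group <- sample(names(ta), n, replace = TRUE)
    completeness <- runif(n, config$completeness_range[1],
                          config$completeness_range[2])
    contamination <- runif(n, config$contamination_range[1],
                           config$contamination_range[2])
    taxonomy <- simulate_taxonomy(n)
    true_modules <- lapply(group, function(g) ta[[g]])
    true_kos <- lapply(true_modules, function(mods)
      unique(unlist(lapply(catalog[mods], module_identifiers))))
    ko_sets <- vector("list", n)
    for (i in seq_len(n)) {
      kos <- true_kos[[i]]
      keep <- rbinom(length(kos), 1L, completeness[i] / 100) == 1L
      observed <- kos[keep]
      avail <- setdiff(pool, kos)
      n_add <- min(round(contamination[i] / 100 * length(kos)), length(avail))
      if (n_add > 0)
        observed <- c(observed, sample(avail, n_add))
      ko_sets[[i]] <- observed
    }
  })
  names(ko_sets) <- ids
  names(true_modules) <- ids
  names(true_kos) <- ids
  list(
    genomes = data.frame(genome_id = ids, taxonomy = taxonomy,
                         completeness = completeness,
                         contamination = contamination, group = group,
                         stringsAsFactors = FALSE),
    ko_sets = ko_sets,
    truth = list(modules = true_modules, kos = true_kos)
  )
}

#' Simulate a random rooted genome tree
#'
#' Random topology (via [ape::rtree()]) with exponential branch lengths;
#' all lengths strictly positive.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed RNG seed.
#' @param labels leaf labels (default `MAG-1..MAG-n`).
#' @param rate exponential rate for branch lengths.
#' @return a rooted binary `phylo`.
#' @export
simulate_tree <- function(n_leaves, seed = 1, labels = NULL, rate = 1) {
  check_number(n_leaves, "n_leaves", allow_vector = FALSE)
  if (n_leaves < 2) stop_field("n_leaves", "must be at least 2")
  n_leaves <- as.integer(n_leaves)
  labels <- labels %||% sprintf("MAG-%d", seq_len(n_leaves))
  if (length(labels) != n_leaves || anyDuplicated(labels))
    stop_field("labels", "must be unique and of length n_leaves")
  withr::with_seed(seed, {
    tree <- ape::rtree(n_leaves, rooted = TRUE,
                       br = function(k) rexp(k, rate))
  })
  tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

sample_names <- function(n_samples) {
  stopifnot(n_samples >= 1, n_samples <= 52)
  groups <- c("RZ", "ND")
  per <- c(ceiling(n_samples / 2), floor(n_samples / 2))
  unlist(lapply(seq_along(groups), function(i)
    if (per[i] > 0) paste0(groups[i], "-", LETTERS[seq_len(per[i])])))
}

#' Simulate per-sample genome coverages
#'
#' Independent lognormal coverage per genome and sample. With six samples
#' the columns follow the two-site naming `RZ-A, RZ-B, RZ-C, ND-A, ND-B,
#' ND-C`.
#'
#' @param genomes data.frame with `genome_id` (from [simulate_genomes()]).
#' @param n_samples number of samples.
#' @param config a [sim_config()] supplying `lognormal_mu`,
#'   `lognormal_sigma` and the seed.
#' @return numeric matrix (genomes x samples).
#' @export
simulate_coverage <- function(genomes, n_samples = 6, config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.data.frame(genomes) || nrow(genomes) == 0L)
    stop_field("genomes", "must be a non-empty data.frame")
  ids <- as.character(genomes$genome_id)
  cols <- sample_names(n_samples)
  withr::with_seed(derive_seeds(config$seed, 3)[3], {
    m <- matrix(rlnorm(length(ids) * n_samples, config$lognormal_mu,
                       config$lognormal_sigma),
                nrow = length(ids), ncol = n_samples,
                dimnames = list(ids, cols))
  })
  m
}

#' Simulate a full community: genomes, truth, tree and coverages
#'
#' Convenience wrapper running [simulate_genomes()], [simulate_tree()] and
#' [simulate_coverage()] on independent sub-streams of `config$seed`.
#'
#' @inheritParams simulate_genomes
#' @return list with `genomes`, `ko_sets`, `truth`, `tree`, `coverage`,
#'   `sample_groups`.
#' @export
simulate_community <- function(config = sim_config(), catalog = builtin_catalog()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  sim <- simulate_genomes(config, catalog)
  seeds <- derive_seeds(config$seed, 3)
  tree <- if (config$n_genomes >= 2)
    simulate_tree(config$n_genomes, seed = seeds[2],
                  labels = sim$genomes$genome_id, rate = config$branch_rate)
  else NULL
  coverage <- simulate_coverage(sim$genomes, config$n_samples, config)
  c(sim, list(tree = tree, coverage = coverage,
              sample_groups = sample_groups_from_names(colnames(coverage))))
}

#' Write a simulated community to disk
#'
#' Emits the pipeline's file interfaces: `genomes.tsv`, `annotations.tsv`
#' (one genome_id/ko_id pair per row), `tree.nwk`, `coverage.tsv`,
#' `sample_groups.tsv` and `truth.json`.
#'
#' @param sim result of [simulate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(sim$genomes, "genomes.tsv")
  ann <- data.frame(
    genome_id = rep(names(sim$ko_sets), lengths(sim$ko_sets)),
    ko_id = unlist(sim$ko_sets, use.names = FALSE))
  tsv(ann, "annotations.tsv")
  if (!is.null(sim$tree))
    ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  cov <- data.frame(genome_id = rownames(sim$coverage), sim$coverage,
                    check.names = FALSE, row.names = NULL)
  tsv(cov, "coverage.tsv")
  tsv(data.frame(sample = names(sim$sample_groups),
                 group = unname(sim$sample_groups)), "sample_groups.tsv")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
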