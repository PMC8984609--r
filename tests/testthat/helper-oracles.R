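# Independent brute-force oracles used to cross-check the implementation.

# Faith's rooted PD by explicit union of root-to-leaf edge paths.
brute_pd <- function(tree, taxa) {
  root <- ape::Ntip(tree) + 1L
  edges <- character()
  for (t in taxa) {
    path <- ape::nodepath(tree, from = root, to = match(t, tree$tip.label))
    edges <- union(edges, paste(path[-length(path)], path[-1]))
  }
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[key %in% edges])
}

# Module completeness as the maximum, over all per-step alternative picks,
# of the fraction of picked complexes fully present. Enumerates the full
# cartesian product of alternatives, so only usable on small modules.
brute_completeness <- function(definition, ko_set) {
  picks <- expand.grid(lapply(definition$steps, seq_along))
  best <- 0
  for (r in seq_len(nrow(picks))) {
    ok <- vapply(seq_along(definition$steps), function(s) {
      all(definition$steps[[s]][[picks[r, s]]] %in% ko_set)
    }, NA)
    best <- max(best, mean(ok))
  }
  best
}

brute_keys <- function(definition, ko_set) {
  for (clause in definition$keys) {
    hit <- FALSE
    for (alt in clause) if (all(alt %in% ko_set)) hit <- TRUE
    if (!hit) return(FALSE)
  }
  TRUE
}

# Random small module over a compact identifier alphabet.
random_module <- function(id = "RND", alphabet = sprintf("K%05d", 1:12)) {
  n_steps <- sample(1:4, 1)
  steps <- lapply(seq_len(n_steps), function(i) {
    n_alt <- sample(1:3, 1)
    lapply(seq_len(n_alt), function(j) sample(alphabet, sample(1:2, 1)))
  })
  key_step <- steps[[sample(n_steps, 1)]]
  module_definition(id, "random module", "nitrogen", steps,
                    keys = if (runif(1) < 0.7) list(key_step) else list())
}

random_catalog <- function(n = 4) {
  mods <- lapply(seq_len(n), function(i)
    random_module(sprintf("RND_%02d", i)))
  cat <- structure(mods, class = "module_catalog")
  names(cat) <- vapply(mods, function(m) m$module_id, "")
  cat
}

# Monte-Carlo expected richness of a subsample of size n.
mc_richness <- function(counts, n, ndraws = 1e4) {
  units <- rep(seq_along(counts), counts)
  draws <- vapply(seq_len(ndraws), function(i)
    length(unique(sample(units, n))), 0L)
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(ndraws))
}
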