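test_that("a fixed seed fixes every artifact bit-for-bit", {
  s1 <- simulate_community(sim_config(n_genomes = 25, seed = 7))
  s2 <- simulate_community(sim_config(n_genomes = 25, seed = 7))
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$ko_sets, s2$ko_sets)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$coverage, s2$coverage)
  # sub-streams are split per artifact: more samples, same genomes and tree
  s3 <- simulate_community(sim_config(n_genomes = 25, seed = 7, n_samples = 2))
  expect_identical(s1$ko_sets, s3$ko_sets)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s3$tree))
})

test_that("dropout and contamination act as specified at the extremes", {
  full <- simulate_genomes(sim_config(n_genomes = 30, seed = 3,
                                      completeness_range = c(100, 100),
                                      contamination_range = c(0, 0)))
  for (g in names(full$ko_sets))
    expect_setequal(full$ko_sets[[g]], full$truth$kos[[g]])
  # completeness 0: nothing from the trait block survives
  none <- simulate_genomes(sim_config(n_genomes = 10, seed = 3,
                                      completeness_range = c(0, 0),
                                      contamination_range = c(0, 0)))
  expect_true(all(lengths(none$ko_sets) == 0))
})

test_that("contamination-free genomes carry no background identifiers", {
  sim <- simulate_genomes(sim_config(n_genomes = 40, seed = 9,
                                     contamination_range = c(0, 0)))
  for (g in names(sim$ko_sets))
    expect_true(all(sim$ko_sets[[g]] %in% sim$truth$kos[[g]]))
})

test_that("expected retained fraction equals completeness/100", {
  # many genomes at one completeness level: pooled retention is binomial
  p <- 0.7
  sim <- simulate_genomes(sim_config(n_genomes = 300, seed = 13,
                                     completeness_range = 100 * c(p, p),
                                     contamination_range = c(0, 0)))
  n_true <- sum(lengths(sim$truth$kos))
  n_kept <- sum(lengths(sim$ko_sets))
  se <- sqrt(p * (1 - p) / n_true)
  expect_lt(abs(n_kept / n_true - p), 3 * se)
})

test_that("contamination adds the rounded proportional number of foreign KOs", {
  sim <- simulate_genomes(sim_config(n_genomes = 30, seed = 21,
                                     completeness_range = c(100, 100),
                                     contamination_range = c(8, 8)))
  for (g in names(sim$ko_sets)) {
    truth <- sim$truth$kos[[g]]
    foreign <- setdiff(sim$ko_sets[[g]], truth)
    expect_equal(length(foreign), round(0.08 * length(truth)))
  }
})

test_that("taxonomy strings are 7-rank GTDB style", {
  sim <- simulate_genomes(sim_config(n_genomes = 20, seed = 2))
  parts <- strsplit(sim$genomes$taxonomy, ";")
  expect_true(all(lengths(parts) == 7))
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  for (p in parts)
    expect_true(all(mapply(startsWith, p, prefixes)))
  expect_silent(parse_taxonomy(sim$genomes$taxonomy, "family"))
})

test_that("simulated trees are rooted, binary, positive-length and labelled", {
  expect_error(simulate_tree(1), "at least 2")
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(t2$Nnode, 1)
  big <- simulate_tree(421, seed = 5)
  expect_equal(ape::Ntip(big), 421)
  expect_false(anyDuplicated(big$tip.label) > 0)
  expect_true(all(big$edge.length > 0))
  expect_true(ape::is.rooted(big) && ape::is.binary(big))
  expect_identical(ape::write.tree(simulate_tree(8, seed = 4)),
                   ape::write.tree(simulate_tree(8, seed = 4)))
})

test_that("coverage tables have the two-site shape and lognormal behaviour", {
  g <- data.frame(genome_id = paste0("MAG-", 1:5))
  cov <- simulate_coverage(g, 6, sim_config(seed = 1))
  expect_identical(colnames(cov),
                   c("RZ-A", "RZ-B", "RZ-C", "ND-A", "ND-B", "ND-C"))
  expect_identical(rownames(cov), g$genome_id)
  expect_true(all(cov > 0))
  # sigma = 0 collapses every coverage onto exp(mu)
  flat <- simulate_coverage(g, 3, sim_config(seed = 1, lognormal_mu = 1,
                                             lognormal_sigma = 0))
  expect_equal(unname(flat), matrix(exp(1), 5, 3))
  expect_identical(cov, simulate_coverage(g, 6, sim_config(seed = 1)))
})

test_that("written simulations read back consistently", {
  dir <- withr::local_tempdir()
  sim <- simulate_community(sim_config(n_genomes = 12, seed = 6))
  write_simulation(sim, dir)
  g <- read_genomes(file.path(dir, "genomes.tsv"))
  expect_equal(g$genome_id, sim$genomes$genome_id)
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  sets <- ko_sets_from_annotations(ann, g$genome_id)
  for (id in g$genome_id)
    expect_setequal(sets[[id]], sim$ko_sets[[id]])
  cov <- read_coverage(file.path(dir, "coverage.tsv"))
  expect_equal(cov, sim$coverage, tolerance = 1e-6)
  tr <- read_genome_tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, g$genome_id)
})

test_that("configuration is validated", {
  expect_error(sim_config(n_genomes = 0), "n_genomes")
  expect_error(sim_config(completeness_range = c(80, 120)), "completeness_range")
  expect_error(sim_config(completeness_range = c(90, 50)), "completeness_range")
  expect_error(simulate_genomes(sim_config(n_genomes = 2),
                                catalog = parse_catalog("")),
               "non-empty")
})
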