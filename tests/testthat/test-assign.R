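cat <- builtin_catalog()

test_that("step satisfaction requires one full alternative", {
  expect_true(step_satisfied("K00001,K00002", "K00002"))
  expect_false(step_satisfied("K00003+K00004", "K00003"))
  expect_true(step_satisfied("K00003+K00004", c("K00003", "K00004")))
})

test_that("module completeness counts satisfied steps", {
  m <- module_definition("T", "t", "nitrogen", c("K00001", "K00002"))
  expect_equal(module_completeness(m, "K00001"), 0.5)
  expect_equal(module_completeness(m, character()), 0)
  expect_equal(module_completeness(m, c("K00001", "K00002")), 1)
  # optional raw KO-fraction mode
  m2 <- module_definition("T2", "t", "nitrogen", "K00001+K00002,K00003")
  expect_equal(module_completeness(m2, "K00003", method = "ko_fraction"), 1 / 3)
  expect_equal(module_completeness(m2, "K00003"), 1)
})

test_that("key gating follows clause-of-alternatives semantics", {
  # nitrate reductase clause satisfied by the napAB alternative alone
  expect_true(keys_present(cat$CUST_DNRA, c("napA", "napB")))
  expect_false(keys_present(cat$CUST_DNRA, c("napA", "narG", "narH")))
  # rTCA-style: > 60% of steps without the aclAB key is not enough
  rtca_ids <- setdiff(module_identifiers(cat$M00173), c("K15230", "K15231"))
  expect_gt(module_completeness(cat$M00173, rtca_ids), 0.6)
  expect_false(keys_present(cat$M00173, rtca_ids))
  expect_false(assign_module(cat$M00173, rtca_ids)$assigned)
  # vacuous truth without key clauses
  m <- module_definition("T", "t", "sulfur", "K00001")
  expect_true(keys_present(m, character()))
})

test_that("assignment threshold is inclusive at exactly 60%", {
  five <- module_definition("T", "t", "nitrogen",
                            sprintf("K1000%d", 1:5))
  expect_true(assign_module(five, sprintf("K1000%d", 1:3))$assigned)  # 3/5
  expect_false(assign_module(five, sprintf("K1000%d", 1:2))$assigned) # 2/5
  ten <- module_definition("T", "t", "nitrogen", sprintf("K2000%d", 0:9))
  expect_false(assign_module(ten, sprintf("K2000%d", 0:4))$assigned)  # 0.5
  expect_true(assign_module(ten, sprintf("K2000%d", 0:6), threshold = 0.7)$assigned)
  expect_error(assign_module(ten, character(), threshold = 0), "threshold")
})

test_that("completeness and keys agree with the brute-force enumerator", {
  withr::with_seed(7, {
    for (i in 1:200) {
      m <- random_module()
      kos <- sample(sprintf("K%05d", 1:12), sample(0:8, 1))
      expect_equal(module_completeness(m, kos), brute_completeness(m, kos))
      expect_identical(keys_present(m, kos), brute_keys(m, kos))
    }
  })
})

test_that("completeness and assignment are monotone under KO supersets", {
  withr::with_seed(8, {
    for (i in 1:200) {
      m <- random_module()
      univ <- sprintf("K%05d", 1:12)
      a <- sample(univ, sample(0:6, 1))
      b <- union(a, sample(univ, sample(0:6, 1)))
      ca <- assign_module(m, a)
      cb <- assign_module(m, b)
      expect_lte(ca$completeness, cb$completeness)
      if (ca$assigned) expect_true(cb$assigned)
    }
  })
})

test_that("build_matrix covers every genome-module cell and catches duplicates", {
  empty <- build_matrix(data.frame(genome_id = character()), list(), cat)
  expect_equal(nrow(empty), 0)
  g <- data.frame(genome_id = c("a", "b"))
  m <- build_matrix(g, list(a = module_identifiers(cat$CUST_ANRA)), cat)
  expect_equal(nrow(m), 2 * length(cat))
  expect_true(m$assigned[m$genome_id == "a" & m$module_id == "CUST_ANRA"])
  expect_false(any(m$assigned[m$genome_id == "b"]))
  dup <- data.frame(genome_id = c("a", "a"))
  expect_error(build_matrix(dup, list(), cat), "unique")
})

test_that("a btuB-only genome gets the transport module but no synthesis route", {
  g <- data.frame(genome_id = "MAG-x")
  m <- build_matrix(g, list(`MAG-x` = "btuB"), cat)
  row <- function(id) m[m$module_id == id, ]
  expect_true(row("CUST_B12_TRANSPORT")$assigned)
  expect_false(row("CUST_B12_AEROBIC")$assigned)
  expect_false(row("CUST_B12_ANAEROBIC")$assigned)
  expect_lt(row("CUST_B12_AEROBIC")$completeness, 0.6)
})

test_that("taxon aggregation counts assigned genomes per rank", {
  g <- data.frame(
    genome_id = c("a", "b", "c"),
    taxonomy = c(
      "d__Bacteria;p__Proteobacteria;c__Alpha;o__O;f__F;g__G;s__S",
      "d__Bacteria;p__Proteobacteria;c__Alpha;o__O;f__F;g__G;s__S2",
      "d__Bacteria;p__Bacteroidota;c__B;o__O;f__F;g__G;s__S3"))
  ko <- module_identifiers(cat$CUST_ANRA)
  m <- build_matrix(g, list(a = ko, c = ko), cat)
  agg <- aggregate_by_taxon(m, g, rank = "phylum")
  anra <- agg[agg$module_id == "CUST_ANRA", ]
  expect_equal(anra$n_assigned[anra$taxon == "Proteobacteria"], 1L)
  expect_equal(anra$n_genomes[anra$taxon == "Proteobacteria"], 2L)
  expect_equal(anra$n_assigned[anra$taxon == "Bacteroidota"], 1L)
  expect_true(all(agg$n_assigned <= agg$n_genomes))
  # empty matrix -> empty summary
  expect_equal(nrow(aggregate_by_taxon(m[0, ], g)), 0)
})

test_that("malformed taxonomy is grouped as unclassified with a warning", {
  expect_warning(tx <- parse_taxonomy(c("not a lineage", "d__Bacteria"),
                                      "phylum"), "unclassified")
  expect_identical(tx, c("unclassified", "unclassified"))
  ok <- parse_taxonomy("d__Bacteria;p__Bacteroidota;c__;o__;f__;g__;s__",
                       "phylum")
  expect_identical(ok, "Bacteroidota")
  expect_identical(
    parse_taxonomy("d__Bacteria;p__Bacteroidota;c__;o__;f__;g__;s__", "class"),
    "unclassified")
})
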