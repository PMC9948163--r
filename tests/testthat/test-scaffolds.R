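test_that("Murcko scaffolds prune side chains and keep ring-linker frameworks", {
  s <- murckoScaffold(c("Cc1ccccc1", "CCCCCC", "C(c1ccccc1)c1ccccc1"))
  expect_equal(s[1], canonicalSmiles("c1ccccc1"))   # toluene -> benzene
  expect_equal(s[2], "")                            # acyclic -> empty
  expect_equal(s[3], canonicalSmiles("C(c1ccccc1)c1ccccc1"))  # all kept
  expect_true(is.na(murckoScaffold("zzz")))
})

test_that("exocyclic double-bonded atoms stay on the scaffold", {
  # cyclohexanone keeps its carbonyl oxygen, loses nothing else
  s <- murckoScaffold("O=C1CCCCC1")
  expect_equal(s, canonicalSmiles("O=C1CCCCC1"))
  # acetophenone: ketone branch is side chain except nothing double-bonded
  # to the ring itself
  expect_equal(murckoScaffold("CC(=O)c1ccccc1"), canonicalSmiles("c1ccccc1"))
})

test_that("cyclic skeletons erase elements and bond orders", {
  expect_equal(cyclicSkeleton(canonicalSmiles("c1ccccc1")),
               canonicalSmiles("C1CCCCC1"))
  expect_equal(cyclicSkeleton(canonicalSmiles("c1ccncc1")),
               canonicalSmiles("C1CCCCC1"))  # pyridine == benzene skeleton
  expect_equal(cyclicSkeleton(canonicalSmiles("c1ccc2ncccc2c1")),
               canonicalSmiles("C1CCC2CCCCC2C1"))  # quinoline -> decalin
  expect_error(cyclicSkeleton(""), "empty")
})

test_that("scaffold and skeleton extraction are idempotent", {
  mols <- c("Cc1ccc(F)cc1", "O=C1NC(=O)CN1", "c1ccc2[nH]ccc2c1",
            "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
            "c1ccc(COc2ccccc2)cc1")
  s <- murckoScaffold(mols)
  expect_equal(murckoScaffold(s), s)
  k <- cyclicSkeleton(s)
  expect_equal(cyclicSkeleton(k), k)
})

test_that("the scaffold table groups, counts and sorts correctly", {
  cur <- makeCurated(paste0("m", 1:4),
                     c("Cc1ccccc1", "CCc1ccccc1", "c1ccccc1",
                       "c1ccc2ncccc2c1"),
                     c(8.5, 7.5, 6.5, 5.0))
  st <- buildScaffoldTable(cur)
  tab <- scaffolds(st)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$frequency, c(3L, 1L))
  expect_equal(tab$scaffold_smiles[1], canonicalSmiles("c1ccccc1"))
  expect_setequal(scaffoldMembers(st)[[tab$scaffold_smiles[1]]],
                  c("m1", "m2", "m3"))
  expect_equal(sum(tab$frequency), 4L)
})

test_that("an all-acyclic set collapses into one flagged record", {
  cur <- makeCurated(c("a", "b"), c("CCCC", "CCO"), c(8.5, 5))
  tab <- scaffolds(buildScaffoldTable(cur))
  expect_equal(nrow(tab), 1)
  expect_true(tab$acyclic)
  expect_equal(tab$scaffold_smiles, "")
  expect_true(is.na(tab$csk_smiles))
})

test_that("diversity ratios reproduce direct arithmetic", {
  r <- diversityRatios(4, 2, 1, 2)
  expect_equal(unname(r), c(0.5, 0.25, 0.5, 1))
})

test_that("diversity metrics respect counting inequalities on synthetic sets", {
  for (seed in c(3L, 13L)) {
    ds <- generateDataset(tinyConfig(seed = seed))
    cur <- curateBioactivities(ds$table)
    dm <- diversityMetrics(cur, by_class = FALSE)
    expect_true(dm$ncsk <= dm$ns)
    expect_true(dm$ns <= dm$n)
    expect_true(dm$nss <= dm$ns)
    expect_true(all(dm[, c("ns_n", "nss_n", "ncsk_n", "ncsk_ns")] <= 1))
  }
})

test_that("per-class diversity rows use independently computed class sets", {
  cur <- tinyCurated()
  # the tiny two-family set leaves some classes empty; those are omitted
  dm <- suppressWarnings(diversityMetrics(cur, by_class = TRUE))
  expect_equal(dm$set[1], "complete")
  expect_equal(sum(dm$n[-1]), dm$n[1])
  # class scaffold counts can overlap, so they may sum above the complete row
  expect_gte(sum(dm$ns[-1]), dm$ns[1])
})

test_that("enrichment factor matches hand arithmetic and its invariants", {
  ds_cls <- factor(rep(c("potent", "inactive"), c(4, 6)),
                   levels = ACTIVITY_LEVELS)
  expect_equal(enrichmentFactor(rep("potent", 3), ds_cls), 2.5)
  expect_equal(enrichmentFactor(rep("inactive", 2), ds_cls), 0)
  # member mix equal to the dataset mix -> EF 1
  expect_equal(enrichmentFactor(
    rep(c("potent", "inactive"), c(2, 3)), ds_cls), 1)
  expect_error(enrichmentFactor("potent",
                                rep("inactive", 5)), "no potent/active")
})

test_that("frequency-weighted EF averages to one over any scaffold table", {
  cur <- tinyCurated()
  st <- buildScaffoldTable(cur)
  tab <- scaffolds(st)
  expect_equal(sum(tab$frequency * tab$ef) / st@n, 1, tolerance = 1e-9)
})

test_that("R-group decomposition reports substituents per canonical position", {
  d <- rgroupDecompose("Cc1ccccc1", "c1ccccc1")
  expect_equal(length(d), 6)
  expect_equal(sort(table(d), decreasing = TRUE),
               sort(table(c(rep("[H]", 5), "C")), decreasing = TRUE),
               ignore_attr = TRUE)
  # identity decomposition: all positions hydrogen
  d0 <- rgroupDecompose("c1ccccc1", "c1ccccc1")
  expect_true(all(d0 == "[H]"))
  expect_error(rgroupDecompose("CCO", "c1ccccc1"), "not a substructure")
})

test_that("the R-group table aligns substituents with activity data", {
  cur <- makeCurated(c("a", "b", "c"),
                     c("Cc1ccccc1", "CCc1ccccc1", "Fc1ccccc1"),
                     c(8.5, 7.2, 5.1))
  tab <- rgroupTable(cur, "c1ccccc1")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$pic50, c(8.5, 7.2, 5.1))
  # each row has exactly one non-hydrogen substituent
  rcols <- grep("^R", names(tab))
  nonH <- apply(tab[, rcols], 1, function(r) sum(r != "[H]"))
  expect_equal(unname(nonH), c(1, 1, 1))
})
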