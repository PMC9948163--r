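test_that("fingerprints are deterministic with the documented widths", {
  s <- c(a = "Cc1ccccc1", b = "c1ccccc1", c = "CCO")
  for (kind in c("ecfp4", "maccs", "pubchem")) {
    f1 <- moleculeFingerprints(s, kind)
    f2 <- moleculeFingerprints(s, kind)
    expect_identical(f1, f2)
    expect_equal(ncol(f1), unname(c(ecfp4 = 2048, maccs = 166,
                                    pubchem = 881)[kind]))
    expect_true(all(f1 %in% c(0L, 1L)))
  }
})

test_that("related molecules share some but not all circular features", {
  f <- moleculeFingerprints(c(bz = "c1ccccc1", tol = "Cc1ccccc1"), "ecfp4")
  s <- tanimoto(f["bz", ], f["tol", ])
  expect_gt(s, 0)
  expect_lt(s, 1)
})

test_that("methane has a near-empty MACCS key set but a nonempty pubchem vector", {
  fm <- moleculeFingerprints(c(m = "C"), "maccs")
  expect_lte(sum(fm), 3)
  fp <- moleculeFingerprints(c(m = "C"), "pubchem")
  expect_gte(sum(fp), 1)  # the any-heavy-atom key
})

test_that("tanimoto matches its set definition", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  z <- tanimoto(c(0, 0), c(0, 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("SALI follows its ratio definition with the degenerate sim = 1 case", {
  expect_equal(sali(3, 0.95), 60)
  expect_equal(sali(2, 0), 2)
  expect_true(is.na(sali(2.5, 1)))
  # strictly increasing in activity difference at fixed similarity
  expect_true(all(diff(sali(seq(0.1, 3, by = 0.1), 0.5)) > 0))
  # strictly increasing in similarity at fixed positive difference
  expect_true(all(diff(sali(2, seq(0, 0.99, by = 0.01))) > 0))
})

test_that("the SAS map enumerates every unordered pair with strict thresholds", {
  cur <- makeCurated(paste0("m", 1:5),
                     c("Cc1ccccc1", "CCc1ccccc1", "Fc1ccccc1",
                       "c1ccc2ncccc2c1", "O=C1NC(=O)CN1"),
                     c(9, 6.8, 6.5, 5.2, 8.1))
  sm <- sasMap(cur, "ecfp4")
  p <- landscapePairs(sm)
  expect_equal(nrow(p), choose(5, 2))
  expect_true(all(p$activity_diff >= 0))
  # brute-force double-loop oracle
  m <- molecules(cur)
  fp <- moleculeFingerprints(m$smiles, "ecfp4", ids = m$molecule_id)
  for (r in seq_len(nrow(p))) {
    a <- p$id_a[r]; b <- p$id_b[r]
    sim <- tanimoto(fp[a, ], fp[b, ])
    diffv <- abs(m$pic50[m$molecule_id == a] - m$pic50[m$molecule_id == b])
    expect_equal(p$sim[r], as.numeric(sim))
    expect_equal(p$activity_diff[r], diffv)
    quad <- if (sim > 0.9) {
      if (diffv > 2) "cliff" else "smooth"
    } else {
      if (diffv > 2) "nondescript" else "scaffold_hop"
    }
    expect_equal(p$quadrant[r], quad)
  }
})

test_that("quadrant boundaries are strict inequalities", {
  cur <- makeCurated(c("a", "b"), c("CCO", "CCO"), c(8, 6))
  sm <- sasMap(cur, "ecfp4", sim_threshold = 0.9, act_threshold = 2)
  p <- landscapePairs(sm)
  # identical structures: sim = 1 > 0.9 but diff = 2 is not > 2 -> smooth
  expect_equal(p$quadrant, "smooth")
  expect_true(p$duplicate_structure)
  expect_true(is.na(p$sali))
})

test_that("identical-structure pairs with large activity gaps count as cliffs", {
  cur <- makeCurated(c("a", "b"), c("CCO", "CCO"), c(8.5, 6))
  p <- landscapePairs(sasMap(cur, "ecfp4"))
  expect_equal(p$quadrant, "cliff")
  expect_true(is.na(p$sali))
})

test_that("the pair set is invariant to molecule input order", {
  cur <- tinyCurated()
  m <- molecules(cur)
  perm <- rev(seq_len(nrow(m)))
  cur2 <- new("CuratedSet", molecules = m[perm, ], log = list())
  p1 <- landscapePairs(sasMap(cur, "maccs"))
  p2 <- landscapePairs(sasMap(cur2, "maccs"))
  expect_same_pairs(p1, p2)
  k1 <- pairKeys(p1$id_a, p1$id_b)
  k2 <- pairKeys(p2$id_a, p2$id_b)
  expect_equal(p1$sim[order(k1)], p2$sim[order(k2)])
})

test_that("consensus cliffs are the intersection of the per-kind sets", {
  s1 <- data.frame(id_a = c("A", "C"), id_b = c("B", "D"))
  s2 <- data.frame(id_a = "A", id_b = "B")
  expect_equal(consensusACs(list(x = s1, y = s2)),
               data.frame(id_a = "A", id_b = "B"))
  expect_equal(nrow(consensusACs(list(x = s1, y = s1))), 2)
  s3 <- data.frame(id_a = "E", id_b = "F")
  expect_equal(nrow(consensusACs(list(x = s1, y = s3))), 0)
  # order of ids within a pair does not matter
  s4 <- data.frame(id_a = "B", id_b = "A")
  expect_equal(nrow(consensusACs(list(x = s2, y = s4))), 1)
})

test_that("cliff generators are counted, filtered and ranked deterministically", {
  acs <- data.frame(id_a = c("A", "A", "A", "C"),
                    id_b = c("B", "C", "D", "D"))
  g <- acGenerators(acs, min_count = 2)
  expect_equal(g$molecule_id, c("A", "C", "D"))
  expect_equal(g$ac_count, c(3L, 2L, 2L))
  expect_equal(g$rank, c(1L, 2L, 2L))
  expect_equal(nrow(acGenerators(acs[0, ], 1)), 0)
  expect_equal(nrow(acGenerators(data.frame(id_a = c("A", "C"),
                                            id_b = c("B", "D")), 2)), 0)
})
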