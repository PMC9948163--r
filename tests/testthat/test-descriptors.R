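test_that("property vectors match hand-checked reference molecules", {
  p <- computeProperties(c(benzene = "c1ccccc1", ethanol = "CCO",
                           butane = "CCCC", toluene = "Cc1ccccc1"))
  expect_equal(p["benzene", "nhd"], 0L)
  expect_equal(p["benzene", "nrot"], 0L)
  expect_equal(p["benzene", "tpsa"], 0)
  expect_equal(p["ethanol", "nhd"], 1L)
  expect_equal(p["ethanol", "nha"], 1L)
  expect_equal(p["ethanol", "tpsa"], 20.23)
  expect_equal(p["butane", "nrot"], 1L)   # one internal C-C bond
  expect_equal(p["toluene", "nrot"], 0L)  # terminal methyl does not rotate
  expect_equal(p["benzene", "mw"], 78.11, tolerance = 1e-3)
  expect_true(is.na(computeProperties("junk_smiles")$mw))
})

test_that("rotatable bonds exclude rings and triple-bond termini", {
  p <- computeProperties(c(cyclohexane = "C1CCCCC1",
                           benzonitrile = "N#Cc1ccccc1",
                           diphenyl = "c1ccc(-c2ccccc2)cc1"))
  expect_equal(p["cyclohexane", "nrot"], 0L)
  expect_equal(p["benzonitrile", "nrot"], 0L)
  expect_equal(p["diphenyl", "nrot"], 1L)
})

test_that("Mann-Whitney exact enumeration matches hand results and an independent oracle", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)  # the two extreme tables of C(6,3)=20
  expect_equal(r$method, "exact")
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # oracle: U by direct pairwise counting, p from wilcox.test's independent
  # exact implementation (tie-free samples)
  set.seed(11)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- sample(seq_len(100), n1)
    y <- sample(setdiff(seq_len(100), x), n2)
    mine <- mannWhitneyU(x, y)
    u_oracle <- sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
    expect_equal(mine$u, u_oracle)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles ties in exact mode via rank enumeration", {
  x <- c(1, 2, 2); y <- c(2, 3, 4)
  mine <- mannWhitneyU(x, y)
  # enumeration oracle over all assignments of the tied ranks
  r <- rank(c(x, y))
  picks <- combn(6, 3)
  us <- apply(picks, 2, function(ix) sum(r[ix])) - 6
  obs <- sum(r[1:3]) - 6
  p_oracle <- mean(abs(us - 4.5) >= abs(obs - 4.5) - 1e-12)
  expect_equal(mine$p, p_oracle)
})

test_that("large-sample path agrees with the tie-corrected normal reference", {
  set.seed(21)
  x <- round(rnorm(40, 0, 2), 1)
  y <- round(rnorm(35, 0.8, 2), 1)
  mine <- mannWhitneyU(x, y)
  expect_equal(mine$method, "normal")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("group summaries: identical groups give p = 1, constants give NaN moments", {
  cur <- makeCurated(paste0("m", 1:8), rep("CCO", 8),
                     c(8.5, 8.2, 7.4, 7.2, 6.5, 6.1, 5.5, 5.2))
  props <- data.frame(mw = rep(c(1, 2, 3, 4), 2),
                      logp = rep(c(1, 2, 3, 4), 2),
                      nha = rep(c(1, 2, 3, 4), 2),
                      nhd = rep(c(1, 2, 3, 4), 2),
                      nrot = rep(c(1, 2, 3, 4), 2),
                      tpsa = rep(5, 8))  # constant
  gs <- summarizeGroups(cur, properties = props)
  expect_true(all(gs$u_pvalue[c("mw", "logp", "nha", "nhd", "nrot")] == 1))
  sk <- gs$stats[gs$stats$property == "tpsa", ]
  expect_true(all(is.nan(sk$skew)))
  expect_true(all(sk$min <= sk$median & sk$median <= sk$max))
})

test_that("group summaries are invariant to molecule order", {
  cur <- tinyCurated()
  m <- molecules(cur)
  props <- computeProperties(m$smiles, ids = m$molecule_id)
  g1 <- summarizeGroups(cur, properties = props)
  perm <- sample(nrow(m))
  cur2 <- new("CuratedSet", molecules = m[perm, ], log = list())
  g2 <- summarizeGroups(cur2, properties = props[perm, ])
  expect_equal(g1$u_pvalue, g2$u_pvalue)
  expect_equal(g1$stats[order(g1$stats$property, g1$stats$group), ],
               g2$stats[order(g2$stats$property, g2$stats$group), ],
               ignore_attr = TRUE)
})

test_that("an empty group is rejected by name", {
  cur <- makeCurated(paste0("m", 1:4), rep("CCO", 4), c(8.5, 8.2, 8.4, 9))
  expect_error(summarizeGroups(cur, properties = data.frame(
    mw = 1:4, logp = 1:4, nha = 1:4, nhd = 1:4, nrot = 1:4, tpsa = 1:4)),
    "group2")
})

test_that("PCA loadings are orthonormal and variance percentages sum to 100", {
  set.seed(5)
  x <- matrix(rnorm(100 * 6), 100)
  colnames(x) <- c("mw", "logp", "nha", "nhd", "nrot", "tpsa")
  r <- runPropertyPCA(x)
  expect_lt(max(abs(crossprod(r$loadings) - diag(6))), 1e-8)
  expect_equal(sum(r$explained_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(r$cumulative_variance) >= 0))
  expect_lte(r$cumulative_variance[6], 100 + 1e-9)
  # sign convention: largest-magnitude loading of each column positive
  for (j in 1:6)
    expect_gt(r$loadings[which.max(abs(r$loadings[, j])), j], 0)
})

test_that("a duplicated column collapses the variance onto PC1", {
  set.seed(6)
  v <- rnorm(50)
  x <- cbind(a = v, b = v)
  r <- runPropertyPCA(x)
  expect_equal(r$cumulative_variance[1], 100, tolerance = 1e-9)
})

test_that("explained variances match an independent eigendecomposition", {
  set.seed(9)
  sigma <- crossprod(matrix(rnorm(36), 6))
  x <- matrix(rnorm(500 * 6), 500) %*% chol(sigma)
  colnames(x) <- paste0("p", 1:6)
  r <- runPropertyPCA(x)
  ev <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(r$explained_variance, 100 * ev / sum(ev), tolerance = 1e-8)
})

test_that("constant property columns are rejected with advice", {
  x <- cbind(a = rnorm(10), b = rep(3, 10))
  expect_error(runPropertyPCA(x), "constant")
})
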