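# Physicochemical descriptors, group-wise exploratory statistics with
# Mann-Whitney U tests, and the PCA chemical-space projection.

.PROPERTY_NAMES <- c("mw", "logp", "nha", "nhd", "nrot", "tpsa")

# Rotatable bonds: single, non-ring bonds between two non-terminal heavy
# atoms, excluding bonds to atoms involved in a triple bond (so nitrile and
# alkyne termini do not count). n-Butane has exactly one.
.countRotors <- function(mg) {
  b <- mg$bonds
  if (nrow(b) == 0) return(0L)
  deg <- tabulate(c(b$a1, b$a2), nbins = mg$n)
  triple <- unique(c(b$a1[b$order == 3], b$a2[b$order == 3]))
  bridges <- igraph::bridges(mg$graph)
  inring <- rep(TRUE, nrow(b))
  inring[as.integer(bridges)] <- FALSE
  rot <- b$order == 1 & !inring &
    deg[b$a1] > 1 & deg[b$a2] > 1 &
    !(b$a1 %in% triple) & !(b$a2 %in% triple)
  sum(rot)
}

#' Physicochemical property vectors
#'
#' Computes the six standard medicinal-chemistry properties per molecule:
#' molecular weight (`mw`, Da), Crippen-type octanol-water partition
#' estimate (`logp`), hydrogen-bond acceptor and donor counts (`nha`,
#' `nhd`), rotatable-bond count (`nrot`) and topological polar surface area
#' (`tpsa`, A^2). MW, log P, acceptors, donors and TPSA come from the
#' OpenBabel descriptor models; rotatable bonds are counted on the
#' molecular graph (single non-ring bonds between non-terminal heavy atoms,
#' triple-bond termini excluded).
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional row identifiers.
#' @return `data.frame` with columns [.PROPERTY_NAMES]; `NA` rows for
#'   molecules that fail to parse.
#' @examples
#' computeProperties(c(benzene = "c1ccccc1", ethanol = "CCO"))
#' @export
computeProperties <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    paste0("mol", seq_along(smiles))
  n <- length(smiles)
  out <- data.frame(mw = rep(NA_real_, n), logp = NA_real_,
                    nha = NA_integer_, nhd = NA_integer_,
                    nrot = NA_integer_, tpsa = NA_real_,
                    row.names = ids)
  tags <- paste0("q", seq_along(smiles))
  usable <- !is.na(smiles) & nzchar(smiles)
  lines <- .obabel(paste(smiles[usable], tags[usable]), "smi", "smi",
                   args = c("--append", shQuote("MW logP TPSA HBA1 HBD")))
  if (length(lines)) {
    parts <- strsplit(trimws(lines), "[ \t]+")
    for (p in parts) {
      if (length(p) == 7 && p[2] %in% tags) {
        i <- match(p[2], tags)
        out$mw[i] <- as.numeric(p[3])
        out$logp[i] <- as.numeric(p[4])
        out$tpsa[i] <- as.numeric(p[5])
        out$nha[i] <- as.integer(p[6])
        out$nhd[i] <- as.integer(p[7])
      }
    }
  }
  ps <- parseSmiles(smiles[usable], ids = tags[usable])
  if (!is.null(ps$sdf) && length(ps$sdf) > 0) {
    got <- ChemmineR::sdfid(ps$sdf)
    for (k in seq_along(got)) {
      i <- match(got[k], tags)
      out$nrot[i] <- .countRotors(.molGraph(ps$sdf[[k]]))
    }
  }
  out
}

#' Two-sample Mann-Whitney U test
#'
#' Rank-sum test with the U statistic (ties counted one half). For small
#' samples (`min(n1, n2) <= exact_max` and no more than 2e5 rank
#' assignments) the two-sided p-value is computed by exact enumeration of
#' all assignments of the pooled ranks; otherwise by the tie-corrected
#' normal approximation.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest `min(n1, n2)` for which enumeration is tried.
#' @return List with `u` (the U statistic of `x`), `p` (two-sided p-value)
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mannWhitneyU <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  if (min(n1, n2) <= exact_max && choose(n1 + n2, n1) <= 2e5) {
    picks <- utils::combn(n1 + n2, n1)
    dev <- abs(apply(picks, 2, function(ix) sum(r[ix])) -
                 n1 * (n1 + 1) / 2 - mid)
    p <- mean(dev >= abs(u - mid) - 1e-12)
    return(list(u = u, p = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal"))
  z <- (u - mid) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Group-wise property summaries with Mann-Whitney tests
#'
#' For each of the six properties, reports min, max, median, mean, sample
#' skewness (adjusted Fisher-Pearson) and excess kurtosis per group
#' (group 1 = potent/active, group 2 = intermediate/inactive), plus the
#' two-sided Mann-Whitney U p-value between the groups. Skewness and
#' kurtosis of a constant sample are reported as `NaN`.
#'
#' @param curated A [CuratedSet-class].
#' @param properties Optional precomputed property `data.frame` from
#'   [computeProperties()] (rows aligned with `molecules(curated)`).
#' @return List with `stats` (long `data.frame`: property, group,
#'   min/max/median/mean/skew/kurtosis) and `u_pvalue` (named vector per
#'   property).
#' @export
summarizeGroups <- function(curated, properties = NULL) {
  stopifnot(is(curated, "CuratedSet"))
  m <- molecules(curated)
  if (is.null(properties))
    properties <- computeProperties(m$smiles, ids = m$molecule_id)
  stopifnot(nrow(properties) == nrow(m))
  for (g in c("group1", "group2"))
    if (!any(m$group == g)) stop("summarizeGroups: ", g, " is empty")
  rows <- list(); pv <- numeric(0)
  for (prop in .PROPERTY_NAMES) {
    v <- properties[[prop]]
    for (g in c("group1", "group2")) {
      x <- v[m$group == g & !is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        property = prop, group = g, min = min(x), max = max(x),
        median = stats::median(x), mean = mean(x),
        skew = if (stats::sd(x) == 0) NaN else
          e1071::skewness(x, type = 2),
        kurtosis = if (stats::sd(x) == 0) NaN else
          e1071::kurtosis(x, type = 2),
        stringsAsFactors = FALSE)
    }
    pv[prop] <- mannWhitneyU(v[m$group == "group1"],
                             v[m$group == "group2"])$p
  }
  list(stats = do.call(rbind, rows), u_pvalue = pv)
}

#' PCA of the property space
#'
#' Principal component analysis of the six physicochemical properties,
#' standardised to zero mean and unit variance (the properties have
#' incommensurate units). Components are ordered by decreasing explained
#' variance; each loading column is sign-fixed so its largest-magnitude
#' coefficient is positive.
#'
#' @param properties `data.frame`/matrix of property columns (rows =
#'   molecules).
#' @param k Number of components to keep (default all).
#' @return List with `loadings` (p x k, orthonormal columns), `scores`
#'   (n x k), `explained_variance` and `cumulative_variance` (percentages).
#' @export
runPropertyPCA <- function(properties, k = ncol(properties)) {
  x <- as.matrix(properties)
  stopifnot(nrow(x) >= 2, k >= 1, k <= ncol(x))
  if (anyNA(x)) stop("runPropertyPCA: missing property values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("runPropertyPCA: constant property column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "),
         " -- remove before PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  sco <- sweep(pc$x, 2, flip, `*`)
  varexp <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = rot[, seq_len(k), drop = FALSE],
       scores = sco[, seq_len(k), drop = FALSE],
       explained_variance = varexp[seq_len(k)],
       cumulative_variance = cumsum(varexp)[seq_len(k)])
}
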