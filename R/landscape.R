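# Molecular fingerprints, Tanimoto similarity, SAS maps, SALI values,
# activity cliffs, consensus cliffs and cliff-generator rankings.

.FP_KINDS <- c(ecfp4 = 2048L, maccs = 166L, pubchem = 881L)

#' Binary molecular fingerprints
#'
#' Computes fixed-length binary fingerprints per molecule:
#' \describe{
#'   \item{`ecfp4`}{Circular (Morgan-type) fingerprint of radius 2, hashed
#'     and folded to 2048 bits (backend ECFP4 output OR-folded in half).}
#'   \item{`maccs`}{The 166 MACCS structural keys from the backend.}
#'   \item{`pubchem`}{An 881-position substructure-key fingerprint laid out
#'     in the PubChem key families -- hierarchic element counts, ring
#'     topology counts, bonded-element-pair and three-atom-path fragments --
#'     computed natively on the molecular graph. The layout is pluggable:
#'     landscape statistics only require a deterministic binary vector per
#'     molecule.}
#' }
#'
#' @param smiles Character vector of SMILES.
#' @param kind One of `"ecfp4"`, `"maccs"`, `"pubchem"`.
#' @param ids Optional row names.
#' @return Binary (0/1) integer matrix, one row per molecule; rows of
#'   unparsable molecules are dropped.
#' @export
moleculeFingerprints <- function(smiles, kind = c("ecfp4", "maccs",
                                                  "pubchem"), ids = NULL) {
  kind <- match.arg(kind)
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    paste0("mol", seq_along(smiles))
  p <- parseSmiles(smiles, ids = ids)
  if (is.null(p$sdf) || length(p$sdf) == 0)
    stop("moleculeFingerprints: no parseable molecules")
  got <- ChemmineR::sdfid(p$sdf)
  if (kind == "pubchem") {
    m <- t(vapply(seq_len(length(p$sdf)), function(i)
      .pubchemKeys(.molGraph(p$sdf[[i]])), integer(881)))
  } else {
    fpname <- c(ecfp4 = "ECFP4", maccs = "MACCS")[[kind]]
    nb_raw <- c(ecfp4 = 4096L, maccs = 256L)[[kind]]
    # molecules without bonds break the SDF round trip of the in-process
    # backend; their fingerprints come from a direct CLI call instead
    nobond <- vapply(seq_len(length(p$sdf)), function(i) {
      bb <- ChemmineR::bondblock(p$sdf[[i]])
      !is.matrix(bb) || nrow(bb) == 0
    }, logical(1))
    raw <- matrix(0L, length(p$sdf), nb_raw)
    if (any(!nobond))
      raw[!nobond, ] <- ChemmineR::fingerprintOB(p$sdf[!nobond],
                                                 fpname)@fpma
    if (any(nobond)) {
      ids_nb <- ChemmineR::sdfid(p$sdf)[nobond]
      smi_nb <- smiles[match(ids_nb, ids)]
      raw[nobond, ] <- .fingerprintCLI(smi_nb, ids_nb, fpname, nb_raw)
    }
    m <- if (kind == "ecfp4") {
      (raw[, 1:2048, drop = FALSE] | raw[, 2049:4096, drop = FALSE]) * 1L
    } else {
      raw[, 1:166, drop = FALSE] * 1L
    }
  }
  rownames(m) <- got
  colnames(m) <- paste0(kind, seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

# Fingerprints via the backend CLI's hex dump (words printed most
# significant first; bit k of the reversed word sequence is key k+1).
.fingerprintCLI <- function(smiles, ids, fpname, nbits) {
  out <- .obabel(paste(smiles, ids), "smi", "fpt",
                 args = c(paste0("-xf", fpname), "-xh"))
  m <- matrix(0L, length(ids), nbits)
  cur <- NULL; words <- list()
  flushMol <- function() {
    if (is.null(cur) || !cur %in% ids) return()
    v <- unlist(words)
    v <- rev(v)
    bits <- integer(nbits)
    for (i in seq_along(v)) {
      hi <- strtoi(substr(v[i], 1, 4), 16L)
      lo <- strtoi(substr(v[i], 5, 8), 16L)
      for (j in 0:15) {
        if (floor(lo / 2^j) %% 2 == 1) bits[(i - 1) * 32 + j + 1] <- 1L
        if (floor(hi / 2^j) %% 2 == 1) bits[(i - 1) * 32 + j + 17] <- 1L
      }
    }
    m[match(cur, ids), ] <<- bits[seq_len(nbits)]
  }
  for (line in out) {
    if (grepl("^>", line)) {
      flushMol()
      cur <- sub("^>([^ ]+).*$", "\\1", line)
      words <- list()
    } else if (grepl("^[0-9a-f ]+$", line)) {
      words[[length(words) + 1L]] <- strsplit(trimws(line), " +")[[1]]
    }
  }
  flushMol()
  m
}

# PubChem-style 881-position key vector for one molecular graph.
# Families: [1..50] element counts, [51..100] ring topology,
# [101..180] bonded element pairs, [181..260] three-atom paths.
# Remaining positions are reserved (always 0).
.pubchemKeys <- function(mg) {
  bits <- integer(881)
  elem <- mg$elem; b <- mg$bonds
  cnt <- function(e) sum(elem == e)
  thr <- function(base, value, cuts) {
    for (j in seq_along(cuts)) if (value >= cuts[j]) bits[base + j] <<- 1L
  }
  halo <- cnt("F") + cnt("Cl") + cnt("Br") + cnt("I")
  hetero <- sum(!elem %in% c("C", "H"))
  thr(0, length(elem), c(1, 6, 12, 24, 32, 48))
  thr(6, cnt("C"), c(2, 4, 8, 16, 24, 32))
  thr(12, cnt("N"), c(1, 2, 4, 6))
  thr(16, cnt("O"), c(1, 2, 4, 8, 12))
  thr(21, cnt("F"), c(1, 2, 4))
  thr(24, cnt("Cl"), c(1, 2))
  thr(26, cnt("Br"), c(1, 2))
  thr(28, cnt("I"), 1)
  thr(29, cnt("S"), c(1, 2))
  thr(31, cnt("P"), 1)
  thr(32, cnt("B"), 1)
  thr(33, cnt("Si"), 1)
  thr(34, halo, c(1, 2, 4))
  thr(37, hetero, c(1, 4, 8))

  if (nrow(b) > 0) {
    ncomp <- igraph::components(mg$graph)$no
    cyclo <- nrow(b) - mg$n + ncomp
    thr(50, cyclo, 1:8)
    bridges <- as.integer(igraph::bridges(mg$graph))
    ring_edge <- setdiff(seq_len(nrow(b)), bridges)
    if (length(ring_edge) > 0) {
      sizes <- vapply(ring_edge, function(e) {
        g2 <- igraph::delete_edges(mg$graph, e)
        d <- igraph::distances(g2, v = as.character(b$a1[e]),
                               to = as.character(b$a2[e]))
        as.integer(d[1, 1] + 1)
      }, integer(1))
      for (k in 3:12) if (any(sizes == k)) bits[58 + k - 2] <- 1L  # 59..68
      n6 <- floor(sum(sizes == 6) / 6)
      thr(68, n6, c(2, 3, 4))  # 69..71
      ring_atoms <- unique(c(b$a1[ring_edge], b$a2[ring_edge]))
      re <- elem[ring_atoms]
      if (any(re == "N")) bits[72] <- 1L
      if (any(re == "O")) bits[73] <- 1L
      if (any(re == "S")) bits[74] <- 1L
      ring_deg <- tabulate(c(b$a1[ring_edge], b$a2[ring_edge]),
                           nbins = mg$n)
      if (any(ring_deg >= 3)) bits[75] <- 1L  # fused/bridgehead atom
    }

    # Bonded element-pair keys: (pair, order) with thresholds >=1,>=2,>=4.
    pairs <- list(
      c("C", "C", 1), c("C", "C", 2), c("C", "C", 3), c("C", "N", 1),
      c("C", "N", 2), c("C", "N", 3), c("C", "O", 1), c("C", "O", 2),
      c("C", "S", 1), c("C", "F", 1), c("C", "Cl", 1), c("C", "Br", 1),
      c("C", "I", 1), c("N", "N", 1), c("N", "O", 1), c("N", "O", 2),
      c("O", "S", 2), c("N", "S", 1), c("O", "P", 1), c("C", "P", 1))
    e1 <- elem[b$a1]; e2 <- elem[b$a2]
    lo <- pmin(e1, e2); hi <- pmax(e1, e2)
    for (j in seq_along(pairs)) {
      pr <- pairs[[j]]
      a <- min(pr[1], pr[2]); z <- max(pr[1], pr[2])
      nmatch <- sum(lo == a & hi == z & b$order == as.integer(pr[3]))
      thr(100 + (j - 1) * 3, nmatch, c(1, 2, 4))
    }

    # Three-atom path keys (middle atom b, ends a/c with bond orders).
    adj <- lapply(seq_len(mg$n), function(i) {
      rbind(data.frame(nb = b$a2[b$a1 == i], o = b$order[b$a1 == i]),
            data.frame(nb = b$a1[b$a2 == i], o = b$order[b$a2 == i]))
    })
    trip <- list(  # mid, end1, order1, end2, order2
      c("C", "O", 2, "N", 1), c("C", "O", 2, "O", 1), c("C", "O", 2, "C", 1),
      c("C", "N", 1, "N", 1), c("C", "O", 1, "O", 1), c("N", "C", 1, "C", 1),
      c("O", "C", 1, "C", 1), c("C", "F", 1, "F", 1), c("S", "O", 2, "O", 2),
      c("C", "N", 3, "C", 1), c("N", "C", 1, "S", 1), c("C", "S", 1, "C", 1),
      c("C", "Cl", 1, "C", 1), c("C", "F", 1, "C", 1), c("N", "N", 1, "C", 1),
      c("O", "C", 1, "N", 1), c("C", "C", 2, "C", 1), c("N", "O", 2, "O", 1),
      c("C", "N", 2, "N", 1), c("S", "N", 1, "N", 1))
    for (j in seq_along(trip)) {
      tp <- trip[[j]]
      nmatch <- 0L
      for (i in which(elem == tp[1])) {
        nb <- adj[[i]]
        if (nrow(nb) < 2) next
        for (u in seq_len(nrow(nb) - 1)) for (v in (u + 1):nrow(nb)) {
          ok1 <- elem[nb$nb[u]] == tp[2] && nb$o[u] == as.integer(tp[3]) &&
                 elem[nb$nb[v]] == tp[4] && nb$o[v] == as.integer(tp[5])
          ok2 <- elem[nb$nb[v]] == tp[2] && nb$o[v] == as.integer(tp[3]) &&
                 elem[nb$nb[u]] == tp[4] && nb$o[u] == as.integer(tp[5])
          if (ok1 || ok2) nmatch <- nmatch + 1L
        }
      }
      thr(180 + (j - 1) * 2, nmatch, c(1, 2))
    }
  }
  bits
}

#' Tanimoto similarity of two binary vectors
#'
#' `|a AND b| / |a OR b|`; two all-zero vectors give 0 (flagged degenerate
#' via the `"degenerate"` attribute).
#'
#' @param a,b Equal-length binary vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("tanimoto: length mismatch")
  u <- sum(a | b)
  if (u == 0) return(structure(0, degenerate = TRUE))
  sum(a & b) / u
}

# All-pairs Tanimoto of a binary matrix via cross products.
.pairwiseTanimoto <- function(m) {
  inter <- tcrossprod(m)
  n1 <- rowSums(m)
  un <- outer(n1, n1, `+`) - inter
  s <- ifelse(un == 0, 0, inter / un)
  s
}

#' Structure-activity landscape index (SALI)
#'
#' `SALI = |activity difference| / (1 - similarity)`. Pairs with similarity
#' exactly 1 have an undefined SALI (`NA`); they are excluded from SALI
#' rankings but still qualify as activity cliffs when their activity
#' difference exceeds the threshold.
#'
#' @param activity_diff Non-negative activity difference(s), pIC50 units.
#' @param sim Similarity value(s) in `[0, 1]`.
#' @return Numeric vector; `NA` where `sim == 1`.
#' @export
sali <- function(activity_diff, sim) {
  stopifnot(all(sim >= 0 & sim <= 1), all(activity_diff >= 0))
  ifelse(sim == 1, NA_real_, activity_diff / (1 - sim))
}

#' SAS map of a curated set
#'
#' Enumerates all `n(n-1)/2` unordered molecule pairs under one fingerprint
#' and assigns each to a SAS-map quadrant with strict thresholds: `cliff`
#' (sim > simThreshold and diff > actThreshold), `smooth` (sim above, diff
#' at or below), `scaffold_hop` (sim at or below, diff at or below) and
#' `nondescript` (sim at or below, diff above). Pairs with identical
#' fingerprints are flagged `duplicate_structure`.
#'
#' @param curated A [CuratedSet-class].
#' @param kind Fingerprint kind, see [moleculeFingerprints()].
#' @param sim_threshold,act_threshold Strict quadrant thresholds (defaults
#'   0.9 and 2).
#' @param fingerprints Optional precomputed fingerprint matrix (rows named
#'   by molecule id) to reuse across maps.
#' @return A [SASMap-class].
#' @export
sasMap <- function(curated, kind = c("ecfp4", "maccs", "pubchem"),
                   sim_threshold = 0.9, act_threshold = 2.0,
                   fingerprints = NULL) {
  kind <- match.arg(kind)
  stopifnot(is(curated, "CuratedSet"))
  m <- molecules(curated)
  if (nrow(m) < 2) stop("sasMap: need at least 2 molecules")
  fp <- if (is.null(fingerprints))
    moleculeFingerprints(m$smiles, kind, ids = m$molecule_id) else
    fingerprints
  fp <- fp[m$molecule_id, , drop = FALSE]
  s <- .pairwiseTanimoto(fp)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  sim <- s[idx]
  diffs <- abs(m$pic50[idx[, 1]] - m$pic50[idx[, 2]])
  quad <- ifelse(sim > sim_threshold,
                 ifelse(diffs > act_threshold, "cliff", "smooth"),
                 ifelse(diffs > act_threshold, "nondescript",
                        "scaffold_hop"))
  pairs <- data.frame(
    id_a = m$molecule_id[idx[, 1]],
    id_b = m$molecule_id[idx[, 2]],
    sim = sim,
    activity_diff = diffs,
    sali = sali(diffs, sim),
    quadrant = quad,
    duplicate_structure = sim == 1,
    stringsAsFactors = FALSE)
  new("SASMap", pairs = pairs, kind = kind,
      simThreshold = sim_threshold, actThreshold = act_threshold)
}

# Canonical unordered pair keys.
.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "||")

#' Activity-cliff pairs of a SAS map
#'
#' @param sasmap A [SASMap-class].
#' @return The cliff-quadrant rows of the pair table.
#' @export
activityCliffs <- function(sasmap) {
  stopifnot(is(sasmap, "SASMap"))
  p <- landscapePairs(sasmap)
  p[p$quadrant == "cliff", , drop = FALSE]
}

#' Consensus activity cliffs across fingerprints
#'
#' Intersects the activity-cliff pair sets of two or more SAS maps (or raw
#' pair tables); a consensus cliff is detected under every fingerprint.
#'
#' @param ac_sets Named list (by fingerprint kind) of cliff pair tables
#'   (`id_a`, `id_b` columns) or [SASMap-class] objects.
#' @return `data.frame` with the consensus `id_a`, `id_b` pairs.
#' @export
consensusACs <- function(ac_sets) {
  stopifnot(length(ac_sets) >= 2)
  keysets <- lapply(ac_sets, function(x) {
    if (is(x, "SASMap")) x <- activityCliffs(x)
    unique(.pairKey(x$id_a, x$id_b))
  })
  common <- Reduce(intersect, keysets)
  parts <- strsplit(common, "||", fixed = TRUE)
  data.frame(id_a = vapply(parts, `[`, "", 1),
             id_b = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Activity-cliff generators
#'
#' Counts, per molecule, the number of activity-cliff pairs it participates
#' in; molecules with at least `min_count` cliff memberships are reported
#' ranked by count (descending), molecule id breaking ties.
#'
#' @param acs Cliff pair table (`id_a`, `id_b`) or a [SASMap-class].
#' @param min_count Minimum number of cliff pairs (default 2).
#' @return `data.frame`: `molecule_id`, `ac_count`, `rank` (dense ranks).
#' @export
acGenerators <- function(acs, min_count = 2) {
  if (is(acs, "SASMap")) acs <- activityCliffs(acs)
  if (nrow(acs) == 0)
    return(data.frame(molecule_id = character(0), ac_count = integer(0),
                      rank = integer(0)))
  cnt <- table(c(acs$id_a, acs$id_b))
  cnt <- cnt[cnt >= min_count]
  if (length(cnt) == 0)
    return(data.frame(molecule_id = character(0), ac_count = integer(0),
                      rank = integer(0)))
  ord <- order(-cnt, names(cnt))
  cnt <- cnt[ord]
  data.frame(molecule_id = names(cnt),
             ac_count = as.integer(cnt),
             rank = match(-as.integer(cnt), sort(unique(-as.integer(cnt)))),
             stringsAsFactors = FALSE, row.names = NULL)
}
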