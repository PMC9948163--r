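# Bemis-Murcko scaffolds, cyclic skeletons, diversity metrics, enrichment
# factors and R-group decomposition.

# Murcko framework atom indices of one molecular graph: the 2-core (ring
# systems plus linkers; iterative removal of terminal atoms), plus atoms
# attached to the core by a bond of order >= 2 (exocyclic =O and the like).
.murckoAtoms <- function(mg) {
  if (nrow(mg$bonds) == 0) return(integer(0))
  core <- as.integer(igraph::V(mg$graph)$name[igraph::coreness(mg$graph) >= 2])
  if (length(core) == 0) return(integer(0))
  b <- mg$bonds
  exo <- unique(c(b$a2[b$a1 %in% core & !(b$a2 %in% core) & b$order >= 2],
                  b$a1[b$a2 %in% core & !(b$a1 %in% core) & b$order >= 2]))
  sort(unique(c(core, exo)))
}

#' Bemis-Murcko scaffold of molecules
#'
#' Extracts the molecular framework: all ring systems plus the linker atoms
#' connecting them, terminal side chains removed. Atoms double-bonded to the
#' framework (e.g. exocyclic carbonyl oxygens) are retained. Acyclic
#' molecules yield an empty string.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules, `NA` for parse failures).
#' @export
murckoScaffold <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  p <- parseSmiles(smiles, ids = paste0("m", seq_along(smiles)))
  if (sum(p$ok) == 0) return(out)
  idx_ok <- which(p$ok)
  subs <- list(); sub_pos <- integer(0)
  res <- character(length(idx_ok))
  for (k in seq_along(idx_ok)) {
    sdfobj <- p$sdf[[k]]
    mg <- .molGraph(sdfobj)
    atoms <- .murckoAtoms(mg)
    if (length(atoms) == 0) {
      res[k] <- ""
    } else if (length(atoms) == mg$n) {
      res[k] <- NA_character_  # canonicalise below, whole molecule
      subs[[length(subs) + 1L]] <- sdfobj
      sub_pos <- c(sub_pos, k)
    } else {
      res[k] <- NA_character_
      subs[[length(subs) + 1L]] <- .subSDF(sdfobj, atoms)
      sub_pos <- c(sub_pos, k)
    }
  }
  if (length(subs) > 0) {
    set <- new("SDFset", SDF = subs, ID = paste0("s", seq_along(subs)))
    res[sub_pos] <- .canonicalOfSDF(set)
  }
  out[idx_ok] <- res
  out
}

#' Cyclic skeleton (CSK) of scaffolds
#'
#' Abstracts a Murcko scaffold to its ring/linker topology: every atom is
#' replaced by carbon and every bond by a single bond, then the result is
#' canonicalised. Benzene and pyridine share the cyclohexane skeleton;
#' quinoline maps to the decalin skeleton.
#'
#' @param scaffold_smiles Character vector of non-empty scaffold SMILES.
#' @return Character vector of canonical skeleton SMILES.
#' @export
cyclicSkeleton <- function(scaffold_smiles) {
  if (any(is.na(scaffold_smiles) | !nzchar(scaffold_smiles)))
    stop("cyclicSkeleton: empty scaffold")
  p <- parseSmiles(scaffold_smiles,
                   ids = paste0("m", seq_along(scaffold_smiles)))
  if (any(!p$ok)) stop("cyclicSkeleton: unparsable scaffold SMILES")
  subs <- lapply(seq_len(length(p$sdf)), function(i) {
    sdfobj <- p$sdf[[i]]
    ab <- ChemmineR::atomblock(sdfobj)
    rownames(ab) <- paste0("C_", seq_len(nrow(ab)))
    sdfobj@atomblock <- ab
    bb <- ChemmineR::bondblock(sdfobj)
    if (is.matrix(bb) && nrow(bb) > 0) {
      bb[, 3] <- 1
      sdfobj@bondblock <- bb
    }
    sdfobj
  })
  set <- new("SDFset", SDF = subs, ID = paste0("s", seq_along(subs)))
  .canonicalOfSDF(set)
}

#' Scaffold table of a curated set
#'
#' Groups molecules by Murcko scaffold, attaches cyclic skeletons,
#' frequencies and scaffold enrichment factors, and sorts by decreasing
#' frequency (scaffold SMILES breaks ties). All acyclic molecules collapse
#' into one record flagged `acyclic` (empty scaffold, no skeleton).
#'
#' @param curated A [CuratedSet-class].
#' @return A [ScaffoldSet-class].
#' @export
buildScaffoldTable <- function(curated) {
  stopifnot(is(curated, "CuratedSet"))
  m <- molecules(curated)
  if (nrow(m) == 0) stop("buildScaffoldTable: empty curated set")
  scaf <- murckoScaffold(m$smiles)
  if (anyNA(scaf)) stop("buildScaffoldTable: scaffold extraction failed for ",
                        paste(m$molecule_id[is.na(scaf)], collapse = ", "))
  groups <- split(m$molecule_id, scaf)
  smls <- names(groups)
  freq <- lengths(groups)
  ord <- order(-freq, smls)
  smls <- smls[ord]; freq <- freq[ord]; groups <- groups[ord]
  acyclic <- !nzchar(smls)
  csk <- rep(NA_character_, length(smls))
  if (any(!acyclic)) csk[!acyclic] <- cyclicSkeleton(smls[!acyclic])
  # EF is undefined on a set without potent/active molecules (e.g. the
  # per-class tables of group-2 classes); reported NA there.
  ef <- if (any(m$activity_class %in% c("potent", "active"))) {
    vapply(groups, function(ids)
      enrichmentFactor(m$activity_class[m$molecule_id %in% ids],
                       m$activity_class), numeric(1))
  } else rep(NA_real_, length(groups))
  tab <- data.frame(scaffold_smiles = smls, csk_smiles = csk,
                    frequency = as.integer(freq), ef = unname(ef),
                    acyclic = acyclic, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("ScaffoldSet", scaffolds = tab, members = groups, n = nrow(m))
}

#' Diversity ratios from scaffold counts
#'
#' The four standard scaffold-diversity ratios, rounded to three decimals:
#' Ns/N, Nss/N, Ncsk/N and Ncsk/Ns.
#'
#' @param n Molecule count N.
#' @param ns Murcko scaffold count Ns.
#' @param nss Singleton scaffold count Nss.
#' @param ncsk Cyclic skeleton count Ncsk.
#' @return Named numeric vector `ns_n`, `nss_n`, `ncsk_n`, `ncsk_ns`.
#' @examples
#' diversityRatios(1678, 558, 362, 317)
#' @export
diversityRatios <- function(n, ns, nss, ncsk) {
  round(c(ns_n = ns / n, nss_n = nss / n, ncsk_n = ncsk / n,
          ncsk_ns = ncsk / ns), 3)
}

#' Scaffold diversity metrics per activity class
#'
#' Counts molecules (N), Murcko scaffolds (Ns), singleton scaffolds (Nss)
#' and cyclic skeletons (Ncsk) for the complete set and, optionally, for
#' each activity class independently (classes may share scaffolds, so class
#' rows can sum to more than the complete row). Acyclic molecules count one
#' shared scaffold record and no skeleton.
#'
#' @param curated A [CuratedSet-class].
#' @param by_class Also report each non-empty activity class.
#' @return `data.frame` with one row per reported set: raw counts plus the
#'   ratios of [diversityRatios()] (rounded to 3 decimals).
#' @export
diversityMetrics <- function(curated, by_class = TRUE) {
  stopifnot(is(curated, "CuratedSet"))
  m <- molecules(curated)
  if (nrow(m) == 0) stop("diversityMetrics: empty curated set")
  one <- function(sub, label) {
    cs <- new("CuratedSet", molecules = sub, log = list())
    st <- scaffolds(buildScaffoldTable(cs))
    n <- nrow(sub)
    ns <- nrow(st)
    nss <- sum(st$frequency == 1)
    ncsk <- length(unique(st$csk_smiles[!st$acyclic]))
    r <- diversityRatios(n, ns, nss, ncsk)
    data.frame(set = label, n = n, ns = ns, nss = nss, ncsk = ncsk,
               ns_n = r[["ns_n"]], nss_n = r[["nss_n"]],
               ncsk_n = r[["ncsk_n"]], ncsk_ns = r[["ncsk_ns"]],
               stringsAsFactors = FALSE)
  }
  out <- one(m, "complete")
  if (by_class) {
    for (cl in ACTIVITY_LEVELS) {
      sub <- m[m$activity_class == cl, , drop = FALSE]
      if (nrow(sub) == 0) {
        warning("diversityMetrics: class '", cl, "' is empty, omitted")
        next
      }
      out <- rbind(out, one(sub, cl))
    }
  }
  rownames(out) <- NULL
  out
}

#' Scaffold enrichment factor
#'
#' Ratio of the proportion of group-1 (potent + active) molecules among a
#' scaffold's members to the proportion of group-1 molecules in the whole
#' data set. EF > 1 marks scaffolds enriched in potent/active chemistry;
#' a scaffold with no group-1 members has EF 0.
#'
#' @param member_classes Activity classes of the scaffold's members.
#' @param dataset_classes Activity classes of the full data set.
#' @return The enrichment factor (numeric scalar).
#' @export
enrichmentFactor <- function(member_classes, dataset_classes) {
  g1 <- c("potent", "active")
  total_g1 <- sum(dataset_classes %in% g1)
  if (total_g1 == 0)
    stop("enrichmentFactor: no potent/active molecules in the data set")
  (sum(member_classes %in% g1) / length(member_classes)) /
    (total_g1 / length(dataset_classes))
}

#' R-group decomposition of a molecule against a scaffold
#'
#' Matches the scaffold into the molecule (element-labelled VF2 subgraph
#' isomorphism) and reports the substituent at every scaffold position.
#' Positions are labelled `R1..Rk` in the atom order of the canonicalised
#' scaffold, which fixes the labels deterministically; of the symmetric
#' matches the one with the lexicographically smallest atom mapping is used.
#' Unsubstituted positions map to `"[H]"`; multiple substituents on one
#' position are dot-joined.
#'
#' @param smiles SMILES of the member molecule.
#' @param scaffold_smiles SMILES of the scaffold (must be a substructure).
#' @param id Molecule id used in error messages.
#' @return Named character vector (`R1..Rk`) of substituent SMILES.
#' @export
rgroupDecompose <- function(smiles, scaffold_smiles, id = "molecule") {
  can_scaf <- canonicalSmiles(scaffold_smiles)
  if (is.na(can_scaf)) stop("rgroupDecompose: unparsable scaffold")
  ps <- parseSmiles(can_scaf, ids = "scaffold")
  pm <- parseSmiles(smiles, ids = "member")
  if (!all(pm$ok)) stop("rgroupDecompose: unparsable member ", id)
  gs <- .molGraph(ps$sdf[[1]])
  gm <- .molGraph(pm$sdf[[1]])
  iso <- igraph::subgraph_isomorphisms(
    pattern = gs$graph, target = gm$graph, method = "vf2",
    vertex.color1 = as.integer(factor(gm$elem,
      levels = sort(unique(c(gm$elem, gs$elem))))),
    vertex.color2 = as.integer(factor(gs$elem,
      levels = sort(unique(c(gm$elem, gs$elem))))))
  if (length(iso) == 0)
    stop("rgroupDecompose: scaffold is not a substructure of ", id)
  maps <- lapply(iso, function(m) as.integer(igraph::V(gm$graph)$name[m]))
  key <- vapply(maps, function(v) paste(sprintf("%06d", v), collapse = ""),
                character(1))
  map <- maps[[which.min(key)]]  # member atom index per scaffold atom
  mapped <- map
  out <- character(length(map))
  b <- gm$bonds
  for (i in seq_along(map)) {
    a <- map[i]
    nb <- c(b$a2[b$a1 == a], b$a1[b$a2 == a])
    att <- setdiff(nb, mapped)
    if (length(att) == 0) {
      out[i] <- "[H]"
      next
    }
    frags <- character(0)
    rest <- igraph::induced_subgraph(
      gm$graph, igraph::V(gm$graph)[!(as.integer(igraph::V(gm$graph)$name)
                                      %in% mapped)])
    comp <- igraph::components(rest)
    for (at in att) {
      vid <- which(as.integer(igraph::V(rest)$name) == at)
      memb <- comp$membership == comp$membership[vid]
      atoms <- sort(as.integer(igraph::V(rest)$name[memb]))
      frag <- .canonicalOfSDF(.subMol(pm$sdf[[1]], atoms, id = "frag"))
      frags <- c(frags, frag)
    }
    out[i] <- paste(sort(frags), collapse = ".")
  }
  stats::setNames(out, paste0("R", seq_along(out)))
}

#' R-group table for one scaffold
#'
#' Decomposes every member of a scaffold and tabulates substituents per
#' position together with pIC50 and activity class, the raw material of a
#' local SAR table.
#'
#' @param curated A [CuratedSet-class].
#' @param scaffold_smiles The scaffold to decompose against.
#' @param member_ids Ids of the members (default: all molecules whose Murcko
#'   scaffold equals `scaffold_smiles`).
#' @return `data.frame`: `molecule_id`, one column per position `R1..Rk`,
#'   `pic50`, `activity_class`.
#' @export
rgroupTable <- function(curated, scaffold_smiles, member_ids = NULL) {
  stopifnot(is(curated, "CuratedSet"))
  m <- molecules(curated)
  if (is.null(member_ids)) {
    scaf <- murckoScaffold(m$smiles)
    member_ids <- m$molecule_id[!is.na(scaf) &
                                scaf == canonicalSmiles(scaffold_smiles)]
  }
  sub <- m[m$molecule_id %in% member_ids, , drop = FALSE]
  if (nrow(sub) == 0) stop("rgroupTable: no members for this scaffold")
  rows <- lapply(seq_len(nrow(sub)), function(i)
    rgroupDecompose(sub$smiles[i], scaffold_smiles, id = sub$molecule_id[i]))
  k <- length(rows[[1]])
  out <- data.frame(molecule_id = sub$molecule_id,
                    do.call(rbind, rows),
                    pic50 = sub$pic50,
                    activity_class = sub$activity_class,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
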