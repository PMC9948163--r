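# Thin layer over OpenBabel (via the obabel CLI for batch conversions and
# ChemmineR/ChemmineOB for containers, fingerprints and SMARTS): SMILES
# parsing, canonicalisation, molecular graphs, induced-subgraph SMILES.
# Everything downstream goes through these helpers so the chemistry backend
# is swapped in one place. The CLI is used for conversions because it
# processes whole tables in a single invocation.

# Run obabel on `input` text; returns stdout lines.
.obabel <- function(input, iformat, oformat, args = character(0)) {
  infile <- tempfile(fileext = paste0(".", iformat))
  on.exit(unlink(infile), add = TRUE)
  writeLines(input, infile)
  out <- suppressWarnings(system2("obabel",
    c(infile, paste0("-o", oformat), args),
    stdout = TRUE, stderr = FALSE))
  out
}

# SMILES lines ("<smiles> <id>") -> named canonical SMILES (NA = failed).
.obCanonical <- function(smiles, ids) {
  out <- .obabel(paste(smiles, ids), "smi", "can")
  res <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (length(out)) {
    parts <- strsplit(trimws(out), "[ \t]+")
    for (p in parts) if (length(p) >= 2 && p[2] %in% ids) res[p[2]] <- p[1]
  }
  res
}

#' Parse SMILES strings into an SDF set
#'
#' Parses a named vector of SMILES into a `ChemmineR::SDFset` (through a
#' single OpenBabel invocation), dropping and reporting molecules the
#' backend cannot parse.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional character vector of identifiers (defaults to names of
#'   `smiles`, else `mol1..moln`).
#' @return A list with elements `sdf` (an `SDFset` of the parseable
#'   molecules, compound ids set from `ids`), `ok` (logical vector over the
#'   input), and `failed` (ids that failed to parse).
#' @export
parseSmiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    paste0("mol", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyNA(ids),
            !anyDuplicated(ids))
  smiles <- as.character(smiles)
  usable <- !is.na(smiles) & nzchar(smiles)
  sdftxt <- .obabel(paste(smiles[usable], ids[usable]), "smi", "sdf")
  if (length(sdftxt) == 0 || !any(grepl("\\$\\$\\$\\$", sdftxt))) {
    return(list(sdf = NULL, ok = rep(FALSE, length(smiles)), failed = ids))
  }
  sdf <- suppressWarnings(ChemmineR::read.SDFset(sdftxt))
  sdf <- .repairZeroBondMols(sdf, sdftxt)
  got <- ChemmineR::sdfid(sdf)
  # molecules OpenBabel skipped, or that came back without atoms, failed
  natoms <- vapply(seq_len(length(sdf)), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    if (is.matrix(ab)) nrow(ab) else 0L
  }, integer(1))
  keep <- !is.na(got) & got %in% ids & natoms >= 1
  sdf <- sdf[keep]
  ChemmineR::cid(sdf) <- ChemmineR::sdfid(sdf)
  ok <- ids %in% ChemmineR::sdfid(sdf)
  list(sdf = sdf, ok = ok, failed = ids[!ok])
}

#' Canonicalise SMILES strings
#'
#' Returns backend-canonical SMILES (no stereo) for each input; `NA` for
#' molecules that fail to parse.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of the same length.
#' @export
canonicalSmiles <- function(smiles) {
  ids <- paste0("q", seq_along(smiles))
  usable <- !is.na(smiles) & nzchar(as.character(smiles))
  out <- rep(NA_character_, length(smiles))
  if (any(usable))
    out[usable] <- unname(.obCanonical(smiles[usable], ids[usable]))
  out
}

# read.SDFset mangles the atom block of molecules without bonds (e.g.
# methane); rebuild those entries from the raw molfile text.
.repairZeroBondMols <- function(sdf, sdftxt) {
  bad <- which(vapply(seq_len(length(sdf)), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    !is.matrix(ab) || ncol(ab) < 3
  }, logical(1)))
  if (length(bad) == 0) return(sdf)
  ends <- which(grepl("^\\$\\$\\$\\$", sdftxt))
  starts <- c(1, head(ends, -1) + 1)
  titles <- sdftxt[starts]
  for (i in bad) {
    id <- ChemmineR::sdfid(sdf[i])
    k <- match(id, titles)
    if (is.na(k)) next
    block <- sdftxt[starts[k]:ends[k]]
    counts <- block[4]
    natoms <- as.integer(substr(counts, 1, 3))
    atoms <- block[5:(4 + natoms)]
    elem <- trimws(substr(atoms, 32, 34))
    ab <- cbind(C1 = as.numeric(substr(atoms, 1, 10)),
                C2 = as.numeric(substr(atoms, 11, 20)),
                C3 = as.numeric(substr(atoms, 21, 30)))
    rownames(ab) <- paste(elem, seq_len(natoms), sep = "_")
    obj <- sdf[[i]]
    obj@atomblock <- ab
    obj@bondblock <- matrix(0, 0, 3,
                            dimnames = list(NULL, c("C1", "C2", "C3")))
    sdf@SDF[[i]] <- obj
  }
  sdf
}

# Molecular graph of one SDF: elements, bond table, igraph object.
.molGraph <- function(sdfobj) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  n <- nrow(ab)
  elem <- sub("_.*$", "", rownames(ab))
  if (is.matrix(bb) && nrow(bb) > 0) {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  g <- igraph::graph_from_data_frame(
    bonds[, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n), elem = elem))
  list(n = n, elem = elem, bonds = bonds, graph = g)
}

# Build an SDFset (length 1) from an existing SDF restricted to atom
# indices. Unlike the stock subsetter this handles one-atom and
# zero-bond fragments.
.subMol <- function(sdfobj, idx, id = "sub") {
  new("SDFset", SDF = list(.subSDF(sdfobj, idx)), ID = id)
}

.subSDF <- function(sdfobj, idx) {
  hb <- ChemmineR::header(sdfobj)
  ab_full <- ChemmineR::atomblock(sdfobj)
  ab <- ab_full[idx, , drop = FALSE]
  rownames(ab) <- paste(sub("_.*$", "", rownames(ab_full)[idx]),
                        seq_along(idx), sep = "_")
  bb_full <- ChemmineR::bondblock(sdfobj)
  if (is.matrix(bb_full) && nrow(bb_full) > 0) {
    keep <- bb_full[, 1] %in% idx & bb_full[, 2] %in% idx
    bb <- bb_full[keep, , drop = FALSE]
    bb[, 1] <- match(bb[, 1], idx)
    bb[, 2] <- match(bb[, 2], idx)
    if (nrow(bb) > 0) rownames(bb) <- seq_len(nrow(bb))
  } else {
    bb <- matrix(0, 0, 3, dimnames = list(NULL, c("C1", "C2", "C3")))
  }
  hb[4] <- paste0(sprintf("%3d", nrow(ab)), sprintf("%3d", nrow(bb)),
                  substr(hb[4], 7, 1000L))
  new("SDF", header = hb, atomblock = ab, bondblock = bb)
}

# V2000 molfile text for one SDF object (handles zero-bond fragments).
.molfileText <- function(sdfobj, title) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  nb <- if (is.matrix(bb)) nrow(bb) else 0L
  elem <- sub("_.*$", "", rownames(ab))
  c(title,
    " chemlandscape",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(ab), nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            ab[, 1], ab[, 2], ab[, 3], elem),
    if (nb > 0) sprintf("%3d%3d%3d  0  0  0  0",
                        as.integer(bb[, 1]), as.integer(bb[, 2]),
                        as.integer(bb[, 3])),
    "M  END",
    "$$$$")
}

# Canonical SMILES of a list of SDF objects (one obabel call; order kept).
.canonicalOfSDFList <- function(sdfs) {
  txt <- unlist(lapply(seq_along(sdfs), function(i)
    .molfileText(sdfs[[i]], paste0("x", i))))
  out <- .obabel(txt, "sdf", "can")
  res <- rep(NA_character_, length(sdfs))
  if (length(out)) {
    parts <- strsplit(trimws(out), "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2 && grepl("^x[0-9]+$", p[2]))
        res[as.integer(sub("^x", "", p[2]))] <- p[1]
    }
  }
  if (anyNA(res)) stop("canonicalisation failed for ", sum(is.na(res)),
                       " fragment(s)")
  res
}

.canonicalOfSDF <- function(sdfset) {
  .canonicalOfSDFList(lapply(seq_len(length(sdfset)),
                             function(i) sdfset[[i]]))
}

# Count unique SMARTS matches for every molecule in an SDFset.
.smartsCount <- function(sdfset, smarts) {
  as.integer(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = TRUE))
}
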