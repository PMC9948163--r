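# Curation of ChEMBL-style bioactivity exports: read, essential-value
# filter, molecule-level deduplication, pIC50 computation, class labeling,
# steroid flagging.

# Default ChEMBL export column mapping.
.DEFAULT_DIALECT <- list(
  molecule_id = "Molecule ChEMBL ID",
  smiles = "Smiles",
  standard_type = "Standard Type",
  relation = "Standard Relation",
  standard_value = "Standard Value",
  units = "Standard Units",
  pchembl = "pChEMBL Value"
)

#' Read a ChEMBL-style bioactivity table
#'
#' Reads a CSV/TSV export into the package's canonical record layout:
#' `molecule_id`, `smiles`, `standard_type`, `relation`, `standard_value`,
#' `units`, `pchembl`. Empty cells become `NA`, never zero. Rows whose
#' value/pchembl cells fail numeric parsing are dropped and counted in the
#' `"parse_errors"` attribute.
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect Named list mapping canonical field names to file column
#'   names; defaults to ChEMBL export headers. `pchembl` is optional in the
#'   file; all other mapped columns are mandatory.
#' @param sep Field separator; default `","` (use `"\t"` for TSV).
#' @return `data.frame` of bioactivity records, with attribute
#'   `parse_errors` (number of rows dropped for unparsable numeric cells).
#' @export
readBioactivityTable <- function(path, dialect = list(), sep = ",") {
  stopifnot(file.exists(path))
  dialect <- utils::modifyList(.DEFAULT_DIALECT, dialect)
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("", "NA"))
  mandatory <- setdiff(names(.DEFAULT_DIALECT), "pchembl")
  for (f in mandatory) {
    if (!dialect[[f]] %in% names(raw))
      stop("bioactivity table is missing mandatory column '", dialect[[f]],
           "' (field ", f, ")")
  }
  rec <- data.frame(
    molecule_id = raw[[dialect$molecule_id]],
    smiles = raw[[dialect$smiles]],
    standard_type = raw[[dialect$standard_type]],
    relation = raw[[dialect$relation]],
    standard_value_chr = raw[[dialect$standard_value]],
    units = raw[[dialect$units]],
    pchembl_chr = if (dialect$pchembl %in% names(raw))
      raw[[dialect$pchembl]] else NA_character_,
    stringsAsFactors = FALSE
  )
  # ChEMBL quotes relations as '"="'; normalise.
  rec$relation <- gsub("'|\"", "", rec$relation)
  num <- function(x) suppressWarnings(as.numeric(x))
  rec$standard_value <- num(rec$standard_value_chr)
  rec$pchembl <- num(rec$pchembl_chr)
  badval <- !is.na(rec$standard_value_chr) & is.na(rec$standard_value)
  badp <- !is.na(rec$pchembl_chr) & is.na(rec$pchembl)
  bad <- badval | badp
  out <- rec[!bad, c("molecule_id", "smiles", "standard_type", "relation",
                     "standard_value", "units", "pchembl")]
  rownames(out) <- NULL
  attr(out, "parse_errors") <- sum(bad)
  out
}

#' Keep records with essential values
#'
#' A record is kept iff it has an IC50 value (`standard_value` present) or a
#' pChEMBL value, AND its relation is exactly `"="`. Everything else (missing
#' values, censored `<`/`>` relations, missing relations) is removed.
#'
#' @param records Bioactivity record `data.frame` (see
#'   [readBioactivityTable()]).
#' @return List with `kept` (the surviving records) and `removed_count`.
#' @export
filterEssential <- function(records) {
  if (nrow(records) == 0)
    return(list(kept = records, removed_count = 0L))
  has_value <- !is.na(records$standard_value) | !is.na(records$pchembl)
  eq <- !is.na(records$relation) & records$relation == "="
  keep <- has_value & eq
  list(kept = records[keep, , drop = FALSE],
       removed_count = as.integer(sum(!keep)))
}

#' Deduplicate records by molecule id
#'
#' Keeps exactly one record per `molecule_id`. With `policy = "first"`
#' (default) the first occurrence in input order is retained. With
#' `policy = "median"` the first occurrence is retained but its
#' `standard_value`/`pchembl` are replaced by the per-id medians, so
#' conflicting duplicate measurements are reconciled.
#'
#' @param records Bioactivity record `data.frame`.
#' @param policy `"first"` or `"median"`.
#' @return List with `kept` and `removed_count`.
#' @export
deduplicateRecords <- function(records, policy = c("first", "median")) {
  policy <- match.arg(policy)
  if (nrow(records) == 0)
    return(list(kept = records, removed_count = 0L))
  first <- !duplicated(records$molecule_id)
  kept <- records[first, , drop = FALSE]
  if (policy == "median" && any(!first)) {
    med <- function(col) tapply(records[[col]], records$molecule_id,
                                function(v) if (all(is.na(v))) NA_real_
                                else stats::median(v, na.rm = TRUE))
    mv <- med("standard_value"); mp <- med("pchembl")
    kept$standard_value <- as.numeric(mv[kept$molecule_id])
    kept$pchembl <- as.numeric(mp[kept$molecule_id])
  }
  rownames(kept) <- NULL
  list(kept = kept, removed_count = as.integer(sum(!first)))
}

#' Convert an IC50 value to pIC50
#'
#' pIC50 = -log10(IC50 in mol/L): `nM` gives `9 - log10(value)`, `uM` gives
#' `6 - log10(value)`, `M` gives `-log10(value)`.
#'
#' @param value Positive IC50 value(s).
#' @param units `"nM"`, `"uM"` or `"M"` (recycled).
#' @return Numeric pIC50; `NA` with a warning-free marker for non-positive
#'   values or unknown units (callers count and exclude these).
#' @export
computePIC50 <- function(value, units) {
  n <- max(length(value), length(units))
  value <- rep_len(as.numeric(value), n)
  units <- rep_len(as.character(units), n)
  offset <- c(nM = 9, uM = 6, M = 0)[units]
  out <- ifelse(!is.na(value) & value > 0 & !is.na(offset),
                unname(offset) - log10(value), NA_real_)
  unname(out)
}

#' Assign the four-level activity class
#'
#' pIC50 >= 8 is `potent`; 7 <= pIC50 < 8 is `active`; 6 <= pIC50 < 7 is
#' `intermediate`; pIC50 < 6 is `inactive`. The four intervals tile the real
#' line, so every finite pIC50 gets exactly one label.
#'
#' @param pic50 Finite numeric vector.
#' @return Factor with levels [ACTIVITY_LEVELS].
#' @export
classifyActivity <- function(pic50) {
  if (any(!is.finite(pic50))) stop("classifyActivity: non-finite pIC50")
  cls <- ifelse(pic50 >= 8, "potent",
         ifelse(pic50 >= 7, "active",
         ifelse(pic50 >= 6, "intermediate", "inactive")))
  factor(cls, levels = ACTIVITY_LEVELS)
}

#' Group label from activity class
#'
#' Group 1 collects the potent and active classes; group 2 the intermediate
#' and inactive classes.
#'
#' @param activity_class Factor/character of activity classes.
#' @return Factor with levels `group1`, `group2`.
#' @export
activityGroup <- function(activity_class) {
  factor(ifelse(activity_class %in% c("potent", "active"),
                "group1", "group2"), levels = c("group1", "group2"))
}

# Gonane (cyclopenta[a]perhydrophenanthrene) as a graph query: the fused
# 6-6-6-5 all-carbon tetracycle with steroid numbering; bond orders are
# deliberately unconstrained so aromatic/unsaturated steroid cores match.
.gonaneGraph <- local({
  edges <- rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 10), c(10, 1),   # ring A
    c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 10),             # ring B
    c(9, 11), c(11, 12), c(12, 13), c(13, 14), c(14, 8),      # ring C
    c(14, 15), c(15, 16), c(16, 17), c(17, 13))               # ring D
  g <- NULL
  function() {
    if (is.null(g))
      g <<- igraph::graph_from_data_frame(
        data.frame(a1 = edges[, 1], a2 = edges[, 2]), directed = FALSE,
        vertices = data.frame(name = 1:17))
    g
  }
})

#' Flag steroidal molecules
#'
#' A molecule is steroidal iff it contains the gonane ring system -- the
#' fused tetracyclic 6-6-6-5 cyclopenta-perhydro-phenanthrene carbocycle --
#' as a substructure. The default match is a carbon-labelled subgraph
#' isomorphism with unconstrained bond orders (so aromatic or unsaturated
#' steroid cores still match); `pattern` accepts a SMARTS query as an
#' alternative operational definition.
#'
#' @param smiles Character vector of SMILES.
#' @param pattern `NULL` (default, built-in gonane graph query) or a SMARTS
#'   string evaluated through the backend.
#' @return Logical vector; `NA` for molecules that fail to parse.
#' @export
flagSteroidal <- function(smiles, pattern = NULL) {
  out <- rep(NA, length(smiles))
  p <- parseSmiles(smiles, ids = paste0("m", seq_along(smiles)))
  if (is.null(p$sdf) || sum(p$ok) == 0) return(out)
  if (!is.null(pattern)) {
    out[p$ok] <- .smartsCount(p$sdf, pattern) > 0
    return(out)
  }
  gq <- .gonaneGraph()
  out[p$ok] <- vapply(seq_len(length(p$sdf)), function(i) {
    mg <- .molGraph(p$sdf[[i]])
    if (sum(mg$elem == "C") < 17 || nrow(mg$bonds) < 20) return(FALSE)
    igraph::subgraph_isomorphic(
      pattern = gq, target = mg$graph, method = "vf2",
      vertex.color1 = as.integer(mg$elem == "C"),
      vertex.color2 = rep(1L, 17))
  }, logical(1))
  out
}

#' Curate a bioactivity table end to end
#'
#' Applies the full curation chain: canonicalise SMILES (parse failures
#' removed and counted), keep essential-value records, deduplicate by
#' molecule id, compute pIC50 (pChEMBL value preferred over converted
#' standard value; disagreements above 0.01 are counted), label activity
#' classes and groups, and flag steroidal molecules.
#'
#' @param records Bioactivity record `data.frame` from
#'   [readBioactivityTable()] or [generateDataset()].
#' @param dedup Duplicate policy, `"first"` (default) or `"median"`.
#' @param steroid_pattern Optional SMARTS for [flagSteroidal()] (default: built-in gonane graph query).
#' @return A [CuratedSet-class].
#' @examples
#' tab <- data.frame(
#'   molecule_id = c("m1", "m2", "m3"),
#'   smiles = c("Cc1ccccc1", "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
#'              "c1ccc2ncccc2c1"),
#'   standard_type = "IC50", relation = "=",
#'   standard_value = c(10, 1000, 50000), units = "nM", pchembl = NA)
#' curateBioactivities(tab)
#' @export
curateBioactivities <- function(records, dedup = c("first", "median"),
                                steroid_pattern = NULL) {
  dedup <- match.arg(dedup)
  log <- list(input = nrow(records))

  fe <- filterEssential(records)
  log$essential_removed <- fe$removed_count
  dd <- deduplicateRecords(fe$kept, policy = dedup)
  log$duplicates_removed <- dd$removed_count
  rec <- dd$kept

  # pIC50: prefer pChEMBL, else convert value+units; drop unconvertible.
  conv <- computePIC50(rec$standard_value, rec$units)
  pic50 <- ifelse(!is.na(rec$pchembl), rec$pchembl, conv)
  log$pchembl_discrepancies <- sum(!is.na(rec$pchembl) & !is.na(conv) &
                                     abs(rec$pchembl - conv) > 0.01)
  convertible <- !is.na(pic50)
  log$conversion_failures <- sum(!convertible)
  rec <- rec[convertible, , drop = FALSE]
  pic50 <- pic50[convertible]

  # SMILES canonicalisation; parse failures excluded and counted.
  can <- canonicalSmiles(rec$smiles)
  okp <- !is.na(can)
  log$parse_failures <- sum(!okp)
  rec <- rec[okp, , drop = FALSE]
  pic50 <- pic50[okp]
  can <- can[okp]

  cls <- classifyActivity(pic50)
  mol <- data.frame(
    molecule_id = rec$molecule_id,
    smiles = can,
    pic50 = pic50,
    activity_class = cls,
    group = activityGroup(cls),
    steroidal = flagSteroidal(can, pattern = steroid_pattern),
    stringsAsFactors = FALSE
  )
  rownames(mol) <- NULL
  log$curated <- nrow(mol)
  new("CuratedSet", molecules = mol, log = log)
}

#' Write a curated set to disk
#'
#' Writes `curated.csv` (molecule_id, smiles, pic50, activity_class, group,
#' steroidal) and `curated.smi` (SMILES + id per line) into `dir`.
#'
#' @param x A [CuratedSet-class].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
writeCurated <- function(x, dir) {
  stopifnot(is(x, "CuratedSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "curated.csv")
  smi <- file.path(dir, "curated.smi")
  utils::write.csv(molecules(x), csv, row.names = FALSE)
  writeLines(paste(molecules(x)$smiles, molecules(x)$molecule_id),
             smi)
  invisible(c(csv = csv, smi = smi))
}
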