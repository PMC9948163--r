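#' Activity class levels
#'
#' Potency classes used throughout the package, ordered from most to least
#' potent: `potent` (pIC50 >= 8), `active` (7 <= pIC50 < 8), `intermediate`
#' (6 <= pIC50 < 7), `inactive` (pIC50 < 6). Group 1 is potent + active,
#' group 2 is intermediate + inactive.
#'
#' @export
ACTIVITY_LEVELS <- c("potent", "active", "intermediate", "inactive")

#' CuratedSet: a curated bioactivity data set
#'
#' Container for a deduplicated, pIC50-annotated molecule set produced by
#' [curateBioactivities()]. One row per molecule with canonical SMILES,
#' pIC50, four-level activity class, two-level group, and a steroid flag.
#'
#' @slot molecules `data.frame` with columns `molecule_id`, `smiles`,
#'   `pic50`, `activity_class` (factor over [ACTIVITY_LEVELS]), `group`
#'   (factor `group1`/`group2`) and `steroidal` (logical).
#' @slot log Named list of curation bookkeeping counts (input size, rows
#'   removed at each filter, parse failures, conversion failures).
#'
#' @seealso [curateBioactivities()], [molecules()], [curationLog()]
#' @export
setClass("CuratedSet", representation(molecules = "data.frame", log = "list"))

setValidity("CuratedSet", function(object) {
  m <- object@molecules
  need <- c("molecule_id", "smiles", "pic50", "activity_class", "group",
            "steroidal")
  if (!all(need %in% names(m)))
    return(paste("missing columns:", paste(setdiff(need, names(m)),
                 collapse = ", ")))
  if (anyDuplicated(m$molecule_id)) return("molecule_id values not unique")
  if (nrow(m) > 0) {
    if (any(!is.finite(m$pic50))) return("non-finite pic50")
    expected <- classifyActivity(m$pic50)
    if (!identical(as.character(expected), as.character(m$activity_class)))
      return("activity_class inconsistent with pic50")
    g1 <- m$activity_class %in% c("potent", "active")
    if (!identical(g1, m$group == "group1"))
      return("group labels inconsistent with activity_class")
  }
  TRUE
})

#' ScaffoldSet: Murcko scaffolds of a curated set
#'
#' One record per distinct Bemis-Murcko scaffold: canonical scaffold SMILES,
#' canonical cyclic-skeleton (CSK) SMILES, member molecule ids, frequency
#' and scaffold enrichment factor. Rows are sorted by frequency (decreasing)
#' then scaffold SMILES. Acyclic molecules collapse into a single record
#' flagged `acyclic` with empty scaffold SMILES.
#'
#' @slot scaffolds `data.frame` with columns `scaffold_smiles`, `csk_smiles`,
#'   `frequency`, `ef`, `acyclic`.
#' @slot members Named list mapping scaffold SMILES (or `""` for the acyclic
#'   record) to the character vector of member molecule ids.
#' @slot n Total number of molecules the table was built from.
#'
#' @seealso [buildScaffoldTable()], [diversityMetrics()]
#' @export
setClass("ScaffoldSet", representation(scaffolds = "data.frame",
                                       members = "list", n = "integer"))

setValidity("ScaffoldSet", function(object) {
  s <- object@scaffolds
  if (nrow(s) != length(object@members)) return("members/scaffolds mismatch")
  if (nrow(s) > 0) {
    if (any(s$frequency < 1)) return("frequency < 1")
    if (sum(s$frequency) != object@n) return("frequencies do not sum to n")
  }
  TRUE
})

#' SASMap: structure-activity similarity map
#'
#' All unordered molecule pairs of a curated set under one fingerprint:
#' Tanimoto similarity, absolute pIC50 difference, SALI value and SAS-map
#' quadrant (`smooth`, `cliff`, `scaffold_hop`, `nondescript`).
#'
#' @slot pairs `data.frame` with columns `id_a`, `id_b`, `sim`,
#'   `activity_diff`, `sali`, `quadrant`, `duplicate_structure`.
#' @slot kind Fingerprint kind used (`ecfp4`, `maccs` or `pubchem`).
#' @slot simThreshold,actThreshold The (strict) similarity and activity
#'   thresholds defining the cliff quadrant.
#'
#' @seealso [sasMap()], [activityCliffs()], [acGenerators()]
#' @export
setClass("SASMap", representation(pairs = "data.frame", kind = "character",
                                  simThreshold = "numeric",
                                  actThreshold = "numeric"))

setValidity("SASMap", function(object) {
  p <- object@pairs
  if (nrow(p) > 0) {
    if (any(p$sim < 0 | p$sim > 1)) return("sim outside [0,1]")
    if (any(p$activity_diff < 0)) return("negative activity_diff")
  }
  TRUE
})

#' @describeIn CuratedSet Number of molecules.
#' @param x,object A `CuratedSet`.
#' @export
setMethod("length", "CuratedSet", function(x) nrow(x@molecules))

setMethod("show", "CuratedSet", function(object) {
  m <- object@molecules
  cat("CuratedSet with", nrow(m), "molecules\n")
  if (nrow(m) > 0) {
    tab <- table(m$activity_class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
    cat("  steroidal:", sum(m$steroidal), "| pIC50 range:",
        sprintf("%.2f..%.2f", min(m$pic50), max(m$pic50)), "\n")
  }
  lg <- object@log
  if (length(lg))
    cat("  curation:", paste(names(lg), unlist(lg), sep = "=",
        collapse = ", "), "\n")
})

setMethod("show", "ScaffoldSet", function(object) {
  s <- object@scaffolds
  cat("ScaffoldSet:", nrow(s), "scaffolds over", object@n, "molecules\n")
  if (nrow(s) > 0)
    cat("  top frequency:", s$frequency[1], "| singletons:",
        sum(s$frequency == 1), "| distinct CSKs:",
        length(unique(s$csk_smiles[!s$acyclic])), "\n")
})

setMethod("show", "SASMap", function(object) {
  p <- object@pairs
  cat("SASMap (", object@kind, "): ", nrow(p), " pairs, thresholds sim > ",
      object@simThreshold, ", diff > ", object@actThreshold, "\n", sep = "")
  if (nrow(p) > 0) {
    tab <- table(p$quadrant)
    cat("  quadrants:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
})

#' Accessors for chemlandscape containers
#'
#' `molecules()` returns the per-molecule table of a [CuratedSet-class];
#' `curationLog()` its bookkeeping counts. `scaffolds()` returns the scaffold
#' table of a [ScaffoldSet-class]; `scaffoldMembers()` its member id lists.
#' `landscapePairs()` returns the pair table of a [SASMap-class].
#'
#' @param x A container object.
#' @return A `data.frame` or list, see above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))
#' @rdname accessors
#' @export
setMethod("molecules", "CuratedSet", function(x) x@molecules)

#' @rdname accessors
#' @export
setGeneric("curationLog", function(x) standardGeneric("curationLog"))
#' @rdname accessors
#' @export
setMethod("curationLog", "CuratedSet", function(x) x@log)

#' @rdname accessors
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))
#' @rdname accessors
#' @export
setMethod("scaffolds", "ScaffoldSet", function(x) x@scaffolds)

#' @rdname accessors
#' @export
setGeneric("scaffoldMembers", function(x) standardGeneric("scaffoldMembers"))
#' @rdname accessors
#' @export
setMethod("scaffoldMembers", "ScaffoldSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("landscapePairs", function(x) standardGeneric("landscapePairs"))
#' @rdname accessors
#' @export
setMethod("landscapePairs", "SASMap", function(x) x@pairs)
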