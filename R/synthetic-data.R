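# Synthetic ChEMBL-shaped bioactivity tables with known ground truth.
#
# Molecules are built from drug-sized scaffold-family templates: each family
# has a fixed ring/linker architecture (distinct cyclic skeleton per family)
# decorated with a constant amide/sulfonamide arm, plus two variable R
# positions filled from a small substituent vocabulary. Activity-cliff pairs
# swap a terminal halogen at the end of a butyl tether -- a one-atom change
# on a large molecule, so fingerprint similarity stays above the cliff
# threshold by construction.

# Constant decorated arm shared by all templates (four rings) -- keeps the
# molecules drug-sized so a single R-group swap perturbs only a small
# fraction of fingerprint features.
.SYN_ARM <- paste0("C(=O)N(CCOCc2ccc(OCc3ccncc3)cc2)",
                   "Cc2cc(Oc3ccc(F)cc3)cc(S(=O)(=O)N3CCN(C(=O)c4cccs4)CC3)c2")

# Tail ring carrying the arm and the R2 tether; appended to each core.
.SYN_TAIL <- paste0("c1cc(OCC(F)(F)F)c(", .SYN_ARM, ")c(CCCC{R2})c1")

# Family cores. Each yields a distinct cyclic skeleton (ring sizes, fusion
# pattern, or core-to-tail linker length differ). Ordered by decreasing
# heavy-atom count of the core; activity cliffs are planted round-robin in
# the first `n_cliff_host` families (the largest molecules).
.SYN_CORES <- c(
  imidazolidinethione = "CC4(C)C(=O)N(c5ccc(C#N)c({R1})c5)C(=S)N4",
  carbazole = "c4ccc5c(c4)c6cc({R1})ccc6n5",
  acridine = "c4cc({R1})c5nc6ccccc6cc5c4",
  quinoline = "n4c5ccc({R1})cc5ccc4",
  indole = "c4ccc5c(c4)cc({R1})n5",
  etherlinked = "c4ccc({R1})cc4OC",
  biphenyl = "c4ccc({R1})cc4",
  azepane = "C4CCCC({R1})CN4"
)

# Substituent vocabulary (as SMILES branch fragments; "" is hydrogen).
.SYN_RGROUPS <- c(H = "", methyl = "C", ethyl = "CC", fluoro = "F",
                  chloro = "Cl", nitrile = "C#N", hydroxyl = "O",
                  trifluoromethyl = "C(F)(F)F", methoxy = "OC", amino = "N")

# Fill the {R1}/{R2} slots of a template; an empty substituent leaves a
# plain hydrogen (empty branches "()" are stripped afterwards).
.fillTemplate <- function(template, r1, r2) {
  s <- gsub("{R1}", r1, template, fixed = TRUE)
  s <- gsub("{R2}", r2, s, fixed = TRUE)
  gsub("()", "", s, fixed = TRUE)
}

#' Configuration for the synthetic bioactivity generator
#'
#' Defaults define the package's reference study conditions: 8 scaffold
#' families of 40 members each with family mean pIC50 spanning all four
#' activity classes (sd 0.3), 30 exact duplicate rows, 20 essential-value
#' violations (10 blanked values, 10 censored relations), and 10 planted
#' activity-cliff pairs at a pIC50 difference of 2.5.
#'
#' @param n_scaffold_families Number of scaffold families (<= 8 templates
#'   available).
#' @param members_per_family Molecules per family (cliff pairs included).
#' @param family_mean_pic50 Mean pIC50 per family; must span `[4, 9]` widely
#'   enough that all four classes occur.
#' @param pic50_sd Within-family pIC50 standard deviation.
#' @param n_duplicates Exact duplicate rows (copied molecule ids) to inject.
#' @param n_missing_value Extra rows with blanked standard value.
#' @param n_noneq_relation Extra rows with relation `">"`.
#' @param n_planted_cliffs Activity-cliff pairs planted by construction.
#' @param cliff_delta Exact pIC50 difference of planted cliff pairs (> 2).
#' @param seed Integer seed; the whole table is a deterministic function of
#'   the configuration.
#' @return A validated list of class `synth_config`.
#' @export
synthConfig <- function(n_scaffold_families = 8L,
                        members_per_family = 40L,
                        family_mean_pic50 = c(8.7, 8.3, 7.6, 7.2, 6.6, 6.2,
                                              5.4, 5.0),
                        pic50_sd = 0.3,
                        n_duplicates = 30L,
                        n_missing_value = 10L,
                        n_noneq_relation = 10L,
                        n_planted_cliffs = 10L,
                        cliff_delta = 2.5,
                        seed = 42L) {
  cfg <- list(n_scaffold_families = as.integer(n_scaffold_families),
              members_per_family = as.integer(members_per_family),
              family_mean_pic50 = as.numeric(family_mean_pic50),
              pic50_sd = as.numeric(pic50_sd),
              n_duplicates = as.integer(n_duplicates),
              n_missing_value = as.integer(n_missing_value),
              n_noneq_relation = as.integer(n_noneq_relation),
              n_planted_cliffs = as.integer(n_planted_cliffs),
              cliff_delta = as.numeric(cliff_delta),
              seed = as.integer(seed))
  if (cfg$n_scaffold_families < 1 ||
      cfg$n_scaffold_families > length(.SYN_CORES))
    stop("n_scaffold_families must be in 1..", length(.SYN_CORES))
  if (length(cfg$family_mean_pic50) != cfg$n_scaffold_families)
    stop("family_mean_pic50 must have one mean per family")
  counts <- c(cfg$members_per_family, cfg$n_duplicates, cfg$n_missing_value,
              cfg$n_noneq_relation, cfg$n_planted_cliffs)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$cliff_delta <= 2)
    stop("cliff_delta must exceed 2 (the activity-cliff threshold)")
  if (min(cfg$family_mean_pic50) > 6 || max(cfg$family_mean_pic50) < 7)
    warning("family means do not span all four activity classes")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic bioactivity table with ground truth
#'
#' Emits a ChEMBL-shaped record table ([readBioactivityTable()] layout) plus
#' a ground-truth list naming every planted artefact, so curation, scaffold
#' recovery, cliff detection and model benchmarks can be checked exactly.
#'
#' IC50 values are lognormal: per-family pIC50 is Normal(family mean, sd)
#' and the stored standard value is `10^(9 - pIC50)` nM. Cliff pairs share
#' all substituents except a terminal fluorine/chlorine swap and differ in
#' pIC50 by exactly `cliff_delta`, centred on the family mean. Duplicate
#' rows are exact copies of existing rows; violation rows are extra unique
#' molecules with either a blanked value or a `">"` relation.
#'
#' @param config A [synthConfig()] object.
#' @return List with `table` (record `data.frame`) and `truth` (list:
#'   `planted_cliff_pairs` two-column matrix of ids, `duplicate_ids`,
#'   `violation_ids`, `family_of` named vector, `family_csk_count`).
#' @examples
#' ds <- generateDataset(synthConfig(n_scaffold_families = 2,
#'   members_per_family = 6, family_mean_pic50 = c(8, 5),
#'   n_duplicates = 2, n_missing_value = 1, n_noneq_relation = 1,
#'   n_planted_cliffs = 1))
#' nrow(ds$table)
#' @export
generateDataset <- function(config = synthConfig()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nf <- config$n_scaffold_families
  cores <- .SYN_CORES[seq_len(nf)]
  vocab <- .SYN_RGROUPS
  n_combo <- length(vocab)^2

  # Per-family demand: members + a share of the violation rows.
  n_viol <- config$n_missing_value + config$n_noneq_relation
  viol_family <- if (n_viol > 0)
    rep_len(seq_len(nf), n_viol) else integer(0)
  demand <- config$members_per_family + tabulate(viol_family, nbins = nf)
  if (any(demand > n_combo))
    stop("scaffold/vocabulary exhaustion: a family needs ", max(demand),
         " unique members but only ", n_combo, " R-group combinations exist")

  # Cliffs round-robin over the largest-template families.
  n_cliff_host <- max(1L, min(nf, 4L))
  if (config$n_planted_cliffs > 0 &&
      config$members_per_family < 2 * ceiling(config$n_planted_cliffs /
                                              n_cliff_host))
    stop("not enough members per family to host the requested cliff pairs")
  cliff_family <- rep_len(seq_len(n_cliff_host), config$n_planted_cliffs)

  combos <- expand.grid(r1 = names(vocab), r2 = names(vocab),
                        stringsAsFactors = FALSE)
  halo <- c("fluoro", "chloro")

  rows <- list(); truth_family <- character(0)
  cliff_pairs <- matrix(character(0), ncol = 2)
  idc <- 0L
  nextId <- function() {
    idc <<- idc + 1L
    sprintf("SYN%05d", idc)
  }

  for (f in seq_len(nf)) {
    template <- paste0(cores[f], .SYN_TAIL)
    used <- rep(FALSE, n_combo)
    take <- function(i) used[i] <<- TRUE

    fam_rows <- list()
    # Planted cliffs first: same r1, r2 = fluoro vs chloro.
    n_cl <- sum(cliff_family == f)
    if (n_cl > 0) {
      r1_pool <- sample(names(vocab), n_cl)
      for (k in seq_len(n_cl)) {
        r1 <- r1_pool[k]
        iF <- which(combos$r1 == r1 & combos$r2 == "fluoro")
        iC <- which(combos$r1 == r1 & combos$r2 == "chloro")
        take(iF); take(iC)
        pg <- config$family_mean_pic50[f] + c(-0.5, 0.5) * config$cliff_delta
        ids <- c(nextId(), nextId())
        for (j in 1:2) {
          fam_rows[[length(fam_rows) + 1L]] <- list(
            id = ids[j],
            smiles = .fillTemplate(template, vocab[[r1]],
                                   vocab[[if (j == 1) "fluoro" else
                                          "chloro"]]),
            pic50 = pg[j])
        }
        cliff_pairs <- rbind(cliff_pairs, ids)
      }
    }
    # Remaining ordinary members: unique unused combos.
    n_rest <- config$members_per_family - 2L * n_cl
    pick <- sample(which(!used), n_rest + sum(viol_family == f))
    for (i in pick) take(i)
    rest_pic50 <- stats::rnorm(n_rest, config$family_mean_pic50[f],
                               config$pic50_sd)
    for (k in seq_len(n_rest)) {
      i <- pick[k]
      fam_rows[[length(fam_rows) + 1L]] <- list(
        id = nextId(),
        smiles = .fillTemplate(template, vocab[[combos$r1[i]]],
                               vocab[[combos$r2[i]]]),
        pic50 = rest_pic50[k])
    }
    for (r in fam_rows) {
      rows[[length(rows) + 1L]] <- r
      truth_family[r$id] <- names(cores)[f]
    }
    # Violation molecules for this family (unique, extra).
    vi <- pick[seq_len(sum(viol_family == f)) + n_rest]
    for (i in vi) {
      r <- list(id = nextId(),
                smiles = .fillTemplate(template, vocab[[combos$r1[i]]],
                                       vocab[[combos$r2[i]]]),
                pic50 = stats::rnorm(1, config$family_mean_pic50[f],
                                     config$pic50_sd),
                violation = TRUE)
      rows[[length(rows) + 1L]] <- r
      truth_family[r$id] <- names(cores)[f]
    }
  }

  df <- data.frame(
    molecule_id = vapply(rows, `[[`, "", "id"),
    smiles = vapply(rows, `[[`, "", "smiles"),
    standard_type = "IC50",
    relation = "=",
    standard_value = 10^(9 - vapply(rows, `[[`, 0, "pic50")),
    units = "nM",
    pchembl = NA_real_,
    stringsAsFactors = FALSE
  )
  is_viol <- vapply(rows, function(r) isTRUE(r$violation), logical(1))
  viol_ids <- df$molecule_id[is_viol]
  # First chunk of violations loses its value, the rest get ">".
  n_mv <- config$n_missing_value
  mv_ids <- head(viol_ids, n_mv)
  gt_ids <- setdiff(viol_ids, mv_ids)
  df$standard_value[df$molecule_id %in% mv_ids] <- NA_real_
  df$relation[df$molecule_id %in% gt_ids] <- ">"

  # Exact duplicate rows copied from clean (non-violation) rows.
  dup_src <- sample(which(!is_viol), config$n_duplicates, replace = TRUE)
  dup_ids <- df$molecule_id[dup_src]
  df <- rbind(df, df[dup_src, , drop = FALSE])

  df <- df[sample(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL

  list(table = df,
       truth = list(planted_cliff_pairs = unname(cliff_pairs),
                    duplicate_ids = dup_ids,
                    violation_ids = viol_ids,
                    family_of = truth_family,
                    n_families = nf))
}

#' Write a synthetic data set to disk
#'
#' @param ds Output of [generateDataset()].
#' @param csv Path for the record table (ChEMBL-style headers).
#' @param truth Path for the ground-truth JSON.
#' @return Invisibly, the two paths.
#' @export
writeSyntheticDataset <- function(ds, csv, truth) {
  tab <- ds$table
  names(tab) <- unlist(.DEFAULT_DIALECT[names(tab)])
  utils::write.csv(tab, csv, row.names = FALSE, na = "")
  tr <- ds$truth
  tr$planted_cliff_pairs <- apply(tr$planted_cliff_pairs, 1, identity,
                                  simplify = FALSE)
  jsonlite::write_json(tr, truth, auto_unbox = TRUE)
  invisible(c(csv = csv, truth = truth))
}
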