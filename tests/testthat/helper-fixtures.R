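# Shared fixtures, built once per test run.

# A small two-family synthetic data set exercising every planted artefact.
tinyConfig <- function(seed = 7L) {
  synthConfig(n_scaffold_families = 2L, members_per_family = 8L,
              family_mean_pic50 = c(8.2, 5.2), pic50_sd = 0.3,
              n_duplicates = 3L, n_missing_value = 2L,
              n_noneq_relation = 1L, n_planted_cliffs = 1L,
              cliff_delta = 2.5, seed = seed)
}

# A four-family configuration whose classes are all populated well enough
# for stratified splitting (used by the pipeline tests).
pipeConfig <- function(seed = 7L) {
  synthConfig(n_scaffold_families = 4L, members_per_family = 10L,
              family_mean_pic50 = c(8.6, 7.5, 6.5, 5.2), pic50_sd = 0.25,
              n_duplicates = 3L, n_missing_value = 2L,
              n_noneq_relation = 1L, n_planted_cliffs = 0L,
              cliff_delta = 2.5, seed = seed)
}

.tiny_cache <- new.env()

tinyDataset <- function() {
  if (is.null(.tiny_cache$ds)) .tiny_cache$ds <- generateDataset(tinyConfig())
  .tiny_cache$ds
}

tinyCurated <- function() {
  if (is.null(.tiny_cache$cur))
    .tiny_cache$cur <- curateBioactivities(tinyDataset()$table)
  .tiny_cache$cur
}

# Hand-written bioactivity records covering simple, easily checked
# molecules spanning all four activity classes.
toyRecords <- function() {
  data.frame(
    molecule_id = paste0("TOY", 1:8),
    smiles = c("Cc1ccccc1", "c1ccc2ncccc2c1", "Cc1ccc(F)cc1",
               "c1ccc(-c2ccccc2)cc1", "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
               "Cc1ccccc1C", "c1ccc2[nH]ccc2c1", "CCc1ccccc1"),
    standard_type = "IC50",
    relation = "=",
    standard_value = c(1, 50, 500, 5000, 50000, 2e5, 2e6, 5),
    units = "nM",
    pchembl = NA_real_,
    stringsAsFactors = FALSE)
}

toyCurated <- function() {
  if (is.null(.tiny_cache$toy))
    .tiny_cache$toy <- curateBioactivities(toyRecords())
  .tiny_cache$toy
}

# Build a CuratedSet directly from ids/smiles/pic50 (bypassing curation).
makeCurated <- function(ids, smiles, pic50) {
  cls <- classifyActivity(pic50)
  new("CuratedSet",
      molecules = data.frame(
        molecule_id = ids, smiles = smiles, pic50 = pic50,
        activity_class = cls, group = activityGroup(cls),
        steroidal = FALSE, stringsAsFactors = FALSE),
      log = list())
}

expect_same_pairs <- function(a, b) {
  key <- function(d) sort(paste(pmin(d$id_a, d$id_b),
                                pmax(d$id_a, d$id_b)))
  expect_identical(key(a), key(b))
}

pairKeys <- function(a, b) paste(pmin(a, b), pmax(a, b))
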