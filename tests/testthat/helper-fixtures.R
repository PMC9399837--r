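# Shared fixture state, built once per test run. Everything is generated
# programmatically by the synthetic-cohort module; no files ship with the
# tests.

.fx <- new.env(parent = emptyenv())

fixture_paths <- function() {
  if (is.null(.fx$paths)) {
    dir <- file.path(tempdir(), "fusetriage-fixture")
    .fx$paths <- build_paper_cohort(dir)
  }
  .fx$paths
}

fixture_annotation <- function() {
  if (is.null(.fx$ann)) {
    p <- fixture_paths()
    .fx$ann <- load_annotation(p$gtf, p$domains)
  }
  .fx$ann
}

fixture_calls <- function() {
  if (is.null(.fx$calls)) .fx$calls <- read_calls(fixture_paths()$calls, "generic")
  .fx$calls
}

fixture_samples <- function() {
  if (is.null(.fx$samples)) {
    .fx$samples <- readr::read_tsv(fixture_paths()$samples,
                                   show_col_types = FALSE)
  }
  .fx$samples
}

fixture_db <- function() {
  if (is.null(.fx$db)) .fx$db <- read_known_db(fixture_paths()$known_db)
  .fx$db
}

# pipeline-stage databases only (the literature entry enters later)
fixture_db_pipeline <- function() {
  db <- fixture_db()
  db[db$source != "literature", , drop = FALSE]
}

fixture_result <- function() {
  if (is.null(.fx$result)) {
    .fx$result <- classify_cohort(fixture_calls(), fixture_samples(),
                                  fixture_annotation(), fixture_db())
  }
  .fx$result
}

fixture_registry <- function() {
  if (is.null(.fx$registry)) .fx$registry <- fixture_fusions()
  .fx$registry
}

registry_call <- function(gene5, gene3, split = 100L, disc = 5L,
                          flags = "", sample_id = "T001") {
  reg <- fixture_registry()
  b <- reg[reg$gene5 == gene5 & reg$gene3 == gene3, ][1, ]
  tibble::tibble(sample_id = sample_id, gene5 = gene5, gene3 = gene3,
                 chrom5 = b$chrom5, pos5 = b$pos5,
                 chrom3 = b$chrom3, pos3 = b$pos3,
                 split_reads = as.integer(split),
                 discordant_mates = as.integer(disc),
                 flags = flags, caller = "archer")
}
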