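# ---------------------------------------------------------------------------
# Synthetic fixture: a mini transcript annotation plus a deterministic cohort
# reproducing the study's call-level structure, and randomized cohorts with
# planted ground truth. Breakpoints of cohort fusions are unpublished except
# for the PTPRG exon-13 / RAF1 exon-7 construct; all others are placed at
# fixture exon boundaries chosen so each fusion's documented frame and
# domain outcome holds. This encodes the study's qualitative claims, not
# invented genomic truth.
# ---------------------------------------------------------------------------

UTR5_LEN <- 200L
UTR3_LEN <- 200L
INTRON_LEN <- 1000L
GENE_SPACING <- 2e6

dom1 <- function(name, category, lo, hi) {
  tibble::tibble(name = name, category = category,
                 aa_start = as.integer(lo), aa_end = as.integer(hi))
}

# default gene body: 14 exons of 120 coding nt (560-residue protein)
default_coding <- function() rep(120L, 14L)
# breaks frame at the exon-5 boundary (cumulative 601 nt) while keeping the
# total CDS a multiple of 3
oddball_coding <- function() c(rep(120L, 4L), 121L, 119L, rep(120L, 8L))

#' Fixture gene catalogue
#'
#' The gene models backing the synthetic annotation: symbol, chromosome,
#' strand, panel gene class, per-exon coding lengths (transcription order),
#' and protein domains. 5' fusion partners live on chr1, 3' partners on
#' chr2 (so no genuine fusion can trip the proximity or read-through
#' rules), and artifact-decoy genes on chr3 with geometries that do.
#'
#' @return Tibble with list-columns `coding` and `domains`.
#' @export
fixture_genes <- function() {
  kin <- function(lo = 400, hi = 500) dom1("kinase", "kinase", lo, hi)
  ta <- function(lo = 400, hi = 500) dom1("transactivation", "transactivation", lo, hi)
  dbd3 <- function(lo = 400, hi = 500) dom1("DBD", "dna_binding", lo, hi)
  dbd5 <- function() dom1("DBD", "dna_binding", 50, 150)
  g <- function(symbol, chrom, strand, gene_class, coding = default_coding(),
                domains = NULL) {
    tibble::tibble(symbol = symbol, chrom = chrom, strand = strand,
                   gene_class = gene_class, coding = list(coding),
                   domains = list(domains %||% empty_fixture_domains()))
  }
  dplyr::bind_rows(
    # --- chr1: 5' partners -------------------------------------------------
    g("TPM3", "chr1", "+", "other"),
    g("EML4", "chr1", "+", "other"),
    g("KIF5B", "chr1", "+", "other"),
    g("SLC34A2", "chr1", "+", "other"),
    g("BRD4", "chr1", "+", "other"),
    g("WHSC1L1", "chr1", "+", "other"),
    g("ESR1", "chr1", "+", "transcription_factor", domains = dbd5()),
    g("COL1A1", "chr1", "+", "other"),
    g("EWSR1", "chr1", "-", "other"),
    g("JAZF1", "chr1", "+", "other"),
    g("SS18", "chr1", "+", "transcription_factor",
      domains = dom1("QPGY", "transactivation", 300, 387)),
    g("FUS", "chr1", "+", "other"),
    g("NAB2", "chr1", "+", "other"),
    g("HEY1", "chr1", "+", "other"),
    g("PAX3", "chr1", "+", "other"),
    g("CAPZA2", "chr1", "+", "other"),
    g("CIC", "chr1", "+", "transcription_factor", domains = dbd5()),
    g("TAF15", "chr1", "+", "other"),
    g("TFE3", "chr1", "+", "transcription_factor", domains = dbd5()),
    g("PLAGL1", "chr1", "+", "transcription_factor", domains = dbd5()),
    g("PTPRG", "chr1", "+", "other", coding = rep(120L, 16L)),
    g("FOS", "chr1", "+", "transcription_factor", domains = dbd5()),
    g("MAZ", "chr1", "+", "transcription_factor", domains = dbd5()),
    g("ZNF462", "chr1", "+", "other"),
    g("LSM1", "chr1", "+", "other"),
    g("APPL2", "chr1", "+", "other"),
    g("PDZD2", "chr1", "+", "other", coding = oddball_coding()),
    g("KIF13A", "chr1", "+", "other", coding = oddball_coding()),
    # --- chr2: 3' partners -------------------------------------------------
    g("NTRK1", "chr2", "+", "protein_kinase", domains = kin()),
    g("ALK", "chr2", "+", "protein_kinase", domains = kin()),
    g("RET", "chr2", "+", "protein_kinase", domains = kin()),
    g("ROS1", "chr2", "+", "protein_kinase", domains = kin()),
    g("NUTM1", "chr2", "+", "other"),
    g("NCOA3", "chr2", "+", "transcription_factor", domains = ta()),
    g("PDGFB", "chr2", "+", "other"),
    g("FLI1", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("PHF1", "chr2", "+", "other"),
    g("MUSK", "chr2", "+", "protein_kinase", domains = kin()),
    g("WT1", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("NRG1", "chr2", "+", "other"),
    g("SSX1", "chr2", "+", "other"),
    g("SSX2", "chr2", "+", "other"),
    g("RAF1", "chr2", "-", "protein_kinase", coding = rep(120L, 18L),
      domains = dom1("kinase", "kinase", 350, 600)),
    g("NFATC2", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("NCOA2", "chr2", "-", "transcription_factor", domains = ta()),
    g("STAT6", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("FEV", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("CREB3L2", "chr2", "+", "transcription_factor", domains = ta()),
    g("FOXO1", "chr2", "-", "transcription_factor", domains = ta()),
    g("MET", "chr2", "+", "protein_kinase", domains = kin()),
    g("DUX4", "chr2", "+", "other"),
    g("CREM", "chr2", "+", "transcription_factor", domains = ta()),
    g("NR4A3", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("ERG", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("KLF14", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("ASPSCR1", "chr2", "+", "other"),
    g("GLI1", "chr2", "+", "transcription_factor", domains = dbd3()),
    g("GREB1", "chr2", "+", "other"),
    g("AKT2", "chr2", "+", "protein_kinase", domains = kin()),
    g("PIK3CA", "chr2", "+", "protein_kinase", domains = kin()),
    # --- chr3: artifact-decoy geometries ----------------------------------
    g("SLC45A3", "chr3", "+", "other"),
    g("ELK4", "chr3", "+", "other"),
    g("FGFR3", "chr3", "+", "protein_kinase", domains = kin()),
    g("TACC3", "chr3", "-", "other"),
    g("BRAF", "chr3", "+", "protein_kinase", domains = kin()),
    g("AKAP9", "chr3", "+", "other")
  )
}

empty_fixture_domains <- function() {
  tibble::tibble(name = character(), category = character(),
                 aa_start = integer(), aa_end = integer())
}

# lay out exon genomic intervals for one gene anchored at its leftmost base
gene_model <- function(symbol, anchor, strand, coding) {
  n <- length(coding)
  len_t <- coding
  len_t[1] <- len_t[1] + UTR5_LEN
  len_t[n] <- len_t[n] + 3L + UTR3_LEN          # stop codon + 3'UTR
  # transcript-order layout on a forward axis starting at `anchor`
  starts <- anchor + cumsum(c(0L, len_t[-n] + INTRON_LEN))
  ends <- starts + len_t - 1L
  cstart <- starts
  cend <- ends
  cstart[1] <- starts[1] + UTR5_LEN
  cend[n] <- starts[n] + (coding[n] + if (n == 1) UTR5_LEN else 0L) - 1L
  if (n == 1) cstart[1] <- starts[1] + UTR5_LEN
  span <- ends[n] - anchor + 1L
  if (strand == "-") {
    refl <- function(x) anchor + span - 1L - (x - anchor)
    tmp_s <- refl(ends); tmp_e <- refl(starts)
    tmp_cs <- refl(cend); tmp_ce <- refl(cstart)
    starts <- tmp_s; ends <- tmp_e; cstart <- tmp_cs; cend <- tmp_ce
  }
  tibble::tibble(symbol = symbol, exon_number = seq_len(n),
                 g_start = starts, g_end = ends,
                 coding_start = cstart, coding_end = cend,
                 coding_len = coding,
                 cum_coding_before = cumsum(c(0L, coding[-n])))
}

# full fixture model: per-gene spans + per-exon coordinates
fixture_models <- function(spec = fixture_genes()) {
  # chr3 decoys get bespoke anchors to realise artifact geometries
  anchors <- list()
  counters <- c(chr1 = 0L, chr2 = 0L)
  exons <- list()
  genes <- list()
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    chrom <- row$chrom
    if (chrom %in% c("chr1", "chr2")) {
      anchor <- as.integer(1e6 + counters[[chrom]] * GENE_SPACING)
      counters[[chrom]] <- counters[[chrom]] + 1L
    } else {
      anchor <- switch(row$symbol,
                       SLC45A3 = 1000000L,
                       ELK4 = 1040000L,      # ~20 kb downstream of SLC45A3
                       FGFR3 = 5000000L,
                       TACC3 = 5090000L,     # ~70 kb downstream of FGFR3
                       BRAF = 10000000L,
                       AKAP9 = 20000000L)
    }
    ex <- gene_model(row$symbol, anchor, row$strand, row$coding[[1]])
    exons[[i]] <- ex
    genes[[i]] <- tibble::tibble(symbol = row$symbol, chrom = chrom,
                                 strand = row$strand,
                                 gene_class = row$gene_class,
                                 start = min(ex$g_start), end = max(ex$g_end),
                                 protein_len = sum(row$coding[[1]]) %/% 3L)
  }
  if (nrow(spec) == 0) {
    genes <- list(tibble::tibble(symbol = character(), chrom = character(),
                                 strand = character(), gene_class = character(),
                                 start = integer(), end = integer(),
                                 protein_len = integer()))
    exons <- list(tibble::tibble(symbol = character(), exon_number = integer(),
                                 g_start = integer(), g_end = integer(),
                                 coding_start = integer(),
                                 coding_end = integer(),
                                 coding_len = integer(),
                                 cum_coding_before = integer()))
  }
  list(genes = dplyr::bind_rows(genes), exons = dplyr::bind_rows(exons),
       spec = spec)
}

# genomic position of a breakpoint described relative to the gene model;
# `at` is one of exon_end / exon_start / utr5 / intron_after
fixture_breakpoint <- function(models, symbol, at, exon = NA, offset = 0L) {
  gi <- models$genes[models$genes$symbol == symbol, ]
  ex <- models$exons[models$exons$symbol == symbol, ]
  minus <- gi$strand == "-"
  pos <- switch(at,
    exon_end = if (minus) ex$g_start[exon] else ex$g_end[exon],
    exon_start = if (minus) ex$g_end[exon] else ex$g_start[exon],
    utr5 = if (minus) ex$g_end[1] - offset else ex$g_start[1] + offset,
    intron_after = if (minus) ex$g_start[exon] - offset else ex$g_end[exon] + offset,
    stop_fus(paste("unknown breakpoint anchor:", at), "spec_error"))
  as.integer(pos)
}

# registry of every fusion the fixture realises: breakpoint placement and
# the documented frame/class outcome each placement was built to satisfy
fixture_fusion_registry <- function() {
  r <- function(gene5, gene3, at5 = "exon_end", exon5 = 7L, off5 = 0L,
                at3 = "exon_start", exon3 = 4L, off3 = 0L,
                frame = "in_frame", outcome = "known") {
    tibble::tibble(gene5 = gene5, gene3 = gene3, at5 = at5, exon5 = exon5,
                   off5 = off5, at3 = at3, exon3 = exon3, off3 = off3,
                   frame = frame, outcome = outcome)
  }
  dplyr::bind_rows(
    # known fusions (DB sources quiver/chimerdb/oncokb)
    r("TPM3", "NTRK1"), r("EML4", "ALK"), r("KIF5B", "RET"),
    r("SLC34A2", "ROS1"), r("BRD4", "NUTM1"), r("WHSC1L1", "NUTM1"),
    r("COL1A1", "PDGFB"), r("EWSR1", "FLI1"), r("JAZF1", "PHF1"),
    r("EWSR1", "WT1"),
    r("SS18", "SSX1", exon5 = 12L), r("SS18", "SSX2", exon5 = 12L),
    r("FUS", "NFATC2"), r("NAB2", "STAT6"), r("HEY1", "NCOA2"),
    r("EWSR1", "FEV"), r("FUS", "CREB3L2"), r("PAX3", "FOXO1"),
    r("CAPZA2", "MET"), r("CIC", "DUX4"), r("EWSR1", "CREM"),
    r("EWSR1", "NR4A3"), r("FUS", "ERG"), r("TAF15", "NR4A3"),
    r("TFE3", "ASPSCR1"),
    # previously reported in the literature only
    r("ESR1", "NCOA3", outcome = "literature_known"),
    # novel oncogenic candidates
    r("PLAGL1", "FOXO1", outcome = "novel"),
    r("PTPRG", "RAF1", exon5 = 13L, exon3 = 7L, outcome = "novel"),
    r("FOS", "GLI1", outcome = "novel"),
    r("MAZ", "NCOA2", outcome = "novel"),
    r("SS18", "KLF14", exon5 = 12L, outcome = "novel"),
    r("ZNF462", "MUSK", at5 = "utr5", exon5 = NA, off5 = 100L,
      at3 = "utr5", exon3 = NA, off3 = 0L,
      frame = "promoter_swap", outcome = "novel"),
    r("LSM1", "NRG1", outcome = "novel"),
    r("APPL2", "RAF1", exon3 = 7L, outcome = "novel"),
    # passengers
    r("SS18", "GREB1", exon5 = 2L, outcome = "passenger_domain"),
    r("PDZD2", "AKT2", at5 = "intron_after", exon5 = 5L, off5 = 500L,
      frame = "out_of_frame", outcome = "passenger_frame_support"),
    r("KIF13A", "PIK3CA", exon5 = 5L,
      frame = "out_of_frame", outcome = "passenger_frame"),
    # artifact decoys
    r("SLC45A3", "ELK4", outcome = "artifact_readthrough"),
    r("FGFR3", "TACC3", outcome = "artifact_proximity"),
    r("BRAF", "AKAP9", outcome = "artifact_mispriming")
  )
}

resolve_fusion_breakpoints <- function(models, registry = fixture_fusion_registry()) {
  registry$chrom5 <- models$genes$chrom[match(registry$gene5, models$genes$symbol)]
  registry$chrom3 <- models$genes$chrom[match(registry$gene3, models$genes$symbol)]
  registry$pos5 <- vapply(seq_len(nrow(registry)), function(i) {
    fixture_breakpoint(models, registry$gene5[i], registry$at5[i],
                       registry$exon5[i], registry$off5[i])
  }, integer(1))
  registry$pos3 <- vapply(seq_len(nrow(registry)), function(i) {
    fixture_breakpoint(models, registry$gene3[i], registry$at3[i],
                       registry$exon3[i], registry$off3[i])
  }, integer(1))
  registry
}

#' Fixture fusion table with resolved breakpoints
#'
#' The catalogue of fusions the synthetic annotation realises, with genomic
#' breakpoints and the frame/outcome each placement was constructed to
#' satisfy.
#'
#' @return Tibble with gene pair, breakpoint placement, `chrom5/pos5`,
#'   `chrom3/pos3`, expected `frame`, and `outcome` label.
#' @export
fixture_fusions <- function() {
  resolve_fusion_breakpoints(fixture_models())
}

gtf_attr <- function(...) {
  kv <- list(...)
  paste(vapply(names(kv), function(k) sprintf('%s "%s";', k, kv[[k]]),
               character(1)), collapse = " ")
}

write_fixture_gtf <- function(models, path) {
  lines <- character()
  for (i in seq_len(nrow(models$genes))) {
    gi <- models$genes[i, ]
    ex <- models$exons[models$exons$symbol == gi$symbol, ]
    gid <- paste0(gi$symbol, "_g")
    tid <- paste0(gi$symbol, "_t1")
    lines <- c(lines, sprintf(
      "%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\t%s",
      gi$chrom, gi$start, gi$end, gi$strand,
      gtf_attr(gene_id = gid, gene_name = gi$symbol,
               gene_class = gi$gene_class)))
    lines <- c(lines, sprintf(
      "%s\tfixture\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
      gi$chrom, gi$start, gi$end, gi$strand,
      gtf_attr(gene_id = gid, gene_name = gi$symbol, transcript_id = tid)))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tfixture\texon\t%d\t%d\t.\t%s\t.\t%s",
        gi$chrom, ex$g_start[j], ex$g_end[j], gi$strand,
        gtf_attr(gene_id = gid, gene_name = gi$symbol, transcript_id = tid,
                 exon_number = ex$exon_number[j])))
      if (ex$coding_len[j] > 0) {
        lines <- c(lines, sprintf(
          "%s\tfixture\tCDS\t%d\t%d\t.\t%s\t0\t%s",
          gi$chrom, ex$coding_start[j], ex$coding_end[j], gi$strand,
          gtf_attr(gene_id = gid, gene_name = gi$symbol, transcript_id = tid,
                   exon_number = ex$exon_number[j])))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_fixture_domains <- function(spec, path) {
  rows <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    d <- spec$domains[[i]]
    if (nrow(d) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(gene = rep(spec$symbol[i], nrow(d))), d)
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(gene = character(), name = character(),
                           category = character(), aa_start = integer(),
                           aa_end = integer())
  }
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

# independent base-by-base walk over the model's coding positions, used to
# verify at build time that each placed fusion realises its intended frame.
# A coding base is transcript-upstream of a position iff it is genomically
# at or below it on the plus strand (at or above on the minus strand), so
# intronic breakpoints need no special casing.
codon_walk_offsets <- function(models, gene5, pos5, gene3, pos3) {
  coding_bases <- function(symbol) {
    ex <- models$exons[models$exons$symbol == symbol, ]
    unlist(lapply(seq_len(nrow(ex)), function(j) {
      if (ex$coding_len[j] == 0) return(integer())
      seq.int(ex$coding_start[j], ex$coding_end[j])
    }))
  }
  is_minus <- function(symbol) {
    models$genes$strand[models$genes$symbol == symbol] == "-"
  }
  v5 <- coding_bases(gene5)
  v3 <- coding_bases(gene3)
  c5 <- if (is_minus(gene5)) sum(v5 >= pos5) else sum(v5 <= pos5)
  c3 <- if (is_minus(gene3)) sum(v3 > pos3) else sum(v3 < pos3)
  list(c5 = c5, c3 = c3)
}

verify_fixture <- function(models, registry) {
  for (i in seq_len(nrow(registry))) {
    row <- registry[i, ]
    if (is.na(row$pos5) || grepl("^artifact", row$outcome)) next
    off <- codon_walk_offsets(models, row$gene5, row$pos5, row$gene3, row$pos3)
    observed <- if (row$frame == "promoter_swap") {
      if (off$c5 == 0 && off$c3 == 0) "promoter_swap" else "violated"
    } else if ((off$c5 - off$c3) %% 3 == 0) "in_frame" else "out_of_frame"
    if (observed != row$frame) {
      stop_fus(sprintf("fixture self-check failed for %s-%s: wanted %s, walk gives %s (c5=%d c3=%d)",
                       row$gene5, row$gene3, row$frame, observed,
                       off$c5, off$c3),
               "spec_error")
    }
  }
  invisible(TRUE)
}

#' Build the synthetic transcript annotation
#'
#' Writes `fixture.gtf` and `domains.tsv` for the fixture gene catalogue and
#' verifies, by an independent base-by-base codon walk, that every placed
#' fusion realises its intended reading-frame outcome.
#'
#' @param dir Output directory (created if needed).
#' @param spec Gene catalogue, as produced by [fixture_genes()].
#' @param verify Run the build-time codon-walk self-check (default TRUE).
#' @return Invisibly, a list with `gtf`, `domains` (paths), `models`
#'   (gene/exon coordinate tables), and `fusions` (resolved registry).
#' @export
build_fixture_annotation <- function(dir, spec = fixture_genes(),
                                     verify = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  models <- fixture_models(spec)
  registry <- fixture_fusion_registry()
  registry <- registry[registry$gene5 %in% spec$symbol &
                         registry$gene3 %in% spec$symbol, , drop = FALSE]
  registry <- resolve_fusion_breakpoints(models, registry)
  if (verify) verify_fixture(models, registry)
  gtf <- file.path(dir, "fixture.gtf")
  domains <- file.path(dir, "domains.tsv")
  write_fixture_gtf(models, gtf)
  write_fixture_domains(spec, domains)
  invisible(list(gtf = gtf, domains = domains, models = models,
                 fusions = registry))
}

group_labels <- function() {
  c("Adenocarcinoma",
    "Carcinoma, a known lineage",
    "Carcinoma, a known fusion",
    "Carcinoma, unknown lineage; undifferentiated carcinoma",
    "Uterine malignancy",
    "Sarcoma, unknown lineage; undifferentiated sarcoma",
    "Sarcoma, known fusion",
    "Sarcoma, myogenic lineage without known fusion",
    "Sarcoma, fibroblastic lineage without known fusion",
    "Sarcoma, neurogenic lineage without known fusion",
    "Sarcoma, chondroid or bone lineage without known fusion",
    "Sarcoma, lipogenic lineage without known fusion",
    "Sarcoma, vascular or perivascular lineage without known fusion",
    "Other malignancy")
}

cohort_group_sizes <- function() c(9L, 3L, 4L, 3L, 13L, 56L, 42L, 9L, 11L, 5L, 4L, 1L, 1L, 4L)

# per-group fusion placements of the deterministic cohort: group, pair,
# number of samples
cohort_placements <- function() {
  p <- function(group, gene5, gene3, n) {
    tibble::tibble(group = group, gene5 = gene5, gene3 = gene3, n = n)
  }
  dplyr::bind_rows(
    p(1, "TPM3", "NTRK1", 2), p(1, "EML4", "ALK", 1), p(1, "KIF5B", "RET", 1),
    p(1, "SLC34A2", "ROS1", 1),
    p(3, "BRD4", "NUTM1", 2), p(3, "WHSC1L1", "NUTM1", 1),
    p(5, "ESR1", "NCOA3", 2),
    p(6, "COL1A1", "PDGFB", 2), p(6, "EWSR1", "FLI1", 2),
    p(6, "JAZF1", "PHF1", 1), p(6, "BRD4", "NUTM1", 1),
    p(6, "ZNF462", "MUSK", 1), p(6, "EWSR1", "WT1", 1),
    p(6, "LSM1", "NRG1", 1), p(6, "SS18", "SSX2", 1),
    p(6, "APPL2", "RAF1", 1), p(6, "FUS", "NFATC2", 1),
    p(6, "MAZ", "NCOA2", 1),
    p(7, "SS18", "SSX1", 6), p(7, "COL1A1", "PDGFB", 4),
    p(7, "NAB2", "STAT6", 4), p(7, "EWSR1", "FLI1", 3),
    p(7, "HEY1", "NCOA2", 3), p(7, "EWSR1", "FEV", 2),
    p(7, "FUS", "CREB3L2", 2), p(7, "PAX3", "FOXO1", 2),
    p(7, "SS18", "SSX2", 2), p(7, "CAPZA2", "MET", 1),
    p(7, "CIC", "DUX4", 1), p(7, "EWSR1", "CREM", 1),
    p(7, "EWSR1", "NR4A3", 1), p(7, "EWSR1", "WT1", 1),
    p(7, "FUS", "ERG", 1), p(7, "SS18", "KLF14", 1),
    p(7, "TAF15", "NR4A3", 1), p(7, "TFE3", "ASPSCR1", 1),
    p(9, "COL1A1", "PDGFB", 2), p(9, "BRD4", "NUTM1", 1),
    p(10, "PTPRG", "RAF1", 1), p(10, "SS18", "SSX2", 1),
    p(10, "FOS", "GLI1", 1),
    p(11, "HEY1", "NCOA2", 1),
    p(14, "PLAGL1", "FOXO1", 1))
}

# named case ids and supports documented for individual samples
cohort_named_cases <- function() {
  tibble::tibble(
    sample_id = c("AF0033", "AF0062", "AF0111", "AF0112", "AF0140", "AF0171",
                  "AF0197", "AF0216", "AF0052", "AF0065", "AF0154"),
    group = c(14L, 10L, 10L, 6L, 7L, 6L, 6L, 6L, 7L, 3L, 7L),
    gene5 = c("PLAGL1", "PTPRG", "FOS", "MAZ", "SS18", "ZNF462", "LSM1",
              "APPL2", "SS18", "BRD4", "CIC"),
    gene3 = c("FOXO1", "RAF1", "GLI1", "NCOA2", "KLF14", "MUSK", "NRG1",
              "RAF1", "SSX1", "NUTM1", "DUX4"),
    split_reads = c(175L, 87L, 110L, 97L, 151L, 37L, 11L, 87L,
                    NA, NA, NA),
    discordant_mates = c(0L, 5L, 0L, 0L, 21L, 3L, 0L, 5L, NA, NA, NA))
}

cohort_passenger_cases <- function() {
  tibble::tibble(
    sample_id = c("AF0050", "AF0162", "AF0201"),
    group = c(5L, 4L, 2L),
    gene5 = c("SS18", "PDZD2", "KIF13A"),
    gene3 = c("GREB1", "AKT2", "PIK3CA"),
    split_reads = c(45L, 7L, 34L),
    discordant_mates = c(2L, 0L, 2L))
}

known_db_table <- function() {
  reg <- fixture_fusion_registry()
  known <- reg[reg$outcome == "known", c("gene5", "gene3")]
  src <- rep(c("quiver", "chimerdb", "oncokb"), length.out = nrow(known))
  dplyr::bind_rows(
    tibble::tibble(gene5 = known$gene5, gene3 = known$gene3, source = src),
    tibble::tibble(gene5 = "ESR1", gene3 = "NCOA3", source = "literature"))
}

#' Build the deterministic study-cohort fixture
#'
#' Writes, into `dir`: the fixture annotation (`fixture.gtf`,
#' `domains.tsv`), `calls.tsv` (generic dialect), `samples.tsv`
#' (`sample_id, group_id, group_label, diagnosis, unique_reads`), and
#' `known_db.tsv`. The cohort has 165 samples across 14 diagnostic groups,
#' 5 sequencing-failure samples (fewer than 10 unique reads), one fusion
#' call per fusion-positive sample matching the per-group inventory, the
#' documented split/discordant supports for the novel fusions, the three
#' passenger cases, and three artifact-decoy calls (read-through geometry,
#' breakpoint proximity, mispriming flag) in otherwise negative samples.
#' Support counts not documented per sample are drawn uniformly from
#' 20-200 split reads / 0-30 discordant mates under a fixed internal seed,
#' so repeated builds are byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of file paths (`gtf`, `domains`, `calls`,
#'   `samples`, `known_db`).
#' @export
build_paper_cohort <- function(dir) {
  fx <- build_fixture_annotation(dir)
  reg <- fx$fusions
  bp <- function(gene5, gene3) {
    reg[reg$gene5 == gene5 & reg$gene3 == gene3, ][1, ]
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(20220816)

  sizes <- cohort_group_sizes()
  labels <- group_labels()
  named <- cohort_named_cases()
  passengers <- cohort_passenger_cases()

  samples <- list(); calls <- list()
  next_id <- 500L
  new_id <- function() {
    id <- sprintf("AF%04d", next_id)
    next_id <<- next_id + 1L
    id
  }
  add_call <- function(sample_id, gene5, gene3, split, disc, flags = "") {
    b <- bp(gene5, gene3)
    calls[[length(calls) + 1L]] <<- tibble::tibble(
      sample_id = sample_id, gene5 = gene5, gene3 = gene3,
      chrom5 = b$chrom5, pos5 = b$pos5, chrom3 = b$chrom3, pos3 = b$pos3,
      split_reads = as.integer(split), discordant_mates = as.integer(disc),
      flags = flags, caller = "archer")
  }
  add_sample <- function(sample_id, group, unique_reads = 5000L,
                         diagnosis = NA_character_) {
    samples[[length(samples) + 1L]] <<- tibble::tibble(
      sample_id = sample_id, group_id = group,
      group_label = labels[group],
      diagnosis = diagnosis %||% labels[group], unique_reads = unique_reads)
  }

  for (g in seq_along(sizes)) {
    placed <- cohort_placements()
    placed <- placed[placed$group == g, , drop = FALSE]
    used <- 0L
    # fusion-positive samples of this group
    for (j in seq_len(nrow(placed))) {
      for (k in seq_len(placed$n[j])) {
        hit <- which(named$group == g & named$gene5 == placed$gene5[j] &
                       named$gene3 == placed$gene3[j])
        if (length(hit)) {
          row <- named[hit[1], ]
          named <- named[-hit[1], ]
          sid <- row$sample_id
          split <- row$split_reads
          disc <- row$discordant_mates
        } else {
          sid <- new_id()
          split <- NA_integer_; disc <- NA_integer_
        }
        if (is.na(split)) {
          split <- sample(20:200, 1)
          disc <- sample(0:30, 1)
        }
        add_sample(sid, g)
        add_call(sid, placed$gene5[j], placed$gene3[j], split, disc)
        used <- used + 1L
      }
    }
    # passenger cases assigned to this group
    pg <- passengers[passengers$group == g, , drop = FALSE]
    for (j in seq_len(nrow(pg))) {
      add_sample(pg$sample_id[j], g)
      add_call(pg$sample_id[j], pg$gene5[j], pg$gene3[j],
               pg$split_reads[j], pg$discordant_mates[j])
      used <- used + 1L
    }
    # sequencing failures and artifact decoys live among group-6 negatives
    if (g == 6L) {
      fail_reads <- c(3L, 5L, 7L, 8L, 9L)
      for (u in fail_reads) {
        add_sample(new_id(), g, unique_reads = u)
        used <- used + 1L
      }
      decoys <- list(c("SLC45A3", "ELK4", ""), c("FGFR3", "TACC3", ""),
                     c("BRAF", "AKAP9", "mispriming"))
      for (d in decoys) {
        sid <- new_id()
        add_sample(sid, g)
        add_call(sid, d[1], d[2], sample(20:200, 1), sample(0:30, 1),
                 flags = d[3])
        used <- used + 1L
      }
    }
    # fusion-negative remainder
    while (used < sizes[g]) {
      add_sample(new_id(), g)
      used <- used + 1L
    }
  }

  samples <- dplyr::bind_rows(samples)
  calls <- dplyr::bind_rows(calls)
  stopifnot(nrow(samples) == sum(sizes))

  paths <- list(gtf = fx$gtf, domains = fx$domains,
                calls = file.path(dir, "calls.tsv"),
                samples = file.path(dir, "samples.tsv"),
                known_db = file.path(dir, "known_db.tsv"))
  write_calls(calls, paths$calls)
  readr::write_tsv(samples, paths$samples, progress = FALSE)
  readr::write_tsv(known_db_table(), paths$known_db, progress = FALSE)
  invisible(paths)
}

default_class_mix <- function() {
  c(artifact_readthrough = 0.08, artifact_proximity = 0.08,
    passenger_low_support = 0.16, passenger_frame = 0.16,
    passenger_domain = 0.12, known = 0.24, novel = 0.16)
}

planted_to_class <- function(subtype) {
  dplyr::case_match(subtype,
                    c("artifact_readthrough", "artifact_proximity",
                      "artifact_mispriming") ~ "artifact",
                    c("passenger_low_support", "passenger_frame",
                      "passenger_domain") ~ "passenger",
                    "known" ~ "known_oncogenic",
                    "novel" ~ "novel_candidate")
}

#' Simulate a randomized cohort with planted ground truth
#'
#' Each simulated sample carries one fusion call whose attributes
#' (gene pair, breakpoints, support, flags) are sampled to realise a
#' planted class drawn from `class_mix`. The triage cascade is a
#' deterministic function of these attributes, so classification must
#' recover the planted class exactly. Identical `seed` and spec yield
#' byte-identical files.
#'
#' @param dir Output directory.
#' @param n_samples Number of samples (one call each).
#' @param class_mix Named numeric vector of class proportions summing to 1
#'   (names as in `default_class_mix()`).
#' @param seed Integer RNG seed.
#' @return Invisibly, paths to `calls.tsv`, `samples.tsv`, `truth.tsv`
#'   (plus the annotation files).
#' @export
simulate_cohort <- function(dir, n_samples = 200,
                            class_mix = default_class_mix(), seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop_fus("class mix proportions must sum to 1", "spec_error")
  }
  if (n_samples < 1) stop_fus("n_samples must be >= 1", "spec_error")
  fx <- build_fixture_annotation(dir)
  reg <- fx$fusions

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  pick <- function(outcomes) {
    cand <- reg[reg$outcome %in% outcomes, , drop = FALSE]
    cand[sample(nrow(cand), 1), ]
  }
  subtypes <- sample(names(class_mix), n_samples, replace = TRUE,
                     prob = class_mix)
  rows <- purrr::map_dfr(seq_len(n_samples), function(i) {
    sub <- subtypes[i]
    flags <- ""
    if (sub == "artifact_readthrough") {
      b <- reg[reg$outcome == "artifact_readthrough", ][1, ]
      split <- sample(20:200, 1); disc <- sample(0:30, 1)
    } else if (sub == "artifact_proximity") {
      b <- reg[reg$outcome == "artifact_proximity", ][1, ]
      split <- sample(20:200, 1); disc <- sample(0:30, 1)
    } else if (sub == "passenger_low_support") {
      b <- pick(c("known", "novel", "literature_known"))
      split <- sample(0:9, 1); disc <- 0L
    } else if (sub == "passenger_frame") {
      b <- pick(c("passenger_frame", "passenger_frame_support"))
      split <- sample(10:200, 1); disc <- sample(0:30, 1)
    } else if (sub == "passenger_domain") {
      b <- reg[reg$outcome == "passenger_domain", ][1, ]
      split <- sample(10:200, 1); disc <- sample(0:30, 1)
    } else if (sub == "known") {
      b <- pick(c("known", "literature_known"))
      split <- sample(20:200, 1); disc <- sample(0:30, 1)
    } else {
      b <- pick("novel")
      split <- sample(10:200, 1); disc <- sample(0:30, 1)
    }
    tibble::tibble(sample_id = sprintf("S%04d", i),
                   gene5 = b$gene5, gene3 = b$gene3,
                   chrom5 = b$chrom5, pos5 = b$pos5,
                   chrom3 = b$chrom3, pos3 = b$pos3,
                   split_reads = as.integer(split),
                   discordant_mates = as.integer(disc),
                   flags = flags, caller = "archer",
                   planted_subtype = sub)
  })

  samples <- tibble::tibble(
    sample_id = rows$sample_id,
    group_id = rep_len(1:14, n_samples),
    group_label = group_labels()[rep_len(1:14, n_samples)],
    diagnosis = NA_character_,
    unique_reads = 5000L)
  truth <- tibble::tibble(sample_id = rows$sample_id,
                          gene5 = rows$gene5, gene3 = rows$gene3,
                          planted_subtype = rows$planted_subtype,
                          planted_class = planted_to_class(rows$planted_subtype))

  paths <- list(gtf = fx$gtf, domains = fx$domains,
                calls = file.path(dir, "calls.tsv"),
                samples = file.path(dir, "samples.tsv"),
                known_db = file.path(dir, "known_db.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_calls(rows[, !(names(rows) %in% "planted_subtype")], paths$calls)
  readr::write_tsv(samples, paths$samples, progress = FALSE)
  readr::write_tsv(known_db_table(), paths$known_db, progress = FALSE)
  readr::write_tsv(truth, paths$truth, progress = FALSE)
  invisible(paths)
}

#' Simulate raw junction reads with molecular barcodes
#'
#' Generates `n_raw` junction-spanning reads over exactly `n_unique`
#' distinct molecular barcodes, so that [unique_fragment_count()] on the
#' result returns `n_unique`.
#'
#' @param sample_id,call_key Identifiers stamped onto the rows.
#' @param n_raw Number of raw reads (>= `n_unique`).
#' @param n_unique Number of distinct barcodes (>= 1).
#' @param seed Integer RNG seed.
#' @return Tibble with columns
#'   `sample_id, call_key, read_id, umi, junction_spanning`.
#' @export
simulate_reads <- function(sample_id, call_key, n_raw, n_unique, seed = 1) {
  if (n_unique < 1 || n_unique > n_raw) {
    stop_fus("need 1 <= n_unique <= n_raw", "spec_error")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  umis <- sprintf("%s-UMI%05d", call_key, sample(99999, n_unique))
  assignment <- c(seq_len(n_unique),
                  sample(n_unique, n_raw - n_unique, replace = TRUE))
  tibble::tibble(sample_id = sample_id, call_key = call_key,
                 read_id = sprintf("%s-R%05d", call_key, seq_len(n_raw)),
                 umi = umis[assignment],
                 junction_spanning = TRUE)
}
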