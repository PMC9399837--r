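test_that("fixture annotation loads with one canonical transcript per gene", {
  ann <- fixture_annotation()
  expect_gte(nrow(ann$genes), 40)
  expect_equal(length(ann$canonical), nrow(ann$genes))
  expect_false(anyDuplicated(ann$genes$symbol) > 0)
  expect_true(all(ann$genes$start <= ann$genes$end))
  expect_true(all(ann$genes$strand %in% c("+", "-")))
  # every domain resolves to a gene and has a valid residue interval
  expect_true(all(ann$domains$gene_symbol %in% ann$genes$symbol))
  expect_true(all(ann$domains$aa_start >= 1 &
                    ann$domains$aa_start <= ann$domains$aa_end))
})

test_that("GTF loading is insensitive to record order", {
  p <- fixture_paths()
  lines <- readLines(p$gtf)
  set.seed(42)
  shuffled <- file.path(tempdir(), "shuffled.gtf")
  writeLines(sample(lines), shuffled)
  ann1 <- fixture_annotation()
  ann2 <- load_annotation(shuffled, p$domains)
  ord <- function(x) dplyr::arrange(x$exons, transcript_id, exon_number)
  expect_equal(ord(ann2), ord(ann1))
  expect_equal(sort(ann2$canonical), sort(ann1$canonical))
})

test_that("domain table rows attach to their gene", {
  ann <- fixture_annotation()
  qpgy <- ann$domains[ann$domains$gene_symbol == "SS18", ]
  expect_equal(qpgy$name, "QPGY")
  expect_equal(qpgy$category, "transactivation")
})

test_that("malformed inputs raise informative errors", {
  bad_gtf <- file.path(tempdir(), "bad.gtf")
  writeLines(c("chr1\tx\tgene\t1\t10\t.\t+\t.\tgene_id \"g\";",
               "chr1\tx\tgene\t1\t10"), bad_gtf)
  expect_error(load_annotation(bad_gtf), "line 2")

  bad_dom <- file.path(tempdir(), "bad_domains.tsv")
  readr::write_tsv(tibble::tibble(gene = "NOSUCHGENE", name = "kinase",
                                  category = "kinase", aa_start = 1,
                                  aa_end = 10), bad_dom)
  expect_error(load_annotation(fixture_paths()$gtf, bad_dom), "NOSUCHGENE")
})

test_that("coding offsets at exon boundaries match the base-by-base oracle", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  for (sym in names(models)) {
    b <- oracle_exon_boundaries(models[[sym]])
    for (pos in unique(c(b$starts, b$ends))) {
      for (side in c("five_prime", "three_prime")) {
        got <- coding_offset(ann, sym, pos, side)$n_coding_nt
        want <- oracle_offset(models[[sym]], pos, side)
        expect_equal(got, want,
                     info = sprintf("%s %s pos=%d", sym, side, pos))
      }
    }
  }
})

test_that("boundary cases: first coding exon sum and CDS-start edge", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  m <- models[["TPM3"]]
  # last base of the first exon (120 coding nt after the 5'UTR)
  b <- oracle_exon_boundaries(m)
  expect_equal(coding_offset(ann, "TPM3", b$ends[1], "five_prime")$n_coding_nt,
               120L)
  # base immediately before the CDS start, three_prime side -> 0 and UTR
  cds_start <- min(m$start[m$type == "CDS"])
  off <- coding_offset(ann, "TPM3", cds_start - 1L, "three_prime")
  expect_equal(off$n_coding_nt, 0L)
  expect_true(off$in_utr)
  # PTPRG breakpoint at end of exon 13: sum of coding lengths of exons 1-13
  ptprg_bp <- fixture_registry()
  ptprg_bp <- ptprg_bp[ptprg_bp$gene5 == "PTPRG", ]$pos5
  expect_equal(coding_offset(ann, "PTPRG", ptprg_bp, "five_prime")$n_coding_nt,
               13L * 120L)
  expect_equal(oracle_offset(models[["PTPRG"]], ptprg_bp, "five_prime"),
               13L * 120L)
})

test_that("five-prime offsets are monotone along the transcript", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  for (sym in c("TPM3", "RAF1")) {   # plus- and minus-strand gene
    b <- oracle_exon_boundaries(models[[sym]])
    boundary_seq <- as.vector(rbind(b$starts, b$ends))  # transcript order
    vals <- vapply(boundary_seq, function(p) {
      coding_offset(ann, sym, p, "five_prime")$n_coding_nt
    }, integer(1))
    expect_true(all(diff(vals) >= 0), info = sym)
  }
})

test_that("offset at the CDS end equals three times the protein length", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  for (sym in c("TPM3", "RAF1", "PTPRG", "SS18")) {
    m <- models[[sym]]
    minus <- m$strand[1] == "-"
    cds_end <- if (minus) min(m$start[m$type == "CDS"]) else max(m$end[m$type == "CDS"])
    tx_id <- ann$canonical[[sym]]
    plen <- ann$transcripts$cds_len[ann$transcripts$transcript_id == tx_id] / 3
    expect_equal(coding_offset(ann, sym, cds_end, "five_prime")$n_coding_nt,
                 as.integer(3 * plen), info = sym)
  }
})

test_that("intronic breakpoints snap to the retained exon boundary", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  b <- oracle_exon_boundaries(models[["TPM3"]])  # plus strand
  mid_intron <- b$ends[2] + 500L
  off5 <- coding_offset(ann, "TPM3", mid_intron, "five_prime")
  expect_true(off5$in_intron)
  expect_equal(off5$n_coding_nt,
               coding_offset(ann, "TPM3", b$ends[2], "five_prime")$n_coding_nt)
  off3 <- coding_offset(ann, "TPM3", mid_intron, "three_prime")
  expect_true(off3$in_intron)
  expect_equal(off3$n_coding_nt,
               coding_offset(ann, "TPM3", b$starts[3], "three_prime")$n_coding_nt)
  # same check on a minus-strand gene
  bm <- oracle_exon_boundaries(models[["RAF1"]])
  mid_intron_m <- bm$ends[2] - 500L
  offm <- coding_offset(ann, "RAF1", mid_intron_m, "five_prime")
  expect_true(offm$in_intron)
  expect_equal(offm$n_coding_nt,
               coding_offset(ann, "RAF1", bm$ends[2], "five_prime")$n_coding_nt)
})

test_that("positions outside a gene span and unknown symbols are errors", {
  ann <- fixture_annotation()
  g <- ann$genes[ann$genes$symbol == "TPM3", ]
  expect_error(coding_offset(ann, "TPM3", g$end + 10L, "five_prime"),
               "outside span")
  expect_error(coding_offset(ann, "NOSUCH", 100L, "five_prime"),
               "unknown gene")
})
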