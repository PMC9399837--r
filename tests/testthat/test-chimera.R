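test_that("PTPRG-RAF1 junction offsets are congruent mod 3 and match the oracle", {
  ann <- fixture_annotation()
  call <- registry_call("PTPRG", "RAF1", split = 87, disc = 5)
  off <- junction_offsets(call, ann)
  expect_equal(off$c5, 13L * 120L)    # PTPRG exons 1-13 retained
  expect_equal(off$c3, 6L * 120L)     # RAF1 exons 1-6 excluded
  expect_equal((off$c5 - off$c3) %% 3, 0)
  models <- oracle_models(fixture_paths()$gtf)
  expect_equal(off$c5, oracle_offset(models[["PTPRG"]], call$pos5, "five_prime"))
  expect_equal(off$c3, oracle_offset(models[["RAF1"]], call$pos3, "three_prime"))
})

test_that("junction offsets equal the base-by-base walk for every fixture fusion", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  reg <- fixture_registry()
  for (i in seq_len(nrow(reg))) {
    call <- registry_call(reg$gene5[i], reg$gene3[i])
    off <- junction_offsets(call, ann)
    expect_equal(off$c5,
                 oracle_offset(models[[call$gene5]], call$pos5, "five_prime"),
                 info = paste(call$gene5, call$gene3))
    expect_equal(off$c3,
                 oracle_offset(models[[call$gene3]], call$pos3, "three_prime"),
                 info = paste(call$gene5, call$gene3))
  }
})

test_that("frame status implements the chimeric-ORF congruence", {
  expect_equal(frame_status(300, 0), "in_frame")
  expect_equal(frame_status(301, 0), "out_of_frame")
  expect_equal(frame_status(601, 360), "out_of_frame")
  expect_equal(frame_status(0, 0, list(utr5 = TRUE)), "promoter_swap")
  expect_equal(frame_status(10, 10, list(noncoding3 = TRUE)), "noncoding")
  ann <- fixture_annotation()
  j_out <- chimeric_junction(registry_call("KIF13A", "PIK3CA"), ann)
  expect_equal(j_out$frame, "out_of_frame")
  j_ps <- chimeric_junction(registry_call("ZNF462", "MUSK"), ann)
  expect_equal(j_ps$frame, "promoter_swap")
  expect_equal(j_ps$c5, 0L)
  expect_equal(j_ps$c3, 0L)
  # 5' breakpoint just before the CDS start retains zero coding bases
  models <- oracle_models(fixture_paths()$gtf)
  cds_start <- min(models[["TPM3"]]$start[models[["TPM3"]]$type == "CDS"])
  off <- coding_offset(ann, "TPM3", cds_start - 1L, "five_prime")
  expect_equal(off$n_coding_nt, 0L)
})

test_that("shifting the 5' breakpoint by one coding base toggles the frame class", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  b <- oracle_exon_boundaries(models[["TPM3"]])
  # interior coding positions of exon 3 (fully coding, plus strand)
  p <- b$starts[3] + 10L
  c_at <- function(pos) coding_offset(ann, "TPM3", pos, "five_prime")$n_coding_nt
  expect_equal(c_at(p + 1L) - c_at(p), 1L)
  expect_false(((c_at(p) - 0) %% 3) == ((c_at(p + 1L) - 0) %% 3))
})

test_that("frame status agrees with the codon-walking oracle on random boundary pairs", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  genes <- fixture_annotation()$genes
  cand5 <- genes$symbol[genes$chrom == "chr1"]
  cand3 <- genes$symbol[genes$chrom == "chr2"]
  set.seed(2024)
  for (i in 1:60) {
    g5 <- sample(cand5, 1); g3 <- sample(cand3, 1)
    b5 <- oracle_exon_boundaries(models[[g5]])
    b3 <- oracle_exon_boundaries(models[[g3]])
    # avoid boundaries in UTR-containing terminal exons for a clean oracle
    e5 <- sample(2:(length(b5$ends) - 1), 1)
    e3 <- sample(2:(length(b3$starts) - 1), 1)
    pos5 <- b5$ends[e5]; pos3 <- b3$starts[e3]
    off5 <- coding_offset(ann, g5, pos5, "five_prime")
    off3 <- coding_offset(ann, g3, pos3, "three_prime")
    got <- frame_status(off5$n_coding_nt, off3$n_coding_nt,
                        list(utr5 = off5$in_utr, noncoding3 = off3$noncoding))
    want <- oracle_frame(models[[g5]], pos5, models[[g3]], pos3)
    expect_equal(got, want, info = sprintf("%s-%s e%d/e%d", g5, g3, e5, e3))
  }
})

test_that("domain retention reports intact, lost, and boundary-equal intervals", {
  ann <- fixture_annotation()
  # RAF1 kinase domain fully inside the retained 3' interval
  j <- chimeric_junction(registry_call("PTPRG", "RAF1"), ann)
  ds <- domain_retention(j, ann)
  raf1 <- ds[ds$gene_symbol == "RAF1", ]
  expect_equal(raf1$status, "intact")
  expect_equal(raf1$partner, "three_prime")
  # SS18 QPGY eliminated by an early 5' breakpoint
  j2 <- chimeric_junction(registry_call("SS18", "GREB1"), ann)
  ds2 <- domain_retention(j2, ann)
  expect_equal(ds2$status[ds2$name == "QPGY"], "lost")
  # domain interval exactly equal to the retained interval counts as intact
  expect_equal(fusetriage:::interval_status(1, 80, 1, 80), "intact")
  expect_equal(fusetriage:::interval_status(1, 81, 1, 80), "truncated")
  expect_equal(fusetriage:::interval_status(81, 90, 1, 80), "lost")
})

test_that("domain trichotomy partitions all configurations", {
  set.seed(5)
  for (i in 1:200) {
    lo <- sample(1:50, 1); hi <- lo + sample(0:50, 1)
    a <- sample(1:60, 1); b <- a + sample(0:60, 1)
    s <- fusetriage:::interval_status(a, b, lo, hi)
    contained <- a >= lo && b <= hi
    disjoint <- b < lo || a > hi
    expect_equal(s, if (contained) "intact" else if (disjoint) "lost" else "truncated")
  }
})

test_that("retention is monotone as the 3' breakpoint moves upstream", {
  ann <- fixture_annotation()
  models <- oracle_models(fixture_paths()$gtf)
  b3 <- oracle_exon_boundaries(models[["RAF1"]])
  rank <- c(lost = 1, truncated = 2, intact = 3)
  statuses <- vapply(rev(seq_along(b3$starts)), function(e) {
    call <- registry_call("PTPRG", "RAF1")
    call$pos3 <- b3$starts[e]
    j <- chimeric_junction(call, ann)
    ds <- domain_retention(j, ann)
    ds$status[ds$gene_symbol == "RAF1"]
  }, character(1))
  # walking the breakpoint upstream (exon 18 -> 1) can only improve retention
  expect_true(all(diff(rank[statuses]) >= 0))
})

test_that("functional pass reflects the driver partner's required domain", {
  ann <- fixture_annotation()
  check <- function(g5, g3) {
    j <- chimeric_junction(registry_call(g5, g3), ann)
    functional_pass(j, domain_retention(j, ann), ann)
  }
  expect_equal(check("PTPRG", "RAF1")$verdict, "pass")        # kinase intact
  expect_equal(check("MAZ", "NCOA2")$verdict, "pass")         # DBD + transactivation intact
  expect_equal(check("ZNF462", "MUSK")$verdict, "pass")       # promoter swap
  fail <- check("SS18", "GREB1")                              # QPGY eliminated
  expect_equal(fail$verdict, "fail")
  expect_match(fail$reason, "SS18")
  # neither partner kinase/TF: the criterion cannot exclude
  expect_equal(check("LSM1", "NRG1")$verdict, "indeterminate_pass")
})
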