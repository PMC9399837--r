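test_that("sample QC flags fewer than 10 unique reads as indeterminate", {
  cfg <- triage_config()
  expect_equal(sample_qc(9, cfg), "indeterminate")
  expect_equal(sample_qc(10, cfg), "pass")
  expect_equal(sample_qc(0, cfg), "indeterminate")
  expect_equal(sample_qc(c(3, 100), cfg), c("indeterminate", "pass"))
  expect_error(sample_qc(-1, cfg), "non-negative")
})

test_that("artifact screen applies proximity, flag, and read-through rules", {
  cfg <- triage_config()
  ann <- fixture_annotation()
  base <- registry_call("TPM3", "NTRK1")
  # same chromosome, 500 kb apart -> proximity artifact
  close_call <- base
  close_call$chrom3 <- close_call$chrom5
  close_call$pos3 <- close_call$pos5 + 500000L
  scr <- artifact_screen(close_call, cfg, ann)
  expect_true(scr$is_artifact)
  expect_true("proximity_lt_1mbp" %in% scr$reasons)
  # exactly 1 Mbp is not an artifact: "less than" is strict
  close_call$pos3 <- close_call$pos5 + 1000000L
  expect_false(artifact_screen(close_call, cfg, ann)$is_artifact)
  # inter-chromosomal, no flags -> clean
  expect_false(artifact_screen(base, cfg, ann)$is_artifact)
  # mispriming flag alone is decisive
  flagged <- base; flagged$flags <- "mispriming"
  expect_equal(artifact_screen(flagged, cfg, ann)$reasons, "mispriming")
  # read-through geometry: adjacent collinear same-strand neighbours
  rt <- registry_call("SLC45A3", "ELK4")
  expect_true("readthrough" %in% artifact_screen(rt, cfg, ann)$reasons)
  # proximity decoy is not collinear (opposite strands) -> proximity only
  px <- registry_call("FGFR3", "TACC3")
  scr_px <- artifact_screen(px, cfg, ann)
  expect_false("readthrough" %in% scr_px$reasons)
  expect_true("proximity_lt_1mbp" %in% scr_px$reasons)
})

test_that("low-support rule is a strict conjunction", {
  cfg <- triage_config()
  expect_false(support_screen(87, 5, cfg))   # PTPRG-RAF1
  expect_true(support_screen(9, 0, cfg))
  expect_false(support_screen(9, 1, cfg))
  expect_false(support_screen(11, 0, cfg))   # LSM1-NRG1
  expect_false(support_screen(10, 0, cfg))   # boundary: 10 is enough
})

test_that("single-call classification follows the cascade with accumulated reasons", {
  ann <- fixture_annotation()
  db <- fixture_db()
  cfg <- triage_config()
  # intronic out-of-frame with low support: both passenger reasons recorded
  pdzd2 <- classify_call(registry_call("PDZD2", "AKT2", split = 7, disc = 0),
                         ann, db, cfg)
  expect_equal(pdzd2$class, "passenger")
  expect_equal(pdzd2$reasons, "low_support;out_of_frame")
  # out-of-frame with adequate support: frame reason only
  kif <- classify_call(registry_call("KIF13A", "PIK3CA", split = 34, disc = 2),
                       ann, db, cfg)
  expect_equal(kif$class, "passenger")
  expect_equal(kif$reasons, "out_of_frame")
  # domain loss
  ss18 <- classify_call(registry_call("SS18", "GREB1", split = 45, disc = 2),
                        ann, db, cfg)
  expect_equal(ss18$class, "passenger")
  expect_equal(ss18$reasons, "domain_lost")
  # previously reported pair
  esr1 <- classify_call(registry_call("ESR1", "NCOA3"), ann, db, cfg)
  expect_equal(esr1$class, "known_oncogenic")
  # clean novel candidate
  appl2 <- classify_call(registry_call("APPL2", "RAF1", split = 87, disc = 5),
                         ann, db, cfg)
  expect_equal(appl2$class, "novel_candidate")
  expect_equal(appl2$reasons, "passes_all")
  # unknown partner symbol
  bad <- registry_call("PTPRG", "RAF1"); bad$gene5 <- "NOSUCH"
  expect_error(classify_call(bad, ann, db, cfg), "unknown gene")
})

test_that("classification matches an exhaustive truth-table oracle", {
  ann <- fixture_annotation()
  db <- fixture_db()
  cfg <- triage_config()
  bases <- list(
    list(g5 = "TPM3", g3 = "NTRK1", frame_bad = FALSE, dom_fail = FALSE,
         in_db = TRUE, geom = FALSE),
    list(g5 = "PTPRG", g3 = "RAF1", frame_bad = FALSE, dom_fail = FALSE,
         in_db = FALSE, geom = FALSE),
    list(g5 = "KIF13A", g3 = "PIK3CA", frame_bad = TRUE, dom_fail = FALSE,
         in_db = FALSE, geom = FALSE),
    list(g5 = "SS18", g3 = "GREB1", frame_bad = FALSE, dom_fail = TRUE,
         in_db = FALSE, geom = FALSE),
    list(g5 = "ZNF462", g3 = "MUSK", frame_bad = FALSE, dom_fail = FALSE,
         in_db = FALSE, geom = FALSE),
    list(g5 = "LSM1", g3 = "NRG1", frame_bad = FALSE, dom_fail = FALSE,
         in_db = FALSE, geom = FALSE),
    list(g5 = "SLC45A3", g3 = "ELK4", frame_bad = FALSE, dom_fail = FALSE,
         in_db = FALSE, geom = TRUE),
    list(g5 = "FGFR3", g3 = "TACC3", frame_bad = FALSE, dom_fail = FALSE,
         in_db = FALSE, geom = TRUE))
  supports <- list(c(5, 0), c(15, 0), c(5, 2), c(9, 1), c(10, 0))
  for (b in bases) {
    for (flag in c("", "mispriming")) {
      for (s in supports) {
        for (dual in list(NA, TRUE, FALSE)) {
          call <- registry_call(b$g5, b$g3, split = s[1], disc = s[2],
                                flags = flag)
          got <- classify_call(call, ann, db, cfg, dual_confirmed = dual)
          # independent restatement of the cascade rules
          expected <- if (nzchar(flag) || b$geom || isFALSE(dual)) {
            "artifact"
          } else {
            low <- s[1] < 10 && s[2] == 0
            if (low || b$frame_bad || b$dom_fail) "passenger"
            else if (b$in_db) "known_oncogenic" else "novel_candidate"
          }
          expect_equal(got$class, expected,
                       info = sprintf("%s-%s flag='%s' s=%d/%d dual=%s",
                                      b$g5, b$g3, flag, s[1], s[2],
                                      as.character(dual)))
        }
      }
    }
  }
})

test_that("dual-caller confirmation is enforced only when a second stream exists", {
  ann <- fixture_annotation()
  db <- fixture_db()
  calls <- rbind(registry_call("PTPRG", "RAF1", sample_id = "S1"),
                 registry_call("TPM3", "NTRK1", sample_id = "S1"))
  samples <- tibble::tibble(sample_id = "S1", unique_reads = 1000L)
  # second stream confirms only PTPRG-RAF1
  calls2 <- registry_call("PTPRG", "RAF1", sample_id = "S1")
  calls2$caller <- "arriba"
  res <- classify_cohort(calls, samples, ann, db, calls2 = calls2)
  got <- res$calls[order(res$calls$gene5), ]
  expect_equal(got$class[got$gene5 == "PTPRG"], "novel_candidate")
  expect_equal(got$class[got$gene5 == "TPM3"], "artifact")
  expect_equal(got$reasons[got$gene5 == "TPM3"], "not_dual_called")
  # without a second stream both survive
  res1 <- classify_cohort(calls, samples, ann, db)
  expect_true(all(res1$calls$class != "artifact"))
})

test_that("cohort classification is independent of input row order", {
  set.seed(99)
  calls <- fixture_calls()
  shuffled <- calls[sample(nrow(calls)), ]
  res_a <- fixture_result()
  res_b <- classify_cohort(shuffled, fixture_samples(), fixture_annotation(),
                           fixture_db())
  expect_equal(res_b$calls, res_a$calls)
  expect_equal(res_b$samples, res_a$samples)
})

test_that("raising the split-read threshold only demotes calls toward low support", {
  ann <- fixture_annotation()
  db <- fixture_db()
  res_lo <- fixture_result()
  res_hi <- classify_cohort(fixture_calls(), fixture_samples(), ann, db,
                            cfg = triage_config(min_split_reads = 200))
  key <- function(x) paste(x$sample_id, x$gene5, x$gene3)
  stopifnot(identical(key(res_lo$calls), key(res_hi$calls)))
  changed <- which(res_lo$calls$class != res_hi$calls$class)
  expect_true(all(res_hi$calls$class[changed] == "passenger"))
  expect_true(all(grepl("low_support", res_hi$calls$reasons[changed])))
  # and nothing ever moves the other way
  onc <- c("known_oncogenic", "novel_candidate")
  expect_true(all(!(res_hi$calls$class %in% onc & !(res_lo$calls$class %in% onc))))
})

test_that("indeterminate samples and empty cohorts are handled", {
  ann <- fixture_annotation()
  db <- fixture_db()
  calls <- registry_call("PTPRG", "RAF1", sample_id = "S1")
  samples <- tibble::tibble(sample_id = c("S1", "S2"),
                            unique_reads = c(5L, 1000L))
  res <- classify_cohort(calls, samples, ann, db)
  expect_equal(res$samples$qc, c("indeterminate", "pass"))
  expect_equal(nrow(res$calls), 0L)  # calls of QC-failed samples are dropped
  expect_false(any(res$samples$fusion_positive))
  # zero calls -> zero positives
  res0 <- classify_cohort(calls[0, ], samples, ann, db)
  expect_equal(sum(res0$samples$fusion_positive), 0L)
  # orphan call
  expect_error(classify_cohort(calls, samples[2, ], ann, db), "unknown sample")
})
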