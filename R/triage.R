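#' Triage configuration
#'
#' Thresholds for the filter cascade. Defaults encode the study's criteria:
#' a call is low-support when fewer than 10 unique split fragments and
#' exactly 0 discordant mates are found simultaneously; same-chromosome
#' breakpoints closer than 1 Mbp are excluded as likely artifacts (the
#' fusion caller's default); samples with fewer than 10 unique RNA reads
#' are indeterminate; dual-caller confirmation requires gene-pair identity
#' with breakpoints within 10 bp.
#'
#' @param min_split_reads Minimum unique split fragments (default 10).
#' @param low_support_max_discordant Discordant-mate count at or below which
#'   the low-support rule can fire (default 0: "0 discordant mates" is
#'   literal).
#' @param min_breakpoint_distance Minimum same-chromosome breakpoint
#'   distance in bp (default 1e6; "less than" is strict).
#' @param min_sample_unique_reads Sample QC threshold (default 10).
#' @param bp_tolerance Breakpoint tolerance for dual-caller matching
#'   (default 10 bp).
#' @param require_dual_caller Require confirmation by a second caller stream
#'   when one is supplied (default TRUE; single-stream inputs skip the
#'   check).
#' @param readthrough_max_gap Maximum intergenic gap, in bp, for the
#'   read-through geometry rule (default 2e5): a same-chromosome,
#'   same-strand call whose 5' gene lies transcriptionally upstream of the
#'   3' gene within this gap mimics read-through transcription.
#' @return A `triage_config` list.
#' @export
triage_config <- function(min_split_reads = 10,
                          low_support_max_discordant = 0,
                          min_breakpoint_distance = 1e6,
                          min_sample_unique_reads = 10,
                          bp_tolerance = 10,
                          require_dual_caller = TRUE,
                          readthrough_max_gap = 2e5) {
  cfg <- list(min_split_reads = min_split_reads,
              low_support_max_discordant = low_support_max_discordant,
              min_breakpoint_distance = min_breakpoint_distance,
              min_sample_unique_reads = min_sample_unique_reads,
              bp_tolerance = bp_tolerance,
              require_dual_caller = require_dual_caller,
              readthrough_max_gap = readthrough_max_gap)
  num <- vapply(cfg[names(cfg) != "require_dual_caller"], as.numeric, numeric(1))
  if (any(num < 0)) stop_fus("triage thresholds must be >= 0", "config_error")
  structure(cfg, class = "triage_config")
}

#' Read a triage configuration from YAML
#'
#' The YAML keys mirror the [triage_config()] argument names; missing keys
#' take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `triage_config`.
#' @export
triage_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(triage_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop_fus(paste("unknown config key(s):", paste(extra, collapse = ", ")),
             "config_error")
  }
  do.call(triage_config, vals)
}

#' Sample-level quality control
#'
#' Samples with fewer unique RNA reads than the threshold are classified
#' indeterminate and excluded from call-level analysis.
#'
#' @param sample_unique_reads Integer vector of per-sample unique read
#'   counts.
#' @param cfg A `triage_config`.
#' @return Character vector: `"pass"` or `"indeterminate"`.
#' @export
sample_qc <- function(sample_unique_reads, cfg = triage_config()) {
  if (any(is.na(sample_unique_reads)) || any(sample_unique_reads < 0)) {
    stop_fus("sample unique-read counts must be non-negative", "input_error")
  }
  ifelse(sample_unique_reads < cfg$min_sample_unique_reads,
         "indeterminate", "pass")
}

#' Artifact screen for a fusion call
#'
#' A call is an artifact if any of: it carries a `mispriming` flag; it
#' carries a `readthrough` flag or satisfies the read-through geometry rule
#' (same chromosome, same strand, 5' gene transcriptionally upstream of and
#' near the 3' gene — see [triage_config()]); or its breakpoints lie on the
#' same chromosome closer than the minimum breakpoint distance (strict
#' inequality).
#'
#' @param call One-row tibble/list with `gene5`, `gene3`, `chrom5`, `pos5`,
#'   `chrom3`, `pos3`, `flags`.
#' @param cfg A `triage_config`.
#' @param annotation Optional `genome_annotation`; required for the
#'   read-through geometry rule (skipped when absent).
#' @return List with `is_artifact` (logical) and `reasons` (character
#'   vector, subset of `mispriming`, `readthrough`, `proximity_lt_1mbp`).
#' @export
artifact_screen <- function(call, cfg = triage_config(), annotation = NULL) {
  reasons <- character()
  flags <- split_flags(call$flags %||% "")
  if ("mispriming" %in% flags) reasons <- c(reasons, "mispriming")
  rt <- "readthrough" %in% flags
  if (!rt && !is.null(annotation)) rt <- is_readthrough_geometry(call, cfg, annotation)
  if (rt) reasons <- c(reasons, "readthrough")
  if (call$chrom5 == call$chrom3 &&
      abs(call$pos5 - call$pos3) < cfg$min_breakpoint_distance) {
    reasons <- c(reasons, "proximity_lt_1mbp")
  }
  list(is_artifact = length(reasons) > 0, reasons = reasons)
}

is_readthrough_geometry <- function(call, cfg, annotation) {
  if (call$gene5 == call$gene3) return(FALSE)  # intragenic deletion isoform
  g5 <- tryCatch(gene_by_symbol(annotation, call$gene5), error = function(e) NULL)
  g3 <- tryCatch(gene_by_symbol(annotation, call$gene3), error = function(e) NULL)
  if (is.null(g5) || is.null(g3)) return(FALSE)
  if (g5$chrom != g3$chrom || g5$strand != g3$strand) return(FALSE)
  if (g5$strand == "+") {
    g5$end < g3$start && (g3$start - g5$end) <= cfg$readthrough_max_gap
  } else {
    g3$end < g5$start && (g5$start - g3$end) <= cfg$readthrough_max_gap
  }
}

#' Low-support screen
#'
#' A call is low-support when fewer than `min_split_reads` unique split
#' fragments *and* no more than `low_support_max_discordant` (default 0)
#' discordant mates are found simultaneously. Split-read counts are
#' post-deduplication unique fragments (see [unique_fragment_count()]).
#'
#' @param split_reads,discordant_mates Integer support counts.
#' @param cfg A `triage_config`.
#' @return Logical: is the support insufficient?
#' @export
support_screen <- function(split_reads, discordant_mates,
                           cfg = triage_config()) {
  split_reads < cfg$min_split_reads &
    discordant_mates <= cfg$low_support_max_discordant
}

#' Classify a single fusion call
#'
#' Applies the filter cascade: (1) artifact screen (mispriming,
#' read-through, breakpoint proximity); (2) dual-caller confirmation when a
#' second caller stream was available; (3) read-support screen; (4) reading
#' frame of the chimeric coding sequence; (5) functional-domain retention
#' (evaluated only for junctions whose frame permits a protein product);
#' (6) known-fusion database lookup. Calls failing (1)-(2) are artifacts;
#' calls failing (3)-(5) are passengers, with all failed checks accumulated
#' as reason codes; surviving calls are `known_oncogenic` when the ordered
#' gene pair is in the database and `novel_candidate` otherwise.
#'
#' @param call One-row tibble of a fusion call (generic columns).
#' @param annotation A `genome_annotation` resolving both partners.
#' @param db A `known_fusion_db`.
#' @param cfg A `triage_config`.
#' @param dual_confirmed `NA` when no second caller stream applies;
#'   otherwise whether the call was confirmed by the second caller.
#' @return One-row tibble: call columns plus `class`, `reasons`
#'   (`;`-joined reason codes), `c5`, `c3`, `frame`, `functional`.
#' @export
classify_call <- function(call, annotation, db, cfg = triage_config(),
                          dual_confirmed = NA) {
  art <- artifact_screen(call, cfg, annotation)
  reasons <- art$reasons
  if (!art$is_artifact && isTRUE(cfg$require_dual_caller) &&
      !is.na(dual_confirmed) && !dual_confirmed) {
    reasons <- c(reasons, "not_dual_called")
  }
  if (length(reasons) > 0) {
    return(classified_row(call, "artifact", reasons,
                          c5 = NA_integer_, c3 = NA_integer_,
                          frame = NA_character_, functional = NA_character_))
  }
  junction <- chimeric_junction(call, annotation)
  if (support_screen(call$split_reads, call$discordant_mates, cfg)) {
    reasons <- c(reasons, "low_support")
  }
  functional <- NA_character_
  if (junction$frame %in% c("out_of_frame", "noncoding")) {
    reasons <- c(reasons, "out_of_frame")
  } else {
    ds <- domain_retention(junction, annotation)
    fp <- functional_pass(junction, ds, annotation)
    functional <- fp$verdict
    if (fp$verdict == "fail") reasons <- c(reasons, "domain_lost")
  }
  if (length(reasons) > 0) {
    return(classified_row(call, "passenger", reasons, junction$c5,
                          junction$c3, junction$frame, functional))
  }
  if (db_lookup(db, call$gene5, call$gene3)) {
    classified_row(call, "known_oncogenic", "in_known_db", junction$c5,
                   junction$c3, junction$frame, functional)
  } else {
    classified_row(call, "novel_candidate", "passes_all", junction$c5,
                   junction$c3, junction$frame, functional)
  }
}

classified_row <- function(call, class, reasons, c5, c3, frame, functional) {
  dplyr::bind_cols(
    tibble::as_tibble(call[c("sample_id", "gene5", "gene3", "chrom5", "pos5",
                             "chrom3", "pos3", "split_reads",
                             "discordant_mates", "flags", "caller")]),
    tibble::tibble(class = class, reasons = paste(reasons, collapse = ";"),
                   c5 = as.integer(c5), c3 = as.integer(c3),
                   frame = frame, functional = functional))
}

#' Classify every call and every sample of a cohort
#'
#' Runs sample-level QC, then the per-call cascade of [classify_call()].
#' Calls are processed in a stable order (sample id, gene pair, positions),
#' so the result is independent of input row order. Samples failing QC have
#' their calls dropped. When a second caller stream is supplied and the
#' configuration requires dual-caller confirmation, primary calls without a
#' within-tolerance match in the second stream (same sample, same ordered
#' gene pair) are classified artifacts with reason `not_dual_called`.
#'
#' @param calls Tibble of fusion calls (generic columns).
#' @param samples Tibble with `sample_id` and optionally `unique_reads`
#'   (per-sample unique RNA read count; all samples pass QC when absent).
#' @param annotation A `genome_annotation`.
#' @param db A `known_fusion_db`.
#' @param cfg A `triage_config`.
#' @param calls2 Optional tibble of calls from a second caller.
#' @return A `triage_result` list with `$calls` (classified calls) and
#'   `$samples` (per-sample `qc`, `n_calls`, `fusion_positive`).
#' @export
classify_cohort <- function(calls, samples, annotation, db,
                            cfg = triage_config(), calls2 = NULL) {
  orphan <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(orphan)) {
    stop_fus(paste("call(s) reference unknown sample(s):",
                   paste(orphan, collapse = ", ")),
             "validation_error")
  }
  qc <- if ("unique_reads" %in% names(samples)) {
    sample_qc(samples$unique_reads, cfg)
  } else rep("pass", nrow(samples))
  sample_tab <- tibble::tibble(sample_id = samples$sample_id, qc = qc)

  calls <- dplyr::arrange(calls, .data$sample_id, .data$gene5, .data$gene3,
                          .data$pos5, .data$pos3)
  keep <- calls$sample_id %in% sample_tab$sample_id[sample_tab$qc == "pass"]
  calls <- calls[keep, , drop = FALSE]

  dual <- rep(NA, nrow(calls))
  if (!is.null(calls2) && isTRUE(cfg$require_dual_caller) && nrow(calls) > 0) {
    dual <- vapply(seq_len(nrow(calls)), function(i) {
      b <- calls2[calls2$sample_id == calls$sample_id[i], , drop = FALSE]
      nrow(concordant_calls(calls[i, ], b, cfg$bp_tolerance)) > 0
    }, logical(1))
  }

  classified <- if (nrow(calls) == 0) {
    tibble::tibble(sample_id = character(), gene5 = character(),
                   gene3 = character(), chrom5 = character(),
                   pos5 = integer(), chrom3 = character(),
                   pos3 = integer(), split_reads = integer(),
                   discordant_mates = integer(), flags = character(),
                   caller = character(), class = character(),
                   reasons = character(), c5 = integer(), c3 = integer(),
                   frame = character(), functional = character())
  } else {
    purrr::map_dfr(seq_len(nrow(calls)), function(i) {
      classify_call(calls[i, ], annotation, db, cfg, dual[i])
    })
  }

  pos_classes <- c("known_oncogenic", "novel_candidate")
  per_sample <- classified %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(n_calls = dplyr::n(),
                     fusion_positive = any(.data$class %in% pos_classes),
                     .groups = "drop")
  sample_results <- sample_tab %>%
    dplyr::left_join(per_sample, by = "sample_id") %>%
    dplyr::mutate(n_calls = dplyr::coalesce(.data$n_calls, 0L),
                  fusion_positive = dplyr::coalesce(.data$fusion_positive, FALSE))

  structure(list(calls = classified, samples = sample_results,
                 config = cfg),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %d samples (%d pass QC, %d fusion-positive), %d calls\n",
              nrow(x$samples), sum(x$samples$qc == "pass"),
              sum(x$samples$fusion_positive), nrow(x$calls)))
  print(table(x$calls$class))
  invisible(x)
}
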