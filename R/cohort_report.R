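oncogenic_classes <- c("known_oncogenic", "novel_candidate")

#' Per-diagnostic-group detection frequency
#'
#' Denominators are all enrolled patients in each group, including
#' sequencing failures. Frequencies are rounded half-up to integer percent.
#'
#' @param result A `triage_result` from [classify_cohort()].
#' @param meta Tibble of sample metadata: `sample_id`, `group_id`, and
#'   optionally `group_label`.
#' @return Tibble with one row per group: `group_id`, `group_label`,
#'   `n_patients`, `n_fusion_positive`, `frequency_pct`.
#' @export
group_frequency <- function(result, meta) {
  unmatched <- setdiff(result$samples$sample_id, meta$sample_id)
  if (length(unmatched)) {
    stop_fus(paste("sample(s) missing from metadata:",
                   paste(unmatched, collapse = ", ")),
             "validation_error")
  }
  if (!"group_label" %in% names(meta)) meta$group_label <- NA_character_
  dplyr::left_join(meta, result$samples, by = "sample_id") %>%
    dplyr::group_by(.data$group_id) %>%
    dplyr::summarise(
      group_label = .data$group_label[1],
      n_patients = dplyr::n(),
      n_fusion_positive = sum(.data$fusion_positive, na.rm = TRUE),
      .groups = "drop") %>%
    dplyr::mutate(frequency_pct = round_half_up(
      100 * .data$n_fusion_positive / .data$n_patients)) %>%
    dplyr::arrange(.data$group_id)
}

#' Fusion recurrence table
#'
#' One row per distinct ordered gene pair among oncogenic-class calls
#' (known oncogenic or novel candidate), counting the samples in which the
#' pair was detected; sorted by descending count, ties broken by fusion
#' name.
#'
#' @param result A `triage_result`.
#' @return Tibble with `fusion`, `gene5`, `gene3`, `n_samples`.
#' @export
recurrence_table <- function(result) {
  result$calls %>%
    dplyr::filter(.data$class %in% oncogenic_classes) %>%
    dplyr::distinct(.data$sample_id, .data$gene5, .data$gene3) %>%
    dplyr::count(.data$gene5, .data$gene3, name = "n_samples") %>%
    dplyr::mutate(fusion = paste(.data$gene5, .data$gene3, sep = "-")) %>%
    dplyr::arrange(dplyr::desc(.data$n_samples), .data$fusion) %>%
    dplyr::select("fusion", "gene5", "gene3", "n_samples")
}

#' Unknown- and novel-fusion inventory
#'
#' `n_unknown_fusions` counts distinct ordered gene pairs absent from the
#' database among calls that survived sample QC and the artifact screen,
#' before the passenger filters; `n_samples_unknown` counts the samples
#' carrying at least one such pair; `novel_after_triage` lists the distinct
#' pairs whose final class is `novel_candidate`.
#'
#' @param result A `triage_result`.
#' @param db A `known_fusion_db`.
#' @return List with `n_unknown_fusions`, `n_samples_unknown`,
#'   `unknown_fusions` (character vector), `novel_after_triage` (character
#'   vector).
#' @export
novel_inventory <- function(result, db) {
  pre <- dplyr::filter(result$calls, .data$class != "artifact")
  pre$in_db <- db_lookup(db, pre$gene5, pre$gene3)
  unknown <- dplyr::filter(pre, !.data$in_db)
  novel <- result$calls %>%
    dplyr::filter(.data$class == "novel_candidate") %>%
    dplyr::distinct(.data$gene5, .data$gene3)
  list(
    n_unknown_fusions = nrow(dplyr::distinct(unknown, .data$gene5, .data$gene3)),
    n_samples_unknown = dplyr::n_distinct(unknown$sample_id),
    unknown_fusions = sort(unique(paste(unknown$gene5, unknown$gene3, sep = "-"))),
    novel_after_triage = sort(paste(novel$gene5, novel$gene3, sep = "-")))
}

#' Assemble a cohort report
#'
#' Combines per-group frequencies, the recurrence table, the novel-fusion
#' inventory, and headline counts: samples enrolled, samples sequenced
#' (QC pass), samples with any non-artifact call before the passenger
#' filters, and fusion-positive samples after the full cascade.
#'
#' @param result A `triage_result`.
#' @param meta Sample metadata (see [group_frequency()]).
#' @param db A `known_fusion_db`.
#' @return A `cohort_report` list with `per_group`, `recurrence`, `novel`,
#'   `counts`.
#' @export
cohort_report <- function(result, meta, db) {
  per_group <- group_frequency(result, meta)
  recurrence <- recurrence_table(result)
  novel <- novel_inventory(result, db)
  pre <- dplyr::filter(result$calls, .data$class != "artifact")
  counts <- list(
    n_enrolled = nrow(result$samples),
    n_sequenced = sum(result$samples$qc == "pass"),
    n_detected_prefilter = dplyr::n_distinct(pre$sample_id),
    n_positive_postfilter = sum(result$samples$fusion_positive),
    distinct_fusion_count = nrow(recurrence))
  structure(list(per_group = per_group, recurrence = recurrence,
                 novel = novel, counts = counts),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "<cohort_report> %d enrolled, %d sequenced, %d with fusions pre-filter,\n  %d fusion-positive post-filter, %d distinct fusions (%d novel)\n",
    n_enrolled, n_sequenced, n_detected_prefilter, n_positive_postfilter,
    distinct_fusion_count, length(x$novel$novel_after_triage))))
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `per_group.tsv`, `recurrence.tsv`, `novel.tsv`, and `summary.json`.
#' Output is byte-stable given identical inputs.
#'
#' @param report A `cohort_report`.
#' @param outdir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  readr::write_tsv(report$per_group, file.path(outdir, "per_group.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$recurrence, file.path(outdir, "recurrence.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    tibble::tibble(fusion = report$novel$novel_after_triage),
    file.path(outdir, "novel.tsv"), progress = FALSE)
  summary <- c(report$counts,
               list(n_unknown_fusions = report$novel$n_unknown_fusions,
                    n_samples_unknown = report$novel$n_samples_unknown,
                    novel_after_triage = report$novel$novel_after_triage))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
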