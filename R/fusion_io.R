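#' Read a fusion call table
#'
#' Two dialects are supported. The `generic` dialect is the package's own
#' TSV with columns `sample_id, gene5, gene3, chrom5, pos5, chrom3, pos3,
#' split_reads, discordant_mates, flags, caller` (flags: `;`-separated subset
#' of `mispriming`, `readthrough`; empty for none). The `arriba` dialect
#' reads the relevant subset of Arriba's `fusions.tsv` columns
#' (`#gene1, gene2, breakpoint1, breakpoint2, split_reads1, split_reads2,
#' discordant_mates, reading_frame`); split-read support is
#' `split_reads1 + split_reads2` and breakpoints are parsed from
#' `"chrom:pos"`.
#'
#' @param path Path to the TSV file.
#' @param dialect `"generic"` or `"arriba"`.
#' @param sample_id Sample id to stamp onto rows of an `arriba` table (that
#'   format carries no sample column). Ignored for `generic`.
#' @return A tibble of fusion calls in input row order with the generic
#'   columns plus `frame_hint` (`in_frame`/`out_of_frame`/`NA`).
#' @export
read_calls <- function(path, dialect = c("generic", "arriba"),
                       sample_id = NULL) {
  dialect <- match.arg(dialect)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "")
  names(tab) <- sub("^#", "", names(tab))
  if (dialect == "generic") {
    need <- c("sample_id", "gene5", "gene3", "chrom5", "pos5", "chrom3",
              "pos3", "split_reads", "discordant_mates", "flags", "caller")
    check_columns(tab, need)
    out <- tibble::tibble(
      sample_id = as.character(tab$sample_id),
      gene5 = tab$gene5, gene3 = tab$gene3,
      chrom5 = as.character(tab$chrom5), pos5 = as.integer(tab$pos5),
      chrom3 = as.character(tab$chrom3), pos3 = as.integer(tab$pos3),
      split_reads = as.integer(tab$split_reads),
      discordant_mates = as.integer(tab$discordant_mates),
      flags = ifelse(is.na(tab$flags), "", as.character(tab$flags)),
      caller = tab$caller,
      frame_hint = if ("frame_hint" %in% names(tab)) tab$frame_hint else NA_character_
    )
  } else {
    need <- c("gene1", "gene2", "breakpoint1", "breakpoint2",
              "split_reads1", "split_reads2", "discordant_mates")
    check_columns(tab, need)
    bp1 <- parse_breakpoints(tab$breakpoint1, "breakpoint1")
    bp2 <- parse_breakpoints(tab$breakpoint2, "breakpoint2")
    frame_hint <- if ("reading_frame" %in% names(tab)) {
      dplyr::case_match(tab$reading_frame,
                        "in-frame" ~ "in_frame",
                        "out-of-frame" ~ "out_of_frame",
                        .default = NA_character_)
    } else NA_character_
    out <- tibble::tibble(
      sample_id = as.character(sample_id %||% NA_character_),
      gene5 = tab$gene1, gene3 = tab$gene2,
      chrom5 = bp1$chrom, pos5 = bp1$pos,
      chrom3 = bp2$chrom, pos3 = bp2$pos,
      split_reads = as.integer(tab$split_reads1) + as.integer(tab$split_reads2),
      discordant_mates = as.integer(tab$discordant_mates),
      flags = "",
      caller = "arriba",
      frame_hint = frame_hint
    )
  }
  if (any(stats::na.omit(c(out$pos5, out$pos3)) < 1)) {
    stop_fus("breakpoint positions must be >= 1", "schema_error")
  }
  out
}

check_columns <- function(tab, need) {
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_fus(paste("call table missing required column(s):",
                   paste(miss, collapse = ", ")),
             "schema_error")
  }
  invisible(TRUE)
}

parse_breakpoints <- function(x, colname) {
  ok <- grepl("^[^:]+:[0-9]+$", x)
  if (any(!ok)) {
    stop_fus(sprintf("unparsable %s at row %d: '%s' (expected chrom:pos)",
                     colname, which(!ok)[1], x[which(!ok)[1]]),
             "row_error")
  }
  list(chrom = sub(":.*$", "", x),
       pos = as.integer(sub("^.*:", "", x)))
}

#' Write fusion calls in the generic dialect
#'
#' Inverse of [read_calls()] for the generic dialect; `read_calls()` on the
#' written file round-trips losslessly.
#'
#' @param calls Tibble of fusion calls (generic columns).
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  cols <- c("sample_id", "gene5", "gene3", "chrom5", "pos5", "chrom3",
            "pos3", "split_reads", "discordant_mates", "flags", "caller")
  readr::write_tsv(calls[, cols], path, progress = FALSE)
  invisible(path)
}

#' Count unique supporting fragments by molecular barcode
#'
#' Collapses raw reads to unique fragments: reads sharing a molecular
#' barcode (UMI) derive from one original fragment, so the support used by
#' the read-count filter is the number of distinct UMIs among
#' junction-spanning reads.
#'
#' @param reads Tibble with columns `umi` (non-empty string) and
#'   `junction_spanning` (logical).
#' @return Integer count of distinct UMIs among junction-spanning reads.
#' @export
unique_fragment_count <- function(reads) {
  if (nrow(reads) == 0) return(0L)
  if (any(!nzchar(reads$umi) | is.na(reads$umi))) {
    stop_fus("empty molecular barcode in read records", "schema_error")
  }
  dplyr::n_distinct(reads$umi[reads$junction_spanning])
}

#' Read a raw-read table with molecular barcodes
#'
#' @param path TSV with header
#'   `sample_id, call_key, read_id, umi, junction_spanning`.
#' @return Tibble of read records.
#' @export
read_raw_reads <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(tab, c("sample_id", "call_key", "read_id", "umi",
                       "junction_spanning"))
  tab$junction_spanning <- as.logical(tab$junction_spanning)
  tab
}

#' Match fusion calls between two caller streams
#'
#' A call in `a` matches a call in `b` iff they share the same ordered
#' (5' gene, 3' gene) pair and both breakpoints lie within `bp_tolerance`
#' (same chromosome). Matching is symmetric: swapping `a` and `b` induces
#' the same matched pair set.
#'
#' @param a,b Tibbles of fusion calls from the same sample.
#' @param bp_tolerance Maximum breakpoint discrepancy in bp (default 10).
#' @return Tibble with one row per matched pair: `idx_a`, `idx_b`, `gene5`,
#'   `gene3`.
#' @export
concordant_calls <- function(a, b, bp_tolerance = 10) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(idx_a = integer(), idx_b = integer(),
                          gene5 = character(), gene3 = character()))
  }
  a2 <- dplyr::mutate(a, idx_a = dplyr::row_number())
  b2 <- dplyr::mutate(b, idx_b = dplyr::row_number())
  j <- dplyr::inner_join(
    dplyr::select(a2, "idx_a", "gene5", "gene3", c5a = "chrom5", p5a = "pos5",
                  c3a = "chrom3", p3a = "pos3"),
    dplyr::select(b2, "idx_b", "gene5", "gene3", c5b = "chrom5", p5b = "pos5",
                  c3b = "chrom3", p3b = "pos3"),
    by = c("gene5", "gene3"), relationship = "many-to-many")
  j <- dplyr::filter(j,
                     .data$c5a == .data$c5b, .data$c3a == .data$c3b,
                     abs(.data$p5a - .data$p5b) <= bp_tolerance,
                     abs(.data$p3a - .data$p3b) <= bp_tolerance)
  dplyr::select(j, "idx_a", "idx_b", "gene5", "gene3")
}

#' Read a known-fusion database
#'
#' Lookup is orientation-sensitive: an entry records an ordered
#' (5' gene, 3' gene) pair, and the reciprocal pair is a distinct entry,
#' since the 5'/3' roles determine oncogenicity. Duplicate rows collapse.
#'
#' @param path TSV with header `gene5, gene3, source`.
#' @return A `known_fusion_db` tibble of distinct entries.
#' @export
read_known_db <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(tab, c("gene5", "gene3", "source"))
  if (any(is.na(tab$gene5) | is.na(tab$gene3))) {
    stop_fus(sprintf("malformed known-fusion row %d: missing gene symbol",
                     which(is.na(tab$gene5) | is.na(tab$gene3))[1]),
             "row_error")
  }
  db <- dplyr::distinct(tab, .data$gene5, .data$gene3, .data$source)
  class(db) <- c("known_fusion_db", class(db))
  db
}

#' Orientation-sensitive known-fusion lookup
#'
#' @param db A `known_fusion_db` (or tibble with `gene5`, `gene3`).
#' @param gene5,gene3 Character vectors (recycled to common length).
#' @return Logical vector: is each ordered pair present in the database?
#' @export
db_lookup <- function(db, gene5, gene3) {
  paste(gene5, gene3, sep = "\r") %in% paste(db$gene5, db$gene3, sep = "\r")
}
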