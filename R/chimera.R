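#' Coding offsets of a fusion junction
#'
#' Computes `c5`, the number of coding nucleotides of the 5' partner retained
#' through the 5' breakpoint, and `c3`, the number of coding nucleotides of
#' the 3' partner excluded upstream of the 3' breakpoint, on each partner's
#' canonical transcript (see [coding_offset()]).
#'
#' @param call One-row tibble (or list) with `gene5`, `gene3`, `pos5`, `pos3`.
#' @param annotation A `genome_annotation` resolving both partners.
#' @return A list with `c5`, `c3`, `utr5` (5' breakpoint upstream of the 5'
#'   CDS), `utr3` (3' breakpoint at/upstream of the 3' CDS start),
#'   `noncoding3` (3' partner has no annotated CDS), `intron5`, `intron3`.
#' @export
junction_offsets <- function(call, annotation) {
  off5 <- coding_offset(annotation, call$gene5, call$pos5, "five_prime")
  off3 <- coding_offset(annotation, call$gene3, call$pos3, "three_prime")
  list(c5 = off5$n_coding_nt, c3 = off3$n_coding_nt,
       utr5 = off5$in_utr, utr3 = off3$in_utr,
       noncoding3 = off3$noncoding,
       intron5 = off5$in_intron, intron3 = off3$in_intron)
}

#' Reading-frame status of a chimeric coding sequence
#'
#' The chimeric ORF is in frame iff the retained 5' coding length and the
#' excluded 3' coding length are congruent modulo 3 (`(c5 - c3) mod 3 = 0`),
#' i.e. the 3' partner's codons are read in their native frame. Two special
#' cases precede the congruence: a fusion whose breakpoints both precede the
#' partners' coding sequences (no 5' coding retained, full 3' CDS retained)
#' is a `promoter_swap` — the enhancer-hijacking configuration that activates
#' an intact gene under a heterologous regulatory region; and a 3' partner
#' with no annotated CDS yields `noncoding`.
#'
#' @param c5,c3 Offsets from [junction_offsets()].
#' @param utr_flags List with logicals `utr5`, `utr3`, `noncoding3` (as
#'   returned by [junction_offsets()]).
#' @return One of `"in_frame"`, `"out_of_frame"`, `"promoter_swap"`,
#'   `"noncoding"`.
#' @export
frame_status <- function(c5, c3, utr_flags = list()) {
  if (isTRUE(utr_flags$noncoding3)) return("noncoding")
  if (isTRUE(utr_flags$utr5) && c5 == 0 && c3 == 0) return("promoter_swap")
  if ((c5 - c3) %% 3 == 0) "in_frame" else "out_of_frame"
}

#' Build the chimeric junction implied by a fusion call
#'
#' Combines [junction_offsets()] and [frame_status()] and derives the
#' retained protein intervals on each partner's native protein. The junction
#' codon split across the partners is attributed to neither side: the 5'
#' partner retains residues `[1, floor(c5/3)]`, the 3' partner residues
#' `[floor(c3/3) + 1, L3]` where `L3` is the 3' native protein length. A
#' promoter swap retains the full 3' protein and nothing of the 5' protein.
#'
#' @inheritParams junction_offsets
#' @return A `chimeric_junction` list: `call`, `c5`, `c3`, `frame`,
#'   `retained5` and `retained3` (integer `c(lo, hi)`; `hi < lo` means
#'   empty), `L3`, plus the UTR/intron flags.
#' @export
chimeric_junction <- function(call, annotation) {
  off <- junction_offsets(call, annotation)
  frame <- frame_status(off$c5, off$c3, off)
  L3 <- protein_length(annotation, call$gene3)
  if (frame == "promoter_swap") {
    retained5 <- c(1L, 0L)
    retained3 <- c(1L, L3)
  } else {
    retained5 <- c(1L, off$c5 %/% 3L)
    retained3 <- c(off$c3 %/% 3L + 1L, L3)
  }
  structure(list(call = call, c5 = off$c5, c3 = off$c3, frame = frame,
                 retained5 = retained5, retained3 = retained3, L3 = L3,
                 utr5 = off$utr5, utr3 = off$utr3,
                 noncoding3 = off$noncoding3,
                 intron5 = off$intron5, intron3 = off$intron3),
            class = "chimeric_junction")
}

#' @export
print.chimeric_junction <- function(x, ...) {
  cat(sprintf("<chimeric_junction> %s-%s c5=%d c3=%d frame=%s\n",
              x$call$gene5, x$call$gene3, x$c5, x$c3, x$frame))
  invisible(x)
}

interval_status <- function(aa_start, aa_end, lo, hi) {
  if (hi < lo) return("lost")                      # empty retained interval
  if (aa_start >= lo && aa_end <= hi) return("intact")
  if (aa_end < lo || aa_start > hi) return("lost")
  "truncated"
}

#' Protein-domain retention across a fusion junction
#'
#' Each annotated domain of the 5' partner is compared with the retained 5'
#' protein interval, and each domain of the 3' partner with the retained 3'
#' interval. Exactly one status holds per domain: `intact` (domain interval
#' contained in the retained interval), `lost` (disjoint), or `truncated`
#' (partial overlap).
#'
#' @param junction A `chimeric_junction`.
#' @param annotation A `genome_annotation` carrying protein domains.
#' @return Tibble with one row per domain: `gene_symbol`, `name`,
#'   `category`, `aa_start`, `aa_end`, `partner`
#'   (`five_prime`/`three_prime`), `status`.
#' @export
domain_retention <- function(junction, annotation) {
  d5 <- gene_domains(annotation, junction$call$gene5)
  d3 <- gene_domains(annotation, junction$call$gene3)
  rows <- list()
  if (nrow(d5)) {
    d5$partner <- "five_prime"
    d5$status <- vapply(seq_len(nrow(d5)), function(i) {
      interval_status(d5$aa_start[i], d5$aa_end[i],
                      junction$retained5[1], junction$retained5[2])
    }, character(1))
    rows <- c(rows, list(d5))
  }
  if (nrow(d3)) {
    d3$partner <- "three_prime"
    d3$status <- vapply(seq_len(nrow(d3)), function(i) {
      interval_status(d3$aa_start[i], d3$aa_end[i],
                      junction$retained3[1], junction$retained3[2])
    }, character(1))
    rows <- c(rows, list(d3))
  }
  if (length(rows) == 0) {
    out <- empty_domains()
    out$partner <- character()
    out$status <- character()
    return(out)
  }
  dplyr::bind_rows(rows)
}

required_categories <- function(gene_class) {
  switch(gene_class,
         protein_kinase = "kinase",
         transcription_factor = c("transactivation", "dna_binding"),
         character())
}

#' Functional-domain filter for a chimeric junction
#'
#' A fusion passes when its driver partner retains the functional domain its
#' gene class requires: a protein-kinase partner must keep a `kinase`-category
#' domain intact; a transcription-factor partner a `transactivation` or
#' `dna_binding` domain. Promoter-swap junctions (full 3' CDS retained under
#' a heterologous promoter) pass. A junction fails only when a required
#' domain is demonstrably truncated or lost; if neither partner is a kinase
#' or transcription factor, or no relevant domain is annotated, the call is
#' `indeterminate_pass` — the domain criterion can only exclude, never
#' rescue.
#'
#' @param junction A `chimeric_junction`.
#' @param domain_statuses Output of [domain_retention()].
#' @param annotation A `genome_annotation` (source of gene classes).
#' @return List with `verdict` (`"pass"`, `"fail"`, or
#'   `"indeterminate_pass"`) and `reason` (character; names the violated
#'   domain on failure).
#' @export
functional_pass <- function(junction, domain_statuses, annotation) {
  if (junction$frame == "promoter_swap") {
    return(list(verdict = "pass",
                reason = "full 3' CDS retained under heterologous promoter"))
  }
  partners <- tibble::tibble(
    symbol = c(junction$call$gene5, junction$call$gene3),
    partner = c("five_prime", "three_prime"))
  partners$gene_class <- vapply(partners$symbol, function(s) {
    gene_by_symbol(annotation, s)$gene_class
  }, character(1))
  drivers <- partners[partners$gene_class %in%
                        c("protein_kinase", "transcription_factor"), ]
  if (nrow(drivers) == 0) {
    return(list(verdict = "indeterminate_pass",
                reason = "no kinase/transcription-factor partner; domain criterion cannot exclude"))
  }
  verdicts <- character(0)
  fail_reason <- NULL
  for (i in seq_len(nrow(drivers))) {
    cats <- required_categories(drivers$gene_class[i])
    rel <- domain_statuses[domain_statuses$partner == drivers$partner[i] &
                             domain_statuses$gene_symbol == drivers$symbol[i] &
                             domain_statuses$category %in% cats, , drop = FALSE]
    if (nrow(rel) == 0) {
      verdicts <- c(verdicts, "indeterminate")
    } else if (any(rel$status == "intact")) {
      verdicts <- c(verdicts, "pass")
    } else {
      verdicts <- c(verdicts, "fail")
      fail_reason <- sprintf("%s %s domain %s (%s)",
                             drivers$symbol[i], rel$category[1], rel$status[1],
                             rel$name[1])
    }
  }
  if (any(verdicts == "pass")) {
    return(list(verdict = "pass", reason = "required functional domain intact"))
  }
  if (any(verdicts == "fail")) {
    return(list(verdict = "fail", reason = fail_reason))
  }
  list(verdict = "indeterminate_pass",
       reason = "no annotated domain in the required category")
}

#' Write a per-junction report
#'
#' One row per (junction, domain) with the computed offsets, frame, and
#' domain retention status.
#'
#' @param junctions List of `chimeric_junction` objects.
#' @param annotation A `genome_annotation`.
#' @param path Output TSV path.
#' @export
write_junction_report <- function(junctions, annotation, path) {
  rows <- purrr::map_dfr(junctions, function(j) {
    ds <- domain_retention(j, annotation)
    base <- tibble::tibble(sample_id = j$call$sample_id %||% NA_character_,
                           gene5 = j$call$gene5, gene3 = j$call$gene3,
                           c5 = j$c5, c3 = j$c3, frame = j$frame)
    if (nrow(ds) == 0) {
      base$domain <- NA_character_
      base$domain_status <- NA_character_
      base
    } else {
      dplyr::bind_cols(base[rep(1, nrow(ds)), ],
                       tibble::tibble(domain = ds$name,
                                      domain_status = ds$status))
    }
  })
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}
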