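#' Load a transcript annotation and protein-domain table
#'
#' Builds a `genome_annotation` object from a GTF file (Ensembl-style
#' attributes, gzip-transparent) and an optional tab-separated protein-domain
#' table. The object carries, for every gene, one canonical transcript
#' (largest coding sequence; ties broken by transcript id) on which all
#' breakpoint coordinate arithmetic is performed.
#'
#' The loader is order-insensitive: exon and CDS records may appear in any
#' order relative to their transcript records. Exon ordinals are recomputed
#' from genomic coordinates in transcription order (genomically descending on
#' the minus strand), so pre-existing `exon_number` attributes are ignored.
#'
#' CDS features are assumed to exclude the stop codon (Ensembl convention),
#' so the coding length of a transcript is three times its protein length.
#'
#' @param gtf_path Path to a GTF file with gene/transcript/exon (and
#'   optionally CDS) features carrying `gene_id`/`transcript_id` attributes.
#'   Genes may carry a `gene_class` attribute (`protein_kinase`,
#'   `transcription_factor`, or `other`) describing the panel role of the
#'   gene; missing values default to `other`.
#' @param domain_table_path Optional path to a TSV with header
#'   `gene,name,category,aa_start,aa_end` giving protein-domain intervals
#'   (1-based inclusive residues on the canonical transcript's protein).
#' @return A `genome_annotation` object: a list with elements `genes`,
#'   `transcripts`, `exons` (per-exon coding intervals and cumulative coding
#'   lengths), `domains`, and `canonical` (named map symbol -> transcript id).
#' @export
load_annotation <- function(gtf_path, domain_table_path = NULL) {
  n_records <- validate_gtf_lines(gtf_path)
  if (n_records == 0) {
    return(new_genome_annotation(empty_genes(), empty_transcripts(),
                                 empty_exons(), empty_domains(), character()))
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- tibble::as_tibble(as.data.frame(gr))
  if (!all(c("type", "gene_id") %in% names(df))) {
    stop_fus("GTF lacks type/gene_id attributes", "gtf_parse_error")
  }
  if (!"gene_name" %in% names(df)) df$gene_name <- df$gene_id
  df$gene_name <- ifelse(is.na(df$gene_name), df$gene_id, df$gene_name)

  gene_rows <- df[df$type == "gene", , drop = FALSE]
  exon_rows <- df[df$type == "exon", , drop = FALSE]
  cds_rows  <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(exon_rows) == 0 && nrow(gene_rows) == 0) {
    # degenerate but valid: empty annotation
    return(new_genome_annotation(empty_genes(), empty_transcripts(),
                                 empty_exons(), empty_domains(),
                                 character()))
  }

  genes <- build_gene_table(gene_rows, exon_rows)
  tx <- build_transcript_tables(exon_rows, cds_rows, genes)

  canonical <- tx$transcripts %>%
    dplyr::arrange(.data$symbol, dplyr::desc(.data$cds_len),
                   dplyr::desc(.data$tx_len), .data$transcript_id) %>%
    dplyr::distinct(.data$symbol, .keep_all = TRUE)
  canon_map <- stats::setNames(canonical$transcript_id, canonical$symbol)

  domains <- if (is.null(domain_table_path)) empty_domains() else {
    read_domain_table(domain_table_path, genes$symbol)
  }

  new_genome_annotation(genes, tx$transcripts, tx$exons, domains, canon_map)
}

# cheap structural validation so malformed lines are reported by number
# before rtracklayer parses the file
validate_gtf_lines <- function(path) {
  lines <- readr::read_lines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- body[nf != 9]
  if (length(bad)) {
    stop_fus(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                     bad[1], nf[which(body == bad[1])]),
             "gtf_parse_error")
  }
  length(body)
}

build_gene_table <- function(gene_rows, exon_rows) {
  if (nrow(gene_rows) > 0) {
    cls <- if ("gene_class" %in% names(gene_rows)) gene_rows$gene_class else NA_character_
    genes <- tibble::tibble(
      gene_id = gene_rows$gene_id,
      symbol = gene_rows$gene_name,
      chrom = as.character(gene_rows$seqnames),
      strand = as.character(gene_rows$strand),
      start = gene_rows$start,
      end = gene_rows$end,
      gene_class = ifelse(is.na(cls), "other", cls)
    )
  } else {
    genes <- exon_rows %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(
        symbol = .data$gene_name[1],
        chrom = as.character(.data$seqnames[1]),
        strand = as.character(.data$strand[1]),
        start = min(.data$start), end = max(.data$end),
        gene_class = "other", .groups = "drop")
  }
  if (anyDuplicated(genes$symbol)) {
    stop_fus(sprintf("duplicate gene symbol in annotation: %s",
                     genes$symbol[duplicated(genes$symbol)][1]),
             "annotation_validation_error")
  }
  genes
}

build_transcript_tables <- function(exon_rows, cds_rows, genes) {
  if (nrow(exon_rows) == 0) {
    return(list(transcripts = empty_transcripts(), exons = empty_exons()))
  }
  ex <- tibble::tibble(
    transcript_id = exon_rows$transcript_id,
    gene_id = exon_rows$gene_id,
    symbol = exon_rows$gene_name,
    strand = as.character(exon_rows$strand),
    g_start = exon_rows$start,
    g_end = exon_rows$end
  )
  # transcription order: ascending genomic on +, descending on -
  ex <- ex %>%
    dplyr::arrange(.data$transcript_id,
                   ifelse(.data$strand == "-", -.data$g_start, .data$g_start)) %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::mutate(exon_number = dplyr::row_number()) %>%
    dplyr::ungroup()

  # coding portion of each exon = intersection with the transcript's CDS span
  if (nrow(cds_rows) > 0) {
    cds <- tibble::tibble(transcript_id = cds_rows$transcript_id,
                          c_start = cds_rows$start, c_end = cds_rows$end) %>%
      dplyr::group_by(.data$transcript_id) %>%
      dplyr::summarise(cds_lo = min(.data$c_start), cds_hi = max(.data$c_end),
                       .groups = "drop")
    ex <- dplyr::left_join(ex, cds, by = "transcript_id")
  } else {
    ex$cds_lo <- NA_integer_; ex$cds_hi <- NA_integer_
  }
  ex <- ex %>%
    dplyr::mutate(
      coding_start = pmax(.data$g_start, .data$cds_lo),
      coding_end = pmin(.data$g_end, .data$cds_hi),
      coding_len = ifelse(is.na(.data$coding_start) |
                            .data$coding_start > .data$coding_end,
                          0L,
                          .data$coding_end - .data$coding_start + 1L)
    ) %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::mutate(cum_coding_before = cumsum(.data$coding_len) - .data$coding_len) %>%
    dplyr::ungroup()

  transcripts <- ex %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::summarise(
      gene_id = .data$gene_id[1], symbol = .data$symbol[1],
      strand = .data$strand[1],
      n_exons = dplyr::n(),
      tx_len = sum(.data$g_end - .data$g_start + 1L),
      cds_len = sum(.data$coding_len),
      .groups = "drop") %>%
    dplyr::mutate(cds_present = .data$cds_len > 0)
  bad_cds <- transcripts$cds_present & transcripts$cds_len %% 3 != 0
  if (any(bad_cds)) {
    rlang::warn(sprintf("CDS length not a multiple of 3 for transcript(s): %s",
                        paste(transcripts$transcript_id[bad_cds], collapse = ", ")))
  }
  list(transcripts = transcripts, exons = ex)
}

read_domain_table <- function(path, known_symbols) {
  dom <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene", "name", "category", "aa_start", "aa_end")
  miss <- setdiff(need, names(dom))
  if (length(miss)) {
    stop_fus(paste("domain table missing column(s):", paste(miss, collapse = ", ")),
             "schema_error")
  }
  unknown <- setdiff(unique(dom$gene), known_symbols)
  if (length(unknown)) {
    stop_fus(paste("domain table references unknown gene(s):",
                   paste(unknown, collapse = ", ")),
             "annotation_validation_error")
  }
  if (any(dom$aa_start < 1 | dom$aa_start > dom$aa_end)) {
    stop_fus("domain table has invalid residue interval (need 1 <= aa_start <= aa_end)",
             "annotation_validation_error")
  }
  tibble::tibble(gene_symbol = dom$gene, name = dom$name,
                 category = dom$category,
                 aa_start = as.integer(dom$aa_start),
                 aa_end = as.integer(dom$aa_end))
}

new_genome_annotation <- function(genes, transcripts, exons, domains, canonical) {
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 domains = domains, canonical = canonical),
            class = "genome_annotation")
}

empty_genes <- function() {
  tibble::tibble(gene_id = character(), symbol = character(),
                 chrom = character(), strand = character(),
                 start = integer(), end = integer(), gene_class = character())
}
empty_transcripts <- function() {
  tibble::tibble(transcript_id = character(), gene_id = character(),
                 symbol = character(), strand = character(),
                 n_exons = integer(), tx_len = integer(), cds_len = integer(),
                 cds_present = logical())
}
empty_exons <- function() {
  tibble::tibble(transcript_id = character(), gene_id = character(),
                 symbol = character(), strand = character(),
                 g_start = integer(), g_end = integer(), exon_number = integer(),
                 cds_lo = integer(), cds_hi = integer(),
                 coding_start = integer(), coding_end = integer(),
                 coding_len = integer(), cum_coding_before = integer())
}
empty_domains <- function() {
  tibble::tibble(gene_symbol = character(), name = character(),
                 category = character(), aa_start = integer(),
                 aa_end = integer())
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes, %d transcripts, %d domains\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$domains)))
  invisible(x)
}

gene_by_symbol <- function(annotation, symbol) {
  i <- match(symbol, annotation$genes$symbol)
  if (is.na(i)) {
    stop_fus(sprintf("unknown gene symbol: %s", symbol), "lookup_error")
  }
  annotation$genes[i, ]
}

canonical_exons <- function(annotation, symbol) {
  tx_id <- annotation$canonical[[symbol]]
  if (is.null(tx_id)) {
    stop_fus(sprintf("no canonical transcript for gene: %s", symbol), "lookup_error")
  }
  annotation$exons[annotation$exons$transcript_id == tx_id, , drop = FALSE]
}

protein_length <- function(annotation, symbol) {
  tx_id <- annotation$canonical[[symbol]]
  i <- match(tx_id, annotation$transcripts$transcript_id)
  annotation$transcripts$cds_len[i] %/% 3L
}

gene_domains <- function(annotation, symbol) {
  annotation$domains[annotation$domains$gene_symbol == symbol, , drop = FALSE]
}

#' Coding-nucleotide offset of a genomic position
#'
#' Strand-aware arithmetic between a genomic breakpoint and the coding
#' sequence of a gene's canonical transcript. Breakpoint semantics follow the
#' usual fusion-caller convention: the 5' breakpoint is the *last retained*
#' genomic base of the 5' partner, the 3' breakpoint the *first retained*
#' base of the 3' partner.
#'
#' For `side = "five_prime"` the returned `n_coding_nt` counts coding
#' nucleotides from the CDS start through `genomic_pos` inclusive; for
#' `side = "three_prime"` it counts coding nucleotides strictly upstream
#' (in transcript orientation) of `genomic_pos`. Intronic positions snap to
#' the nearest retained exon boundary (5' side: end of the preceding exon;
#' 3' side: start of the following exon), mirroring spliced fusion
#' transcripts, and are reported with `in_intron = TRUE`. Positions upstream
#' of the CDS return 0 with `in_utr = TRUE`. Genes without an annotated CDS
#' return 0 with `noncoding = TRUE` (for the 3' side this is the
#' full-CDS-retained convention).
#'
#' @param annotation A `genome_annotation`.
#' @param symbol Gene symbol.
#' @param genomic_pos 1-based genomic position within the gene's span.
#' @param side `"five_prime"` or `"three_prime"`.
#' @return A list with `n_coding_nt`, `in_utr` (upstream of CDS),
#'   `in_intron`, and `noncoding`.
#' @export
coding_offset <- function(annotation, symbol, genomic_pos,
                          side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  gene <- gene_by_symbol(annotation, symbol)
  if (genomic_pos < gene$start || genomic_pos > gene$end) {
    stop_fus(sprintf("position %d outside span of gene %s [%d, %d]",
                     genomic_pos, symbol, gene$start, gene$end),
             "range_error")
  }
  ex <- canonical_exons(annotation, symbol)
  minus <- ex$strand[1] == "-"
  no_cds <- all(ex$coding_len == 0)

  in_intron <- FALSE
  hit <- which(genomic_pos >= ex$g_start & genomic_pos <= ex$g_end)
  if (length(hit) == 0) {
    in_intron <- TRUE
    # transcript-order snap: five_prime keeps the preceding exon's end,
    # three_prime keeps the following exon's start
    if (!minus) {
      prev <- which(ex$g_end < genomic_pos)
      nxt <- which(ex$g_start > genomic_pos)
      if (side == "five_prime") {
        e <- prev[which.max(ex$g_end[prev])]
        genomic_pos <- ex$g_end[e]
      } else {
        e <- nxt[which.min(ex$g_start[nxt])]
        genomic_pos <- ex$g_start[e]
      }
    } else {
      prev <- which(ex$g_start > genomic_pos)   # transcript-upstream exons
      nxt <- which(ex$g_end < genomic_pos)
      if (side == "five_prime") {
        e <- prev[which.min(ex$g_start[prev])]
        genomic_pos <- ex$g_start[e]
      } else {
        e <- nxt[which.max(ex$g_end[nxt])]
        genomic_pos <- ex$g_end[e]
      }
    }
    hit <- e
  }
  e <- hit[1]

  if (no_cds) {
    return(list(n_coding_nt = 0L, in_utr = TRUE, in_intron = in_intron,
                noncoding = TRUE))
  }

  # coding bases of exon e at transcript-coordinate <= genomic_pos (inclusive)
  row <- ex[e, ]
  if (row$coding_len == 0) {
    up_incl <- 0L
    pos_is_coding <- FALSE
  } else if (!minus) {
    up_incl <- max(0L, min(genomic_pos, row$coding_end) - row$coding_start + 1L)
    pos_is_coding <- genomic_pos >= row$coding_start & genomic_pos <= row$coding_end
  } else {
    up_incl <- max(0L, row$coding_end - max(genomic_pos, row$coding_start) + 1L)
    pos_is_coding <- genomic_pos >= row$coding_start & genomic_pos <= row$coding_end
  }
  n_incl <- row$cum_coding_before + up_incl
  in_utr <- n_incl == 0L && !pos_is_coding  # upstream of the CDS start
  total <- sum(ex$coding_len)
  # distinguish 5'UTR from 3'UTR: upstream means no coding base at or before pos
  if (in_utr && n_incl == 0L) {
    # check whether pos lies transcript-downstream of the CDS end
    downstream <- row$cum_coding_before == total
    if (downstream) {
      in_utr <- FALSE
      n_incl <- total
    }
  }
  n <- if (side == "five_prime") n_incl else n_incl - as.integer(pos_is_coding)
  list(n_coding_nt = as.integer(n), in_utr = in_utr, in_intron = in_intron,
       noncoding = FALSE)
}
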