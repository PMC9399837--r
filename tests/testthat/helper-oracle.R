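# Independent brute-force oracle. Parses the fixture GTF directly (no reuse
# of the package's loader or interval arithmetic) and enumerates coding
# bases one by one. A coding base is transcript-upstream of a position iff
# it lies genomically at/below it on the plus strand (at/above on minus),
# which also handles intronic positions without a snapping rule.

oracle_models <- function(gtf_path) {
  lines <- readLines(gtf_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
    if (length(m) == 0) NA_character_ else sub(sprintf('%s "(.*)"', key), "\\1", m)
  }
  rows <- do.call(rbind, lapply(f, function(x) {
    data.frame(chrom = x[1], type = x[3], start = as.integer(x[4]),
               end = as.integer(x[5]), strand = x[7],
               symbol = attr_val(x[9], "gene_name"),
               stringsAsFactors = FALSE)
  }))
  split(rows, rows$symbol)
}

oracle_coding_bases <- function(model) {
  cds <- model[model$type == "CDS", ]
  if (nrow(cds) == 0) return(integer())
  sort(unlist(mapply(seq.int, cds$start, cds$end, SIMPLIFY = FALSE)))
}

oracle_offset <- function(model, pos, side) {
  v <- oracle_coding_bases(model)
  minus <- model$strand[1] == "-"
  if (side == "five_prime") {
    if (minus) sum(v >= pos) else sum(v <= pos)
  } else {
    if (minus) sum(v > pos) else sum(v < pos)
  }
}

# frame by codon-phase comparison: the first retained 3' base is read at
# chimeric phase c5 mod 3 and sits at native phase c3 mod 3
oracle_frame <- function(model5, pos5, model3, pos3) {
  c5 <- oracle_offset(model5, pos5, "five_prime")
  c3 <- oracle_offset(model3, pos3, "three_prime")
  if (c5 %% 3 == c3 %% 3) "in_frame" else "out_of_frame"
}

# exon boundary positions of a gene in transcript order (first/last base of
# each exon in transcript orientation)
oracle_exon_boundaries <- function(model) {
  ex <- model[model$type == "exon", ]
  minus <- model$strand[1] == "-"
  ord <- order(if (minus) -ex$start else ex$start)
  ex <- ex[ord, ]
  list(starts = if (minus) ex$end else ex$start,
       ends = if (minus) ex$start else ex$end)
}
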