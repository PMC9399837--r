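---
title: "Methods: frame determination, domain retention, and the triage cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frame determination, domain retention, and the triage cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusetriage)
```

## Scope and model

`fusetriage` operates downstream of fusion calling. Its inputs are
breakpoint-level fusion calls (with split-read and discordant-mate support,
optionally raw reads carrying molecular barcodes), a transcript annotation,
a protein-domain table, a known-fusion database, and sample metadata. Its
job is the decision layer: is each call an artifact, a passenger, a known
oncogenic fusion, or a novel candidate worth follow-up?

### Coordinate conventions

Coordinates follow the GTF convention (1-based, inclusive). The 5'
breakpoint is the **last retained** genomic base of the 5' partner; the 3'
breakpoint the **first retained** base of the 3' partner. This matches how
exon-junction fusions are reported by callers and makes exon-boundary
arithmetic exact: a breakpoint at the end of exon *k* retains exactly the
coding content of exons 1..*k*.

Each gene is represented by one canonical transcript — the one with the
longest coding sequence (ties broken by transcript id). Fusion callers and
panel pipelines rarely disclose isoform choice, so a deterministic
convention is preferable to silent multiplicity; it can be revisited by
supplying an annotation restricted to the desired isoforms. CDS features
are assumed to exclude the stop codon (Ensembl convention), so retained-
protein arithmetic satisfies `floor(c/3) = residues` without special-casing
the terminal codon.

Intronic breakpoints snap to the nearest retained exon boundary (5' side:
end of the preceding exon; 3' side: start of the following exon), because
the observed fusion transcript is spliced; the `in_intron` flag is kept for
reporting. Genes without an annotated CDS yield `noncoding` junctions.

### Frame and domains

With `c5` = retained 5' coding nucleotides and `c3` = excluded 3' coding
nucleotides, the chimeric ORF preserves the 3' partner's reading frame iff
`(c5 - c3) mod 3 = 0`. The junction codon split across the partners is
attributed to neither protein: retained intervals are `[1, floor(c5/3)]`
and `[floor(c3/3) + 1, L3]`. This is conservative (a hybrid junction
residue never counts toward a domain) and deterministic.

Two configurations bypass the congruence. When both breakpoints precede
their partners' coding sequences, the 3' gene's entire protein is expressed
from the 5' partner's regulatory context: a **promoter swap**. Such calls
are frame-pass — enhancer-hijacking activation of an intact kinase is a
bona fide oncogenic mechanism, and the cohort fixture contains one such
case. When the 3' partner has no CDS the junction is `noncoding` and is
treated like an out-of-frame call.

Domain retention is a trichotomy by interval containment: `intact`
(domain ⊆ retained), `lost` (disjoint), `truncated` (otherwise). The
functional filter asks whether the *driver* partner keeps the domain class
its gene role requires — kinase domain for protein-kinase genes,
transactivation or DNA-binding domain for transcription-factor genes. Genes
of class `other` impose no requirement. When no partner is a kinase or
transcription factor, or no relevant domain is annotated, the verdict is
`indeterminate_pass`: the domain criterion is exclusionary only, since an
absent annotation is not evidence of a lost function.

### Support and deduplication

Split-read support counts **unique fragments**: raw reads sharing a
molecular barcode (UMI) collapse to one fragment
(`unique_fragment_count()`). The deduplication key is the barcode alone.
A call is low-support when, simultaneously, unique split fragments < 10
and discordant mates = 0; the discordant criterion is literal equality
with zero (configurable via `low_support_max_discordant`).

### The cascade

`classify_call()` applies, in order: artifact screen (mispriming flag;
read-through; breakpoint proximity < 1 Mbp on the same chromosome, strict
inequality), dual-caller confirmation (only when a second caller stream is
supplied — the tool must remain usable on one stream), support screen,
frame, domain, database lookup. Support and frame failures both accumulate
into the reason list (a junction can be simultaneously low-support and
out-of-frame); the domain check runs only when the frame admits a protein
product, so out-of-frame calls are never additionally labelled
`domain_lost`. Order affects only the recorded reasons, never membership of
the oncogenic classes, which is asserted by test.

The read-through rule had to be made concrete: same chromosome, same
strand, 5' gene transcriptionally upstream of the 3' gene, with an
intergenic gap of at most `readthrough_max_gap` (default 200 kb). Published
pipelines exclude read-throughs by manual review without an operational
definition; the gap bound restricts the rule to plausible
transcription-continuation neighbours rather than any collinear pair.
Mispriming is accepted only as an upstream annotation flag; no primer
heuristic is attempted.

Known-fusion lookup is orientation-sensitive: the 5'/3' roles decide which
partner donates the promoter and which the effector domain, so a
reciprocal pair is a different biological object.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_split_reads` | 10 | unique fragments | low-support threshold |
| `low_support_max_discordant` | 0 | read pairs | conjunct of the low-support rule |
| `min_breakpoint_distance` | 1e6 | bp | same-chromosome proximity artifact |
| `min_sample_unique_reads` | 10 | reads | sample QC (indeterminate below) |
| `bp_tolerance` | 10 | bp | dual-caller breakpoint matching |
| `readthrough_max_gap` | 2e5 | bp | read-through geometry bound |

The first four encode the study's stated criteria; `bp_tolerance` and
`readthrough_max_gap` are this package's own conservative readings of
"confirmed by a second caller" and "read-through", respectively.

## Cohort-level reporting

`cohort_report()` summarises a classified cohort: per-diagnostic-group
detection frequency (denominator = all enrolled patients in the group,
including sequencing failures, matching how such tables are printed),
fusion recurrence (distinct ordered pairs among oncogenic-class calls,
sorted by sample count then name), and the unknown/novel inventory.
Frequencies are rounded half-up to integer percent; computing 5/9 gives
56%, and where a source table and its narrative disagree (57% vs 56%) the
count-derived value wins.

The unknown-fusion count is evaluated against the *pipeline* databases
(the `source` column of the known-fusion table distinguishes fusion-caller
databases from literature curation): pairs absent there are "unknown", and
a pair later found in the literature (the fixture's ESR1-NCOA3) is removed
from the novel list without re-entering the unknown count. This mirrors
the two-stage lookup of panel practice: automated database matching first,
manual literature review second.

## The synthetic cohort

The generator serves two distinct needs.

`build_paper_cohort()` is deterministic: 165 samples in 14 groups with the
published group sizes, 5 sequencing failures, one call per fusion-positive
sample matching the per-group fusion inventory, the documented
split/discordant supports for the eight novel fusions (175/0, 87/5, 110/0,
97/0, 151/21, 37/3, 11/0, 87/5), the three passenger cases
(SS18-GREB1 domain loss; PDZD2-AKT2 intronic, out-of-frame, low support;
KIF13A-PIK3CA out-of-frame), and three artifact decoys. Support counts not
documented per sample are drawn uniformly from 20–200 split reads and 0–30
discordant mates under a fixed internal seed — any value above the support
threshold is equivalent for every reported count — so builds are
byte-identical. Gene placement puts 5' partners, 3' partners, and decoy
geometries on separate chromosomes, so only the decoys can trip the
proximity and read-through rules.

Breakpoints are not published for the cohort fusions (except the documented
PTPRG exon 13 / RAF1 exon 7 junction, which the fixture reproduces
exactly: c5 = 1560, c3 = 720). Fixture genes therefore use a regular
template — 14 exons of 120 coding nt, 200 nt UTRs, 1 kb introns — with
deviations only where an outcome requires them: a 121/119 nt exon pair
creates the out-of-frame boundary for KIF13A and PDZD2; an early SS18
breakpoint strands the QPGY transactivation domain (residues 300–387)
outside the retained interval for SS18-GREB1 while the later SS18-SSX
breakpoints keep it; a UTR-to-UTR junction realises the ZNF462-MUSK
promoter swap. Every placement is verified at build time by an independent
base-by-base codon walk; a mismatch aborts the build.

`simulate_cohort()` is randomized with planted ground truth: each sample
receives one call whose attributes realise a class drawn from a
configurable mix (default: 8% read-through artifacts, 8% proximity
artifacts, 16% low-support, 16% frame, 12% domain passengers, 24% known,
16% novel). Because the cascade is a deterministic function of the
generated attributes, classification must recover the planted class for
100% of calls — the test suite asserts this on a 500-call cohort — and
identical seeds produce byte-identical files.

What the generator does *not* emulate: sequence-level reads, splice-site
context, expression levels, multi-fusion samples, caller disagreement
beyond presence/absence, and breakpoint uncertainty. Passing tests
therefore demonstrate the correctness of the decision layer given faithful
call-level inputs, not robustness to upstream calling errors.

## Numerical and degenerate-input choices

- Tie-breaks are lexicographic everywhere (canonical transcript by CDS
  length then id; recurrence by count then fusion name), so outputs are
  order-insensitive and byte-stable.
- Rounding of percentages is half-up (base `round()` is banker's).
- Empty inputs are valid: an empty GTF yields an empty annotation, an
  empty call table an empty result, an empty database makes every pair
  unknown.
- A domain interval exactly equal to the retained interval is `intact`
  (containment is non-strict).
- `c5` at the CDS end equals 3 × protein length; a 3' breakpoint at the
  CDS start gives `c3 = 0` (full protein retained).

## Problem sizes

The deterministic cohort is 165 samples / 74 calls / 66 genes and runs in
seconds. Property suites use all exon-boundary pairs of the fixture fusion
partners for the frame oracle, a 500-call randomized cohort for
planted-class recovery, and 240 attribute combinations for the cascade
truth table.

## Known limitations

- One canonical isoform per gene; no cross-isoform domain lift-over.
- Domain coordinates refer to the canonical transcript's native protein.
- The read-through rule is geometric; it cannot recognise read-throughs
  between non-adjacent genes, which remain a manual-review item.
- Intragenic deletion isoforms (same gene both sides) reuse the same
  arithmetic but are only lightly exercised by the fixture.
- Sample QC is per-sample, not per-target-region; a per-region unique-read
  criterion would need region-level counts the call tables do not carry.
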