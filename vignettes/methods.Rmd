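---
title: "Profiling 5-hmC enrichment peaks over genomic elements: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling 5-hmC enrichment peaks over genomic elements: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcpeaks)
```

## The analysis problem

5-hmC enrichment sequencing pulls down hydroxymethylated DNA fragments;
after alignment and peak calling, the biological questions are positional and
functional: are peaks concentrated in exons, introns, or the regulatory
flanks of genes, and do hydroxymethylated genes share functions that genes
devoid of the mark lack? hmcpeaks implements that downstream layer for
compact invertebrate genomes (the motivating organism is the water flea
*Daphnia pulex*, whose gene bodies are a few kilobases with 4–11 short
exons), together with the restriction-enzyme qPCR arithmetic used to
validate modification levels at individual loci. Peak calling, alignment,
and gene prediction are out of scope: the package consumes BED, GFF3,
bedGraph and gene→GO TSV files.

## Coordinates and data model

Internally every interval is a `GRanges` (1-based, closed) — the single
convention of the Bioconductor interval stack — and conversion happens only
at file boundaries: BED and bedGraph (0-based, half-open) are shifted on
read and write, GFF3 passes through unchanged. Using one internal convention
eliminates the off-by-one class of bugs; using the stack's native one lets
every overlap, union and complement go through IRanges rather than bespoke
code. Gene models are a body interval plus ordered, non-overlapping CDS
exons; the constructor enforces these invariants so downstream code can
assume them. When a GFF3 gene carries several transcripts, the one with the
longest total CDS is kept, ties broken by transcript id — a deterministic
rule that makes real-world annotations acceptable. UTRs are not modelled:
gene predictions in this setting are CDS-only, so the gene body is taken to
be the prediction span.

## The element map

The genome is partitioned into eight classes: merged CDS exons of all genes;
introns, defined as gene-body bases exonic in *no* gene; and strand-aware
flank windows of 1, 5 and 10 kb anchored at the TSS (upstream) and TES
(downstream), clipped to contig bounds. Three ownership rules matter and are
recorded in the map's metadata:

* **Priority.** CDS exons > introns > flanks. A base inside any gene's exon
  never counts toward another gene's intron or flank, which prevents the
  same base inflating both a genic and a flank total.
* **Cumulative nesting.** The 5-kb window contains the 1-kb window, and the
  10-kb the 5-kb. Tag counts therefore rise monotonically with window size,
  which is how published element tables of this kind behave (e.g. 1012 ≤
  2304 ≤ 2585 upstream tags). A `nested = "disjoint"` mode counts each flank
  peak only in the smallest containing window, for users who want
  annulus-style counts.
* **Cross-gene flank overlap.** Upstream windows of one gene may overlap
  downstream windows of its neighbour; such bases count in both sides'
  totals. No published resolution rule exists for this case; symmetric
  treatment is the least surprising choice and whether neighbouring gene
  bodies are removed from flanks (they are) is stated in the metadata so the
  convention is auditable.

Intergenic bases beyond 10 kb belong to no class and are reported as
unassigned diagnostics rather than as a ninth row.

Peak assignment follows the same priority: ≥ 1 bp of exonic overlap ⇒
`CDS_Exons` only; else intronic overlap ⇒ `Introns` only; else all flank
classes overlapped. Whole-interval overlap is the default criterion — no
summit information survives into a BED3 file — with a midpoint criterion
available as `criterion = "midpoint"`. Densities are tag count per class
divided by class kilobases; rounding (half-up, two decimals, matching the
published tables) is applied only at output, and the unrounded densities are
kept in an attribute so ratios are never computed from rounded values.

## PPKM and gene groups

PPKM — peaks per kilobase of protein-coding sequence per million peaks — is
the RPKM analogue for peak data:

$$\mathrm{PPKM} = \frac{n_\text{peaks}}{L_\text{coding}/10^3 \cdot
N_\text{total}/10^6}$$

Peaks are counted against the gene *body* (introns included) while the
normalising length is protein-coding only; this mirrors the definition's
wording ("density of peaks across gene body", normalised "to the length of
protein-coding DNA") and is switchable to exon-only counting
(`count_mode = "exon"`). The two functional groups are *void* — CDS exons
completely free of peaks — and *high* — PPKM at or above the cut-off
(default 10, inclusive per "equal or higher"). A gene can satisfy both when
intronic peaks drive its PPKM over the cut-off while its exons stay clean;
the tie goes to *high*, because the cut-off was designed to split genes into
two disjoint groups of comparable size. PPKM is invariant under joint
rescaling of gene counts and library size, which the tests assert by
construction.

Before scoring, peaks in pathologically deep regions can be removed: the
coverage mask takes bedGraph intervals with depth strictly above a threshold
(default 50×) and discards any peak overlapping the mask. Whether such an
exclusion is best applied to reads before peak calling or to called peaks is
ambiguous in practice; this package filters peaks, which is the only option
once peak calling is upstream, and says so here. When no coverage file is
supplied peaks pass through with a warning, since many peak sets arrive
pre-filtered.

## GO-term comparison

For each term annotated to at least one gene in each group (terms seen in
only one group are excluded — with no gene in one margin the comparison is
degenerate and such terms would be dominated by annotation sparsity), a 2×2
table of gene counts is tested with the two-sided Fisher exact test: the sum
of hypergeometric probabilities of all tables with the observed margins no
more probable than the observed one (relative tolerance 10⁻⁷). Fisher is a
design choice: the selection criterion in the motivating analysis is stated
only as "frequency significantly different", and the exact test is the
standard, enumeration-verifiable choice for small gene-set tables. Selection
uses the asymmetric raw cut-offs p ≤ 0.01 for high-enriched and p ≤ 0.05 for
void-enriched terms — deliberately uncorrected, reproducing the original
selection behaviour — while a Benjamini–Hochberg q is reported as an extra
column for users who want error-rate control. Frequencies count genes, not
annotation lines, and GO ancestry is *not* propagated: terms are used as
annotated, since nothing in the source analysis indicates ontology
expansion. Selected lists are ordered by enrichment ratio, the quantity
treemap areas are proportional to in the usual visualisation.

## Restriction-qPCR modification percent

The standard curve regresses mean CT on log₁₀ relative input over at least
three dilutions; efficiency is E = 10^(−1/slope) − 1, so a slope of −3.3219
gives E = 1 (perfect doubling). E in the percent formula

$$\% = \frac{100}{(1+E)^{\Delta CT}}, \qquad
\Delta CT = \overline{CT}_\text{digested} - \overline{CT}_\text{mock}$$

is a *fraction* (0.95, not 95): with E ≈ 1 the base is ≈ 2, and one cycle of
delay halves the protected fraction — the standard ΔCT algebra. Interpreting
it as a percentage would make the base ≈ 96 and the formula meaningless.
ΔCT uses arithmetic means of replicate CTs. Negative ΔCT (digested
amplifying earlier than mock) signals a pipetting or normalisation problem:
the percent is clamped to 100 and flagged rather than raised as an error,
since a batch report should not die on one bad well. Fewer than four
replicates per cell is likewise flagged, and E outside [0.6, 1.2] flags a
suspect curve. The three assay configurations (MspI/HpaII and TaqI/HpyF30I
for 5-mC at CCGG/TCGA; T4-BGT glucosylation + Epi-MspI for 5-hmC at CCGG)
are reported separately; each measures what its enzyme pair can see, and no
cross-assay deconvolution of 5-mC versus 5-hmC is attempted.

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with the statistical structure the analysis
assumes. `simulate_genome` places non-overlapping genes with 4–11 exons of
80–400 bp (the scale of the motivating genome's gene models) separated by
random gaps. `simulate_peaks` draws peak counts class-wise — multinomial
given a total, Poisson given intensities alone — over *disjoint placement
territories* (exons, introns, flank annuli, intergenic), and places each
peak entirely inside one territory interval. Containment is a deliberate
design choice: the generating class is then recovered exactly by the
assignment rules, so density-recovery tests measure sampling error, not
boundary leakage. The default intensity preset (0.61/0.27/0.08…0.02 per kb)
emulates the published density profile, giving an exon:intron ratio of
≈ 2.26 by construction. `simulate_go` plants per-group Bernoulli term
frequencies over a background independent of group; `simulate_qpcr` inverts
the percent formula to generate CT values with Gaussian noise (default four
replicates, 0.1-cycle noise, noiseless standard curve).

Every generator is a pure function of its seed: each derives an independent
substream from (seed, generator tag), restores the caller's RNG state, and
writes byte-identical files across runs. What the synthetic data does *not*
emulate: enrichment chemistry and antibody bias, read-level noise and
mapping artefacts, overlapping or nested real gene models, GC- or
repeat-driven coverage structure, and the correlated annotation structure of
the real GO graph. Passing tests therefore demonstrate that the
*arithmetic and rules* are correct under controlled truth, not that any
particular biological dataset will reproduce a given density table.

## Numerical choices and degenerate inputs

* Reported densities round half away from zero at two decimals, at output
  only; R's banker's rounding would disagree on exact ties.
* The exon:intron ratio divides unrounded densities; a zero intron density
  raises an error (undefined), a zero exon density returns 0.
* Empty peak sets yield all-zero density rows; single-exon genes yield empty
  intron sets; flank windows at contig edges clip to zero width silently.
* Fisher p-values come from `stats::fisher.test`, whose two-sided rule is
  exactly the enumeration definition above; the test suite checks it against
  an independent exhaustive enumeration on all tables with margins ≤ 12.
* Coverage masking is strict (> threshold), so depth exactly 50 survives.
* Tie-breaks (equal-CDS transcripts, equal enrichment ratios) fall back to
  lexicographic order so outputs are reproducible.

## Problem sizes used in the checks

The shipped tests and acceptance script run on deliberately small instances
chosen to make the statistics decisive: 100 single-contig genomes of 40 kb
for the per-base oracle equivalence, a 1-Mb ten-contig genome with 10⁴ peaks
for density recovery (three delta-method standard errors of the 2:1 target),
1000 null terms at 100 + 100 genes for type-I control, and 50–100 seeds for
the power and qPCR-recovery estimates. These sizes are the package's own
choices for fast, reproducible verification; all scale linearly if users
want larger replicates.

## Known limitations

* Flank totals double-count bases shared by the upstream window of one gene
  and the downstream window of another (documented convention; toggleable
  only by editing the element map).
* The "more than 27,000 peaks" style of headline count depends on the
  counting convention for nested windows; both cumulative (default) and
  disjoint counting are implemented because published tables are ambiguous
  on this point.
* Dataset-dependent results (absolute gene-group sizes, assembly statistics,
  locus-level bar heights) require the original reads and assembly and are
  deliberately not reproduced; the property suite covers the corresponding
  logic on synthetic data instead.
* The GO comparison treats annotations as flat labels; users wanting
  DAG-aware enrichment should export the gene groups to a dedicated
  ontology tool.
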