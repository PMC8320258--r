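---
title: "Methods: identifying antigen-specific TCRs from single-cell activation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying antigen-specific TCRs from single-cell activation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrscreen)
```

## The screening problem

Tumor-infiltrating T cells that recognize neoantigens — peptides arising
from tumor-specific somatic mutations — are rare, and isolating their
T-cell receptors (TCRs) is the bottleneck for TCR-engineered cell
therapies. The screen this package implements works directly on a
dissociated tumor specimen: sorted T cells are stimulated for a few hours
with autologous dendritic cells loaded with candidate antigens (tandem
minigenes or peptide pools), then run through droplet single-cell V(D)J
sequencing with targeted PCR enrichment of two activation markers
(IFN-γ, IL-2) and three lineage markers (CD4, CD8A, CD8B). A cell that
responds to its cognate antigen transcribes IFN-γ and/or IL-2 within the
stimulation window; its droplet barcode links those UMI counts to its
assembled TCR contigs.

The computational task is then:

1. reduce per-barcode contig tables to paired α/β receptors and call
   **clonotypes by exact CDR3β nucleotide identity** — the CDR3β junction
   is diverse enough to act as a natural barcode, and nucleotide (not
   amino-acid) identity keeps silent variants apart;
2. flag **activated cells** from marker UMIs;
3. remove **autoreactive clonotypes** — clonotypes with activated cells in
   the no-antigen negative control respond to the dendritic cells
   themselves and are not antigen-specific;
4. report candidate receptors per stimulation, classified **shared**
   (identical TCR in ≥ 2 activated cells) versus **unique** (one cell),
   because shared candidates are far more reliable than singletons, which
   are contaminated by sequencing errors and doublets;
5. compute **merged clonotype frequencies** across all of a specimen's
   conditions, dropping clonotypes detected only once before normalizing —
   most singletons are artifacts, and keeping them would deflate every
   real frequency.

## Cell and clonotype model

A cell's V(D)J evidence is summarized per barcode. A cell is *paired* when
it carries exactly one distinct productive CDR3β nucleotide sequence (one
or two productive α chains may accompany it — up to a third of mature
T cells carry two functional α chains, and both are reported for
candidates since only transduction can tell which one confers
specificity). Two or more distinct β sequences make the cell *mixed*
(doublet signature; excluded from clonotype membership entirely rather
than assigned to the stronger β), and no productive β makes it
*undetectable*. Identical duplicate β contigs (allelic duplicates) collapse
to the highest-UMI one and the cell stays paired.

Clonotypes partition paired cells by the exact CDR3β string; V/J gene
labels are carried for reporting only and play no part in identity. The
partition is an equivalence relation — every paired cell lands in exactly
one clonotype and counts are conserved — and is invariant to input row
order.

## Marker positivity rules

Counts are raw targeted-enrichment UMIs; no normalization is applied by
design. Lineage positivity uses the two-or-more-UMIs rule: CD4⁺ iff
`cd4 ≥ 2`; CD8⁺ iff `cd8a + cd8b ≥ 2`. The combined CD8 sum is the
permissive reading of "two or more CD4, CD8A or CD8B UMIs" (the
alternative, per-gene reading differs only for cells with exactly one UMI
of each CD8 transcript).

Activation cutoffs are configurable with defaults `ifng_min = 5` and
`il2_min = 5` UMIs, boundary-inclusive. Activated cells in this assay
typically show tens of UMIs while ambient background averages ~0.05 per
marker, so any cutoff between ~3 and ~9 separates the same cells; 5 was
fixed once as an order of magnitude below typical responder counts. An
IL-2-only cell (no IFN-γ) still counts as activated and is logged
separately. All rules are pure per-cell functions and monotone: raising a
count never removes a positive call.

## Candidate extraction and ranking

Candidates are per *(condition, clonotype)*: the same clonotype elicited
by two different stimulations yields two rows, deduplicated by key in
frequency reports. Support is the number of distinct activated paired
cells in the eliciting condition; `klass` is `shared` at support ≥ 2.
Ranking — which decides which unique candidates are worth synthesizing —
is: shared before unique, then descending support, then descending summed
IFN-γ UMIs over supporting cells, then lexicographic key. The IFN-γ
tie-break is this package's documented choice of "top" for unique
receptors; the screening practice it mirrors tested every shared receptor
but only a top slice of the uniques, so validation honors an explicit
tested flag.

Autoreactive removal is clonotype-level: one activated cell in the
negative control disqualifies the clonotype everywhere. The operation is
idempotent, and a control with zero activated cells removes nothing.

## Merged frequencies

All of a specimen's conditions are merged with condition-namespaced
barcodes; each clonotype's merged count is its paired-cell count summed
over conditions. Clonotypes seen once are dropped, and frequency is
count / retained cells (retained = non-singleton). The retained
denominator is the package's reading of "removed from the frequency
calculation"; a flag can switch to all paired cells. Shared candidates
can never be dropped (support ≥ 2 implies merged count ≥ 2); unique
candidates whose clonotype was detected once get `NA` frequency rather
than a fabricated value.

## Somatic variant hard filter

The upstream mutation-calling screen that feeds antigen design is out of
scope except for its hard filter, which is implemented exactly: tumor
depth ≥ 10, normal depth ≥ 10, VAF ≥ 10 %, tumor variant reads ≥ 4, all
boundary-inclusive, with every violated criterion reported per record.
"Read counts of 10 or greater" is read as total site depth per sample; a
per-allele reading is not recoverable from the rule's wording. VAF given
in percent is auto-detected (values > 1) and normalized with a message.

## The synthetic-data generator

No patient-level data accompany this design, so validation rests on a
droplet-level simulator whose structure mirrors what the analysis
assumes, plus six reference fixtures with planted ground truth.

`simulate_repertoire()` draws clonotypes with unique in-frame CDR3
sequences (Cys...Phe frame, no stop codons), a clonotype-frequency law
(power law with exponent 1.5 by default — tumor-infiltrating repertoires
are highly diverse with few cells per clonotype — or log-normal), a
CD4/CD8 lineage, and two productive α chains in one third of clonotypes.
`simulate_condition()` loads a stimulation: `target_recovery` barcodes
(defaults mirror a 10,000-cells-loaded / 6,000-recovered channel),
doublets at rate 0.04 (two whole cells merged: contigs and marker counts
summed), per-contig CDR3 substitution errors at 5 × 10⁻⁴ per nucleotide
(the process that manufactures singleton artifact clonotypes), Poisson
ambient marker background (mean 0.05 UMIs per marker per barcode), and
responder marker counts drawn from a left-truncated negative binomial
(floor 10, mean 50, dispersion 2). The truncation guarantees responders
clear the activation threshold structurally — activated cells in this
assay are well separated from background — rather than by seed luck; the
fixture noise levels in general are calibrated so planted counts are
recoverable, not to any instrument's published characteristics, because
none are available. Only about a third of a reactive clonotype's cells
respond (`responder_fraction = 1/3` by default); the rest model exhausted
cells. Lineage markers are Poisson (mean 4 split over the lineage's own
genes).

### The six fixtures

`make_fixture()` builds specimens `M1`–`M3` (melanoma-like: multi-pool
stimulations, optional pre-screen) and `CC1`–`CC3` (colorectal-like:
direct stimulation, no IFN-γ/IL-2 coexpression) with fixed documented
seeds, so their files are byte-identical across runs. Planted structure —
responder counts per condition, shared/unique candidate splits, one
autoreactive clonotype responding in every condition of M2, error-derived
artifact singletons, two genuinely reactive singleton clonotypes (CC2,
CC3), an IL-2-only cell in CC1, and a twin receptor pair in M2 differing
by two CDR3β amino acids and one silent CDR3α change — is written to
truth tables alongside the inputs. Activated cells whose TCR is
undetectable or mixed are planted too (13 of M1's 26 activated cells), so
the pipeline's exclusion logging is exercised. The pooled planted design
tests 19 shared candidates (all truly reactive) and 23 unique candidates
(9 reactive), 28 reactive receptors in all; the per-specimen split
(M1 2+4, M2 9+0, M3 3+5, CC1 4+7, CC2 1+4, CC3 0+3 tested shared+unique)
is one consistent choice among the partially determined possibilities and
is pinned in the truth tables rather than inferred.

Merged retained-cell totals are planted per specimen (M1: 5,000 — chosen
so its top candidate clonotype of 15 cells sits at 0.30 % — and 6,000,
4,000, 6,000, 3,000, 2,500 for the others), with background repertoires
built deterministically: a few >1 % clonotypes, a power-law body, a tail
of doubletons, plus planted singleton clonotypes.

### What the simulator does not emulate

Read-level errors and assembly, transcriptome-wide expression, chimeric
PCR artifacts, barcode collisions, cell-cycle or stress covariation of
markers, and biologically structured V/J usage are all absent. Passing
the fixture suite therefore shows the *analysis logic* is correct under
the stated noise model; it does not certify performance on real
instrument output, where thresholds in particular may need the optional
control-derived setting rather than the defaults.

## Validation statistics

`evaluate_candidates()` marks a candidate reactive iff its clonotype key
is truth-flagged reactive (and not autoreactive); per-class precision is
reactive/tested over tested candidates, reported in percent (rounded to
integers in text reports; raw fractions are kept in machine-readable
output). Pooled precisions are recomputed from pooled counts, never
averaged. With the error and doublet processes disabled, unique-candidate
precision is 100 % by construction — the property suite demonstrates that
sub-100 % unique precision is purely a noise phenomenon.

## Numerical and engineering choices

* Determinism: everything downstream of simulation is free of randomness;
  reruns are byte-identical and row-order-invariant. Simulation is
  seeded, with the RNG state restored afterwards.
* Ties: representative β contig per cell by highest UMI then contig id;
  representative member per clonotype by highest UMI then barcode;
  candidate α chains by supporting-cell count, then UMIs, then sequence.
* Degenerate inputs: empty contig tables, marker-only barcodes,
  contig-only barcodes, all-singleton frequency tables and empty tested
  classes (precision `NA`, never 0) all have defined behavior.
* Problem sizes: fixtures hold ~2,500–6,400 paired cells per specimen
  across two to four conditions; the whole six-specimen
  simulate → screen → validate suite runs in well under a minute on one
  core, and the test suite's property checks use instances of up to 500
  cells with brute-force oracles.

## Known limitations

* The IFN-γ/IL-2 cutoffs and the unique-candidate ranking rule are
  documented package choices, not published constants.
* Cells with two productive β chains are discarded rather than rescued;
  at higher doublet rates this loses real responders.
* Frequencies use the retained-cell denominator; comparisons against
  pipelines that keep singletons need the alternative flag.
* The tested-subset bookkeeping lives in fixture truth tables; applying
  the package to real data requires recording which candidates were
  actually synthesized and tested.
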