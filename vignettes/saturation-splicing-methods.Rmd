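---
title: "Methods: saturation interpretation of coding-SNV splicing impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturation interpretation of coding-SNV splicing impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satsplice)
```

## The problem

A single-nucleotide variant inside a coding exon can disrupt pre-mRNA
splicing — by weakening the donor or acceptor signal at an exon boundary, or
by creating a competing cryptic site — even when its protein-level annotation
reads "missense" or "synonymous". For a small, clinically important gene it
is feasible to interpret *every* possible coding SNV prospectively: enumerate
all `3 × L` substitutions, triage them with an in-silico splice predictor,
assay an informative subset in a full-length gene splicing assay (FLGSA),
calibrate the predictor's decision cutoff against the assay labels, and
extrapolate to the untested remainder. `satsplice` implements that pipeline
end-to-end and ships it worked for the four-exon SPINK1 gene (240 coding
nucleotides, 720 possible coding SNVs, 67 of them assayed), the gene in which
loss-of-function variants predispose to chronic pancreatitis.

## Gene model and coordinates

A `gene_model` stores per-exon coding (cDNA) spans and genomic anchor spans,
the strand, and the set of splice sites documented across transcript
isoforms. All public coordinates are HGVS-style, 1-based inclusive; intronic
positions use the nearest-boundary `c.N+M` / `c.N-M` form (midpoint ties in
an intron break toward the upstream exon — the tie never arises in the
packaged gene but must be deterministic). Because intron lengths are defined
by the gaps between exon genomic spans, the pre-mRNA is one contiguous
genomic block and both coordinate maps are exact inverses; on the minus
strand the map is order-reversing. UTR positions are deliberately out of
model: the analysis concerns coding SNVs, and rejecting `c.0`/`c.L+1` early
catches off-by-one errors in score tables.

Pre-mRNA offsets attached to predictor scores follow the sense-strand
convention: a positive offset points 5'-ward. `shift_on_premrna()` counts
distance on the pre-mRNA (introns included), so an offset can carry a
position across an exon boundary into `c.N+M` territory.

## Saturation enumeration and consequences

`enumerate_snvs()` emits exactly three variants per coding position. Protein
consequences are called codon-wise against a CDS assembled in cDNA order, so
codons spanning exon junctions (SPINK1's Gly19 codon straddles exons 1/2)
need no special casing; a property test re-chunks one CDS into different exon
structures and demands identical calls. Variants in the first and last codon
are classed `initiation_codon` / `termination_codon` regardless of the
amino-acid effect, keeping the five classes a true partition of `3 × L`. The
classifier is validated against an independent oracle that mutates the whole
CDS string and translates it in full with Biostrings.

The packaged `spink1_synthetic_cds()` is a synthetic scaffold, not the real
CDS (no sequence databases are fetched): it is constrained to reproduce the
reference base and the published protein annotation at every position touched
by the 67 assayed variants and the additionally discussed exon-1 positions,
with arbitrary filler elsewhere. Consequence calls at assayed positions are
therefore exact, while genome-wide class totals (e.g. the full
missense/synonymous split) are scaffold properties and are not reported as
SPINK1 results; the partition *logic* is what the oracle-equivalence tests
certify.

## Score ingestion and the physiological-relevance filter

Each variant carries four delta scores in `[0, 1]` — acceptor gain/loss,
donor gain/loss — with offsets reported when a score reaches the table's
0.10 threshold. The filter's premise: a *loss* score is only meaningful if
the site it claims to destroy actually exists, i.e. resolves to a boundary in
the documented isoform splice-site whitelist. In SPINK1, several exon-1
variants carry donor-loss scores up to 0.55 pointing at the GT dinucleotide
at c.7_8, which no documented isoform uses as a donor; the filter masks
those, leaving e.g. c.26T>G with a maximum relevant score of 0.03 instead of
0.29. Gain scores are never masked — a new site can arise anywhere, and the
screen's cryptic-gain candidates were evaluated, not excluded. Loss-site
matching is exact to the annotated boundary (configurable tolerance,
default 0); every physiologically relevant loss in the packaged tables
resolves exactly to a boundary. Scores below the reporting threshold lack an
offset, stay formally relevant, and cannot cross any decision cutoff at or
above 0.20, so the choice is inert. A loss whose offset escapes the modeled
region is masked; an unresolvable gain stays relevant with a flag. An AL
resolving to a donor (kind mismatch) is masked and logged — the underlying
data never exhibit it, so masking is the conservative reading. The variant's
summary statistic is `max_relevant`, the highest surviving score, with the
driving channel reported under a fixed DL > AL > DG > AG tie-break (purely
for deterministic reporting).

## Candidate selection

Selection is the union of four explicit rules (boundaries, score cutoff,
per-exon top-k donor gains, controls/manual additions), each selected variant
tagged with all its reasons. The screen's judgment calls — the c.9 negative
controls, the c.43 and c.84 companions — are configuration, not inference:
no mechanical rule reproduces "we deliberately added comparators", and
pretending one does would overfit the packaged gene. With the packaged rules
the selection is a strict superset of the 35 prospectively assayed variants
(47 in total: the rules also nominate the previously assayed boundary
variant c.194G>A and the above-cutoff variants that the screen resolved by
extrapolation instead). Selection size is provably non-increasing in the
cutoff, which the property suite asserts on synthetic screens.

## Assay outcomes

An outcome is a set of transcript species with band intensities: normal,
exon-skip, intron-retention (with retained length), or other, with a flag
for bands known to contain both isoforms through hybrid-dimer formation (the
flag is carried but ignored in ratio arithmetic, matching how the published
densitometry was done). Classification drops bands below 10% of the
strongest (`faint_band_policy`; the rationale is that a variant retaining
over ~90% of normal transcript is unlikely to be pathologically
significant) and then reads the surviving species: `normal_only`, `mixed`,
or `aberrant_only`. The densitometric aberrant/normal ratio is
scale-invariant and reported in the conventional `x/1` / `1/x` style. The
packaged outcome table stores the *printed* classes and ratio strings as
ground truth; intensities are normalized so each mixed variant's bands
reproduce its printed ratio exactly. Note one deliberate asymmetry: the
printed class is authoritative even where re-deriving it from intensities
under the default policy would differ (c.55G>C, ratio 1/21.72, keeps its
splice-altering label although its aberrant band sits below the 10% line);
the round-trip property is therefore stated, and tested, for ratios within
the policy's representable band.

## Calibration and extrapolation

Labels are binary — splice-altering = mixed or aberrant_only — and the
classifier is a single threshold on `max_relevant`, so sensitivity is
non-increasing and specificity non-decreasing in the cutoff (asserted over
the whole grid). On the 67 assayed variants, moving the cutoff from the
conventional 0.20 to 0.30 keeps sensitivity at 12/12 while specificity
rises from 43/55 to 50/55. The recommended cutoff is the smallest grid value
maximizing Youden's J — a reproducible statistic in place of qualitative
reasoning, with ties broken toward the more sensitive side; on the packaged
data it lands on 0.30. Three empirical band edges summarize the
outcome-vs-score scatter: the smallest altering score (0.31), the largest
normal_only score (0.61), and the smallest score among complete-aberrance
outcomes (0.92). These are reported as-is; under perfect class separation
the first can exceed the second, so no ordering is enforced.

Extrapolation is deliberately conservative. An untested variant is cleared
only if its maximum relevant score is below the 0.20 floor, or an assayed
normal_only comparator — same coding position preferred, otherwise same exon
and same driving channel — scored at least as high; among adequate
comparators the one with the *smallest* score is cited, since the closest
resemblance is the informative one. Every call records its basis. On the
packaged data all 653 untested variants clear: 646 by the floor, seven
exon-1 donor-gain variants (scores 0.20–0.24 at the c.7_8 pseudo-site) by
comparators (c.11C>T through the same-position c.11C>G, donor gain 0.44; the
rest through c.37G>T, donor gain 0.23, normal_only).
The ratio-vs-score relationship within positions assayed in triplicate is
reported as a rank-concordance table rather than a fitted model, because a
single discordant pair among so few points would dominate any regression.

## Donor-signal scoring

The 9-bp 5' donor signal window (last 3 exonic + first 6 intronic bases)
pairs position-wise with the U1 snRNA 5'-end sequence, written 3'→5' as
`GUCCAUUCA`; windows stay in the DNA alphabet with T≡U, alignment is fixed
with no shifts, and N counts as non-pairing. Since each U1 base has a unique
Watson–Crick partner, the pair count equals 9 minus the Hamming distance to
the consensus `CAGGTAAGT` — the independent oracle the tests use. The
packaged regional sequence is synthetic (the reference genomic sequence is
not redistributed) and is constructed to reproduce the documented pairing
counts: physiological intron-1 donor 8/9, the experimentally activated deep-
intron cryptic donor at c.55+141_142 8/9, and the in-silico-favoured c.7_8
pseudo-donor 6/9, rising to 7/9 under c.11C>G. A PWM hook accepts a
user-supplied 9×4 log-odds matrix; none ships with the package.

## Synthetic-data generator

The generator emulates the structure the analysis assumes, with defaults
fixed once: four exons of 30–110 nt, introns of 200–2,000 nt, random strand;
background scores half-normal at scale 0.02, truncated below the 0.10
reporting threshold so background never acquires offsets; elevated loss
scores uniform on [0.2, 0.95] at the three SNVs of every internal boundary
position, offsets resolving to the true site; a 5% share of non-boundary
SNVs planted with equally high but irrelevant losses (offset resolving to
the variant's own non-site position); labels from a latent threshold of 0.30
with 2% flip noise; and a logistic score-to-aberrant-fraction link centred
at the midpoint of the boundary-effect support (weakly monotone — enough to
reproduce the qualitative ordering claim without overcommitting to a shape).
Fractions above 0.95 emit as complete aberrance, mirroring how a minor
normal band disappears from a gel. Emitted splice classes are read from the
generated bands with the same faint-band policy as real readouts, so a label
flip whose linked aberrant fraction is too small to show as a band stays
invisible — observable label noise is the noise a gel could actually
display, which is what keeps threshold recovery well-posed. One seed drives
the run, with fixed per-stage sub-seeds, so emitted fixture sets are
byte-identical across calls.

What passing synthetic tests shows — and does not. The generator reproduces
the *location* of signal (boundaries), the background sparsity, the
existence of irrelevant losses and a monotone score/outcome link. It does
not attempt realistic SpliceAI score distributions, sequence-dependent
effects, or assay artefacts beyond faint bands; recovery of the latent
threshold on synthetic screens certifies the calibration machinery, not the
biological accuracy of any particular cutoff on real genes.

## Numerical choices and problem sizes

Cutoff grids default to steps of 0.05 on [0, 1]; recovery claims are "within
one grid step". Youden ties break toward the smaller cutoff. Ratio
round-trips are exact to 1e-9 relative. Property suites run 5–10 random
models or seeds per claim and 1,000–10,000 random windows for the pairing
oracle — sizes chosen so the whole suite exercises every contract while
remaining a desk-scale run. Degenerate inputs error early and descriptively:
empty label sets, one-class label sets, zero intensities, escaping offsets,
truncated signal windows, malformed species tokens.

## Known limitations

* Real-sequence results (the exact missense/synonymous totals, real window
  sequences) require the actual CDS and genomic sequence; the shipped
  scaffolds are constrained stand-ins, clearly labelled synthetic.
* The relevance filter depends entirely on the documented isoform
  splice-site whitelist; an incomplete whitelist would mask genuine losses.
* Extrapolation comparator logic assumes the assayed set spans the score
  range of the untested set within each exon and channel; for a new gene
  with sparse assays, expect `indeterminate_assay_recommended` calls.
* The binary altering/non-altering label discards the ratio magnitude;
  clinical weighting of partial aberrance is out of scope.
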