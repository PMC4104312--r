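---
title: "Delineating and classifying PIN protein architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating and classifying PIN protein architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinarch)
```

PIN auxin efflux carriers have a tripartite architecture: an N-terminal
bundle of five transmembrane helices, a central intracellular loop, and
a C-terminal bundle of five more helices.  `pinarch` turns the analyses
that characterize this architecture — domain delineation, conservation
profiling, loop-motif scanning, canonical classification, helix
topology, and origin counting — into a tested pipeline.  This vignette
explains the model behind each stage, the defaults and why they were
chosen, and what the synthetic-data generator does and does not
emulate.

## Coordinates and domain delineation

All user-facing coordinates are 1-based inclusive, the natural
convention in R and the one in which canonical positions are labelled
(N1…N158, C1…C154; 312 assessed transmembrane positions in total).

Two short anchor motifs delimit the domains: the N-domain runs from the
initiator **to the end of** `FLFEFRAAR`, the C-domain **from the start
of** `VWRKLIRN` to the stop.  The literature leaves open whether the
anchors belong to the membrane domains or the loop; we include them in
the domains because that choice makes complete canonical domains come
out at their modal lengths of 158 and 154 residues.  Anchor search is
an exhaustive substitution-count scan; "or variant" is operationalized
as at most `max_subs = 3` mismatches (configurable), with ties broken
toward the expected region (start near position 150 for the N-anchor,
154 from the C-terminus for the C-anchor).

Complete N-domains longer than 158 residues are treated as carrying an
insertion between N97 and N98, where almost all observed insertions
(up to 18 extra residues) sit; longer surpluses are additionally
flagged `atypical_n`.  Sequences without a complete N-terminus never
receive a label N1 — they are counted backwards from the anchor, which
is pinned at N158.  This keeps partial EST-derived fragments on the
shared coordinate system without guessing their true start.

Loops of at most 120 residues are classed *short* (the observed
noncanonical range is 32–120), loops over 150 *long*, the gap in
between *intermediate*, and loops flanked by a missing anchor
*unknown*.

## Conservation profiles and bands

Per-position profiles count residue frequencies over the sequences that
observe each canonical position; `-`, `?` and `X` are missing and drop
out of the denominator, and insertion residues never contribute to
canonical positions.  Because EST-heavy data leave many positions
thinly covered, band counting excludes positions under a minimum
coverage (default 10 sequences) and reports them separately.

Two band schemes ship with the package: the *cross* scheme (100%,
>99%, >95%, >90%) used for conserved canonical positions and their
retention in noncanonical groups, and the *self* scheme (100%, 95–99,
90–95, 70–90, 50–70, <50) used for within-clade self-identity.  Bands
are open at the lower edge and closed at the upper, with 100% its own
band — so identity exactly 0.90 falls in 70–90%, and ">99%" means
above 0.99 but below 1.  Published counts are ambiguous about whether
"near-invariant" includes the invariant class, so reports always carry
both the 100% band and the >99% band side by side.

## Loop motifs and their states

The canonical loop is an ordered series of motifs.  A motif library is
an ordered table of patterns (wildcard `X` matches anything and is
excluded from identity denominators; `[SN]` style brackets allow
alternatives).  Scanning assigns each motif its best gapless window
subject to the order constraint — a maximum-weight increasing
assignment solved by dynamic programming and verified in the tests
against exhaustive enumeration on small instances.

Presence states and their defaults (all configurable, all recorded in
the run manifest; the thresholds themselves are package choices, since
the published analysis assigned states by inspection):

* **present** — window identity ≥ 0.70;
* **present but divergent** — similarity ≥ 0.40 (identical or
  positively scoring under BLOSUM62) *and* identity ≥ 0.40, the window
  sitting in order between located neighbours.  The identity floor
  keeps random spacer windows, which reach similarity 0.4 by chance
  surprisingly often, from masquerading as divergent motifs;
* **partially present** — a clipped window at a truncated loop edge
  covering at least half the motif at present-level identity;
* **no data** — the loop is truncated over the motif's span;
* **absent** — otherwise.

Clade-level matrices take the strict-majority state over members with
data; when no state exceeds half, the cell reads *no consensus*.  (The
50%-exactly case counts as no consensus: two of four members do not
make a majority.)

The repeated trio of motifs around HC2 (led by the phosphorylated
TPRXS[S/N] element) is counted by a greedy left-to-right scan requiring
each unit motif present-or-divergent in order within a bounded gap.

## Canonical classification

A protein is **canonical** when all four highly conserved regions
HC1–HC4 are located in order in its loop and the pooled identity over
their consensus columns is at least 0.50 *or* the pooled similarity at
least 0.70 (thresholds inclusive).  We read the published rule as
pooled over the concatenated regions because its worked example applies
an identity percentage to a single region; a per-region strict mode is
available behind `strict_regions = TRUE`.  "Similarity" is not defined
in the source analysis; we use the fraction of columns identical or
positively scoring under BLOSUM62, the standard log-odds table.  A
region counts as *located* when at least half of its consensus columns
match (`locate_min = 0.50`); a lower threshold lets random windows in
long loops pass, which inflates semicanonical loops into canonical
ones.

**Semicanonical** proteins keep loop homology (at least two regions
located and passing per-region) but lack at least one region —
the structure of the PIN6/PIN12 type.  Everything else with enough
data is **noncanonical**; sequences whose loop exposes under half of
the pooled consensus columns are **insufficient data**.

Clades are canonical when ≥90% of informative members are (strict
majority under ten members), noncanonical symmetrically.
Semicanonical members count on the noncanonical side of the clade
rule; this choice is surfaced in the run manifest.

## Helix topology

Hydropathy is the Kyte–Doolittle scale smoothed with a centred
19-residue window (ends truncated, no padding).  Helices are maximal
runs of at least 7 positions above a cutoff, merged across dips
shorter than 3.  The expected count is five per domain; starting from
a cutoff of 1.6 the threshold relaxes in steps of 0.1 down to a floor
of 0.5 until the expected count appears, and helices that only emerge
below the primary cutoff are flagged **cryptic**.  These parameters
are transparent replacements for an external HMM predictor followed by
manual reanalysis of its hydrophobicity traces; the published criterion
for a cryptic peak is not stated, so the schedule above is a package
default, not an inferred value.

## Origins of noncanonical structure

Structural states binarize as canonical = 0, noncanonical or
semicanonical = 1 (both represent loss of at least one HC region).  A
Sankoff-style dynamic programme minimizes state changes on a rooted
clade cladogram with the root fixed canonical — a single canonical PIN
in the last common ancestor.

Reversals deserve a design note.  Noncanonical structure is the loss
of the modular loop, and regaining a lost modular loop is not a
plausible single event, so the default model forbids 1→0 changes
(`reversals = "none"`); the origin count is then the minimum number of
independent losses.  Under the alternative equal-cost model
(`reversals = "equal"`, total changes minimized first, 0→1 edges
second) the bundled reference cladogram admits a labeling in which the
PIN5 and PIN12 origins merge through an ancestral loss and a reversal
in the gymnosperm PINI clade — giving six origins instead of seven.
The seven-origins statement therefore rests on irreversibility, which
is why it is the default.  Both modes are verified against exhaustive
enumeration over all internal labelings on hundreds of random trees.

The bundled cladogram (`reference_cladogram()`) encodes the clade
arrangement stated in the text sources: Eu1 = PIN5 + (PINI, PIN12);
Eu2 = the monilophyte PINK–PINN group sister to PIN6; PIN9 arising
from within the PIN1 clade inside Eu3; Lyco1 + Lyco2; and the
bryophyte proteins as a basal grade with PIND beside the moss
canonical PINA and PINW/X/Y beside the Marchantia canonical PINZ —
the long-branch-attraction reading under which the "BNC" grouping is
artifactual and each bryophyte noncanonical lineage arose
independently.  The within-lineage branching is an interpretation
(the published figure is an image); the tip set and states ship as
editable text fixtures.

Long-branch flagging compares each clade's median MRCA-to-tip path
against the median of that quantity over all tips; the default ratio 2
is a package choice.

## The synthetic generator

`generate_family()` produces a family with full ground truth.  Its
defaults *are* the emulated study conditions, chosen once from the
published numbers and not revisited:

* 473 sequences in the 25 reference clades, with the published
  subgroup sample sizes for PIN1 (76), PIN5 (42), PIN6 (18) and
  PIN8 (15);
* family-wide transmembrane band counts 56 / 49 / 58 / 30 over the 312
  positions (the remaining 119 positions draw background identity
  0.55–0.90), with the anchors, the initiator and the invariant
  tyrosine at C123 forced invariant;
* within-clade band counts (174, 53, 11, 39, 19, 16) for the reference
  canonical clade, (50, 39, 42, 62, 76, 43) for noncanonical clades
  and (197, 0, 24, 44, 30, 17) for semicanonical clades — the last
  adjusted by one position in the lowest class to restore the 312
  total, which the published column does not reach under any parsing
  of its digits;
* insertions of 1–18 residues between N97/N98 in 15% of N-complete
  members; noncanonical replacement loops of 32–120 residues; loop
  noise 0.02 per residue; EST-style geometric truncation targeting 45%
  missing data.

Some design points worth knowing before trusting a passing test:

* **Substitutions are planted as exact counts among the members that
  observe a position** (and whose anchor survives, since profiling
  only sees anchored domains), so the realized band structure equals
  the configured one over observed data.  The alternative — Bernoulli
  draws per member — makes near-invariant bands unrepresentable at
  finite coverage and lets band fractions drift; the published
  statistics are themselves finite-sample observations, so planting
  counts is the closer emulation.  Near-invariant positions are
  assigned to well-covered positions, because a >99% band needs more
  than 100 observations to be expressible at all.
* **Family-wide substitutions are allocated clade-block-first** (whole
  clades carry a fixed difference, remainders scatter over members),
  emulating lineage-specific fixed differences; this is what makes
  within-clade self-identity much higher than family-wide identity, as
  observed.
* **Helix positions substitute only within hydrophobic residues, and
  non-helix positions only within polar residues.**  The first encodes
  the membrane constraint (and the observation that helices are the
  most conserved parts of the domains, with no major helix changes
  even in noncanonical proteins); the second keeps inter-helix spacers
  polar so that hydropathy peaks never merge or appear spuriously.
  Helix 3 of the template is deliberately weak (alternating V/T) so
  that it is only ever recovered as a cryptic peak.
* **Truncation is corrected to the target missing fraction** by a
  seeded adjustment pass (tolerance 0.005); fragments shorter than 100
  residues are redrawn, mirroring the discard rule for very short
  sequences.
* The canonical loop plants each copy of the HC2 trio as one
  contiguous block with spacers between copies, so the repetitive
  region is dense.

What the generator does **not** emulate: phylogenetically correlated
substitution (no tree-shaped evolution within clades; clade-fixed
differences are planted directly), indels inside domains other than
the N97/N98 insertion, alignment error, codon-level structure (the
published alignment statistics of 1,809 nucleotide columns and 1,690
parsimony-informative sites belong to a nucleotide alignment that is
consumed, not produced, by this package; `alignment_stats()` is
instead verified against its per-column definition), and biological
sequence composition beyond hydropathy.  A passing pipeline-closure
test therefore shows the implementation is faithful to its model, not
that the model captures every feature of real PIN data.

## Problem sizes and determinism

The test suite and the acceptance script run the full 473-sequence
conditions for the closure and reproduction checks, a ~90-sequence
family for module tests, and oracle comparisons on small instances
(anchor scans on hundreds of random sequences, order-respecting motif
assignment on loops of up to 60 residues with three motifs, exhaustive
origin enumeration on trees of up to 12 tips).  Every stochastic step
flows from a single integer seed through R's default generator;
identical configurations produce byte-identical outputs, and the
pipeline itself is deterministic given its inputs.

## Known limitations

Gapless window matching is used for anchors, motifs and HC regions;
indel-containing variants score as substitutions, which is adequate at
the divergence levels involved but would understate homology for
heavily gapped loops.  The loop profile uses loop-relative positions,
not a loop alignment.  Clade classification treats members as
exchangeable (no phylogenetic weighting).  The long-branch test is a
descriptive flag, not a rate model.
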