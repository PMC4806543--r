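---
title: "Dating and dissecting centromere repeat history with cenarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and dissecting centromere repeat history with cenarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenarch)
```

## The problem

Centromeres of many plants and animals are built from two repeat classes:
long tandem arrays of a satellite monomer (in maize, the 156-nt CentC
repeat) and centromere-specific LTR retrotransposons (CR elements).
Because double-strand breaks near the kinetochore are frequent, these
regions accumulate deletions, adjacent segmental duplications (visible in
satellite arrays as higher-order repeats, HORs), chimeric elements, and
inversions. Each such event leaves a datable molecular signature:

* a retroelement's two LTRs are identical at insertion and diverge
  afterwards at the neutral substitution rate;
* the two copies of a segmental duplication diverge the same way;
* a deletion repaired by alternative end-joining (MMEJ) leaves a short
  identical sequence — microhomology — at its junction.

`cenarch` implements this repeat archaeology as a reusable, testable
pipeline: repeat scanning and monomer extraction, LTR pairing and
molecular-clock dating, HOR detection/dating/boundary refinement,
breakpoint and microhomology analysis, windowed cenH3 ChIP enrichment,
assembly overlap QC, and a seeded generator that plants every one of
those signatures with known truth so the estimators can be validated by
parameter recovery.

## The dating model

For two homologous sequences we count, over the gap-free columns of a
global alignment, the transition proportion $P$ and transversion
proportion $Q$, and compute the Kimura two-parameter distance

$$K = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

Ages follow from a strict molecular clock,

$$t = \frac{K}{d \cdot \mu}, \qquad \mu = 3.3\times10^{-8}
  \ \text{substitutions site}^{-1}\text{yr}^{-1},$$

with divergence divisor $d = 2$: the two copies were identical at the
event and have each accumulated substitutions independently since, so
their pairwise distance grows at $2\mu$ per site per year. The rate is
the maize nuclear rate conventionally used for retroelement dating.

Numerical choices worth knowing:

* **Gapped and `N` columns are excluded** from $P$ and $Q$. A deletion in
  one copy therefore removes sites but does not add divergence.
* **Saturation** ($1-2P-Q \le 0$ or $1-2Q \le 0$) is a classed error, not
  a clamped value. Distance-matrix construction for bootstrap replicates
  may instead cap saturated pairs at a large finite distance so a single
  degenerate resample does not abort a replicate.
* **Identical copies** give $K = 0$ and a point estimate of 0 years. We
  additionally report `upper_bound_years`, the age at which one
  substitution would be expected across the compared sites,
  $t_{max} = (1/L)/(2\mu)$ for $L$ aligned sites. It is recorded as a
  bound, never as the estimate: a ~1 kb LTR pair that is still identical
  is younger than ~15 kya, it is not "0 years old".
* Pairwise global alignment uses affine gap scoring (match 1, mismatch
  −1, gap open 4, extend 1). On two sequences this plays the role a
  general-purpose multiple aligner plays in interactive work; for the
  substitution-dominated divergences the clock operates on (well below
  saturation) the alignment is essentially forced and the scoring
  details do not move $K$.

## LTR pairing filters

Only clean insertions are dated. A candidate element passes, in order:

1. **TSD match** — the 5 nt of host sequence duplicated on both sides of
   the element at insertion must agree (Levenshtein distance 0; a relaxed
   mode allows 1 edit, covering one mismatch or indel);
2. **terminal edges** — the first 2 nt of the 5' LTR must be the reverse
   complement of the last 2 nt of the 3' LTR (canonically `TG...CA`);
3. **same subfamily**, 4. **same orientation**;
5. **length ratio** — the shorter LTR must be at least 90% of the longer.

Each rejection records the first criterion failed. A structurally
complete element whose TSDs disagree beyond the tolerance is flagged
*chimeric*: it is the recombination product of two insertions and its
LTR divergence dates neither.

## HOR detection and dating

The package formalizes HOR detection, which in practice is often done by
eye on a tree, as a reciprocal-nearest-neighbour rule: monomers are
numbered 5'→3'; for an offset $d$, a run of at least two consecutive
indices $i$ where monomers $i$ and $i+d$ are mutual nearest neighbours in
the K2p distance matrix (and closer than `ratio_threshold` — default
0.5 — times the median pairwise distance) is an HOR with copies
$[i..j]$ and $[i+d..j+d]$. Ties in nearest-neighbour lookup go to the
smaller index; runs are trimmed so the copies cannot overlap; competing
candidates are resolved longest-run-first, then earliest start. This is
the positional-pairing pattern one sees in an NJ tree of the monomers of
an adjacent duplication, made algorithmic.

Dating an HOR uses only the *internal* monomers of each copy — the first
and last monomer of a copy may be recombinant at the duplication
breakpoints — concatenated in order and aligned copy against copy. An
HOR with two monomers per copy has no internal monomer and is reported
`undatable` rather than silently skipped. Monomers from inverted arrays
are strand-normalized before any alignment.

Boundary refinement moves the HOR borders from monomer-run ends to the
endpoints of the *longest* maximal exact match between the two copies'
neighbourhoods that is consistent with the duplication offset (±half a
monomer by default). Using only the longest match matters in satellite
context: non-copy monomers of the same family routinely share ≥20-nt
exact matches at the right offset, and chaining them would drag the
borders outward. Note that for a perfect duplication the breakpoint is
intrinsically ambiguous wherever the flanking bases happen to repeat;
the refined boundary is then one representative of that window.

The NJ tree itself is canonical Saitou–Nei agglomeration (via `ape`),
with bootstrap supports computed by column resampling of the monomer
alignment under a single seeded generator; `clade_support()` retrieves
the support of a specific bipartition regardless of where the stored
tree places its basal node. Multiple alignment of monomers delegates to
the `mafft` progressive aligner on a fixed input order, which keeps the
result deterministic.

## Junctions and microhomology

For a deletion with breakpoints $(a, b]$ the microhomology is the
longest sequence shared by the two breakpoint flanks: the maximal common
suffix of the sequences ending at $a$ and at $b$, plus the maximal
common prefix of the sequences starting after them. Defined this way its
total length is invariant to where within the ambiguity window the
breakpoint is placed — with $k$ nt of homology the breakpoint can sit
anywhere in a $k{+}1$-nt window. The canonical report is the **leftmost**
placement (homology attached to the left flank) and the window is always
reported alongside; the convention is arbitrary and documented rather
than meaningful.

Breakpoint location itself has two paths. When the length difference
equals one clean deletion and the flanks align without indels, an exact
$O(n)$ scan over all split points finds the minimal-mismatch placements
directly; because a flank substitution can, by chance, create an
isolated cost tie away from the junction, the reported placement is the
tie with maximal reference homology and the window is its contiguous
sequence-equality shift range. Otherwise a global alignment with cheap
long gaps (open 25, extend 0.05 per nt, mismatch 4 apart) localizes one
or several events; gaps are then shifted to their leftmost
sequence-equivalent position. Events below `min_deletion` (default
50 nt) are treated as alignment noise. Several qualifying gaps yield a
`multi` status listing each event; no attempt is made to choose among
alternative multi-event histories.

Adjacent duplications are the mirror image: the junction motif is the
longest overlap between the end of the upstream copy and the start of
the downstream copy, capped strictly below the copy length (for an exact
tandem duplication the full unit is trivially such an "overlap" — that
is the duplication, not a repair motif). Consistency with a single
alternative end-joining event additionally requires the same motif at
the 5' end of the upstream and the 3' end of the downstream segment.
Dating a duplication first excises masked intervals (e.g. retroelements
that inserted into one copy after the event); because gapped columns are
excluded from K2p anyway, masking mainly guards against partial
misalignment of insert edges, and fewer than 200 unmasked aligned sites
downgrade the event to `low_confidence`.

Array-versus-array comparison (`diff_monomer_arrays`) aligns two
homologous satellite arrays, reports indels at monomer resolution, and
calls a *chimeric monomer* when a deletion's breakpoints fall inside two
different reference monomers with an ambiguity window narrower than
40 nt — the signature of two monomers fused through shared sequence.

## ChIP enrichment

Coverage is summed in 100-kb windows every 10 kb, averaged over 9
consecutive windows, scaled per million read pairs, and the ChIP/input
ratio is taken per step. The 9-window average is implemented as a
**centered** moving average (4 windows each side), with edge windows
averaging over whatever neighbours exist; a trailing-window reading of
the same description would shift the profile half a smoothing span to
the right, and the choice is configurable. The per-million scale factor
is likewise a convention — any fixed constant cancels in the ratio.
Where the normalized input is zero the ratio is undefined (`NA`) unless
a pseudocount is set. Read mapping is upstream of the package; inputs
are per-base coverage tracks plus library sizes.

## Assembly overlap QC

Two independent assemblies of the same region are globally aligned;
mismatched columns are SNPs, maximal gap runs are indel events (one
event regardless of length), and rates are per aligned column. Indels
are annotated with the maximal mononucleotide run they abut; a run must
be at least 5 nt to count, chosen because residual single-pass
sequencing error concentrates at homopolymers of roughly 5–33 nt, and
the headline statistic is the fraction of single-nucleotide indels at
run ends. `inversion_rate()` is deliberately trivial arithmetic —
elapsed time divided by inversion count — kept as a function so the
quantity is computed, not transcribed.

## What the generator emulates — and what it does not

Every analysis has a generator counterpart with machine-readable truth:

* `simulate_ltr_insertion()` builds TG…CA-terminated LTR pairs with 5-nt
  TSDs in random flank; each LTR is mutated independently at
  $\mu t$ substitutions/site so expected pairwise divergence is $2\mu t$.
* `simulate_hor_array()` derives monomers from a random 156-nt consensus
  at a configurable per-monomer divergence (default 0.08
  substitutions/site from the consensus, i.e. roughly 15% between
  monomers), duplicates a run adjacently, and ages the two copies
  independently; a foreign insertion can be planted in one copy.
* `simulate_mmej_deletion()` writes an exact $k$-nt block at both
  breakpoints and deletes the intervening sequence plus one copy — the
  alternative end-joining geometry. The bases bounding both homology
  copies are forced to mismatch and flank mutations are excluded from
  the homology tract ±2 nt, otherwise the planted $k$ would be
  ill-defined (a chance match extends it ~25% of the time) and exact
  recovery would be unmeasurable.
* `simulate_coverage_pair()` draws per-base Poisson coverage at `depth`
  (input) and `depth × fold` (ChIP). Both tracks record the *genome-
  scale* library size (`depth × length / 200`, i.e. 2×100-nt pairs):
  the simulated region stands for a small slice of a genome, as in real
  ChIP, so depth normalization leaves the planted fold recoverable.
  Normalizing by within-region totals would deflate a 3× / 500-kb
  plateau to about 2.4 by construction.

Substitutions are Poisson in count with positions drawn with
replacement (back-mutation possible), transitions twice as likely as
either transversion — the model under which K2p is the matched
estimator. The generator does **not** model GC bias, substitution-rate
heterogeneity along the sequence, gene conversion between monomers,
indel mutation in flanks, or read-level artefacts (coverage is generated
directly, not from reads). Passing recovery tests therefore shows the
estimators are correct under their own model assumptions at realistic
signal sizes; it does not certify behaviour under model violations such
as concerted evolution of satellite arrays, which in real data will pull
HOR dates toward the present.

All generators are deterministic given `sim_config(seed = …)`,
bit-identical across runs.

## Validation conditions and problem sizes

The recovery suite runs at the sizes the analyses target in real use,
scaled to run comfortably on a laptop: 200 simulated elements per age in
{50, 100, 200, 500} kya with 1-kb LTRs (mean age recovered within 5%);
100 deletions per microhomology length in {0, 1, 2, 3, 5, 11, 28} nt
with deletions of 0.5–5 kb and 2% flank divergence (length recovered
exactly in every trial); 50 arrays with a planted 5-monomer duplication
at 100 kya over 8%-divergence background (offset and monomer boundaries
exact in ≥90%, mean age within 10%, and 100 vs 300 kya ordering correct
in ≥95% of paired trials — ordering is checked on truth-anchored monomer
tables so it measures the dating stage, detection having been measured
separately); 100 seeded tracks with a 3× / 500-kb domain at 20× depth
(plateau within 0.15 of 3.0, midpoint within one 10-kb step). Maximal-
match finding and NJ are checked for exact agreement with brute-force
oracles (full enumeration; exhaustive topology search with least-squares
branch lengths at ≤6 taxa).

The per-trial sampling noise of a dated event is worth internalizing:
a 100-kya duplication dated from three internal 156-nt monomers carries
a ~57-kya standard deviation (about three expected substitutions), so
individual HOR dates are order-of-magnitude statements and only means
over replicates, or orderings, are tested at tight tolerances.

## Coordinates, formats, interfaces

All intervals are 1-based and closed inside the package — the
R/Bioconductor convention — so annotation tibbles line up with `IRanges`
and GFF3 directly; BED export converts to 0-based half-open at the
boundary. FASTA I/O goes through `Biostrings`; GFF3 through
`rtracklayer` (the `Target` attribute records the matched consensus
span); enrichment profiles export as bedGraph. The package's surface is
tidyverse-shaped: scanners, filters and analysers return tibbles that
pipe into `dplyr`, result objects carry `tidy()`/`glance()` methods, and
`autoplot()` renders enrichment profiles and HOR sets. There is no
shell executable: the functions, this vignette and the scripted
analyses under `scripts/` are the interface.

## Known limitations

* The repeat scanner is a homology scanner for a user-supplied consensus
  library; it does no de-novo repeat discovery and none of the
  species-library logic of a full RepeatMasker, so absolute repeat-
  content totals depend on the library and thresholds supplied.
* Structural discovery of LTR elements (finding unannotated elements
  from scratch) is out of scope; the dating pipeline consumes element
  annotations.
* The clock is strict and the rate fixed; rate variation translates
  linearly into age error and no uncertainty from rate misspecification
  is propagated.
* `locate_deletion`'s fast path assumes substitution-only flanks; inputs
  with flank indels fall back to the alignment path, whose breakpoint
  resolution is then bounded by alignment ambiguity.
* Tree inference is NJ with bootstrap only — no likelihood or Bayesian
  alternatives — matching its role here as a grouping device rather
  than an inferential endpoint.
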