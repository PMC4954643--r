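---
title: "Models and methods in mirduplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mirduplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mirduplex learns miRNA targeting rules directly from crosslinking data:
CLASH chimeric reads, which ligate a miRNA to the mRNA fragment it was
bound to and so label (miRNA, site) interactions directly, and AGO CLIP
peaks, which mark where the Argonaute complex sits on 3'UTRs. Two models
divide the problem. The *duplex model* scores how well a miRNA can base-pair
with a candidate site; the *binding model* scores whether the local UTR
context of a canonical seed match looks like an AGO-occupied site. This
vignette describes both models, the choices behind their implementation,
and what the synthetic data used in the test suite does and does not show.

## The duplex model

### Event grammar and scoring

A duplex between a miRNA (read 5'→3', positions $p = 1..P$) and a site
(read 3'→5', antiparallel) is represented as an ordered sequence of
events:

* `PAIR(p, q, b)` — a base pair of type $b \in$ {AU, UA, GC, CG, GU, UG}
  between miRNA position $p$ and site position $q$;
* `LOOP_OPEN(p)` — the start of an internal loop;
* `SYM_EXT(p)` — a symmetric loop extension consuming one base on each
  strand;
* `ASYM_EXT_MIRNA(p)` / `ASYM_EXT_SITE(p)` — asymmetric extensions
  consuming one base on a single strand.

The first and last events are PAIRs, PAIR positions increase strictly
along the miRNA and decrease strictly along the site, and every internal
loop is one `LOOP_OPEN` followed by extensions consuming at least one
base. Mismatched opposed bases are not PAIR events; they are realized as a
loop whose symmetric extension consumes one base from each strand, since
only the six complementary pair types carry pairing scores. Pairing at
miRNA position 1 is special: it is legal only opposite an adenosine and is
scored by a single dedicated m1A weight, reflecting the fact that AGO's
t1-adenosine pocket recognizes the base identity rather than
complementarity to the miRNA.

The score of an alignment is additive over events. The weight vector
holds, per miRNA position, the six pair-type scores, loop opening and
symmetric/asymmetric extension weights, and a paired/unpaired indicator
weight, plus the single m1A score — 271 parameters at the default maximum
miRNA length of 27. Two bookkeeping conventions close the gaps the event
list leaves open: loop events are indexed by the last *consumed* miRNA
position (so a site-side extension is charged to the miRNA base it sits
under), and among equal-scoring alignments the dynamic program prefers
fewer events, then the 5'-most miRNA start, then the 5'-most site start,
which makes results deterministic. A loop consuming $a$ miRNA-side and
$b$ site-side bases is decomposed into symmetric and asymmetric
extensions by the dynamic program itself, which maximizes over
decompositions; this keeps the score linear in event counts.

The optimal alignment under a weight vector is computed by a
two-state dynamic program (in C++; states: "last event was a PAIR" and
"inside a loop") that is local on both strands: any contiguous miRNA
range against any contiguous site range. If no legal alignment scores
above zero the empty alignment is returned with score 0. An `anchored`
variant restricting the first PAIR to miRNA positions 1–2 is available as
a sensitivity analysis (`duplex_control(anchor = "anchored")`); the
default is fully local, which is the weaker and therefore safer reading
of a local pairwise alignment.

### Training

Training alternates between two steps, starting from alignments produced
by a fixed thermodynamic-like initializer (GC pairs 3, AU 2, GU wobbles
1, loop opening −3, symmetric extension −1, asymmetric extension −2 —
order-of-magnitude ratios of stacking free energies, not fitted values):

1. re-align every example under the current weights;
2. refit a linear soft-margin SVM (hinge loss) on the event-count
   features, with all positives and negatives resampled from the pool at
   the configured ratios (15 CLASH negatives per CLASH positive, one CLIP
   negative per CLIP positive), using an iteration-indexed seed.

Because an example's model score is the *maximum* of $w \cdot \phi$ over
its alignments, treating only the currently imputed alignment of a
negative example underestimates its hinge loss and makes the plain
alternation oscillate: the refit weights license new high-scoring
alignments for negatives, the next refit over-corrects, and the loop can
collapse to the zero vector. The trainer therefore solves the convex
subproblem properly by constraint generation: every distinct negative
alignment encountered is kept as a working-set constraint, and within an
iteration the SVM is refit until realignment of the sampled negatives
produces no new alignment. Positives contribute only their currently
imputed alignment, as in the concave-convex procedure for latent-variable
margin models. With this working set the alternation reaches an exact
fixed point — identical alignments, identical constraint set, identical
weights — typically within 6–9 iterations; the default of 12 iterations
is retained and the per-iteration weight change is recorded in the
model's convergence trace. Once the fixed point is reached with an
unchanged negative sample, remaining iterations are provably identical
and are not recomputed.

The soft-margin cost defaults to `C = 0.05`. Larger values (C ≥ 0.5)
let intermediate weight vectors over-commit to transient alignment
patterns and can destabilize the alternation before the working set is
rich enough; 0.05 converges robustly on data of the scale the package
targets while still separating planted structure perfectly. An internal
5-fold cross-validation over {0.01, 0.1, 1, 10} can be requested
(`tune_C = TRUE`) when the data call for it.

### Example construction

CLASH positives pass three filters: the site lies in a cataloged 3'UTR;
it contains a match to the interacting miRNA's 6-mer seed (reverse
complement of miRNA positions 2–7) within edit distance 1, where
substitutions and indels each count 1 and indel matches may be 5–7 nt
wide; and the interaction has non-chimeric read support. The site used is
the chimera-mapped fragment interval as given in the input. Negatives are
mispaired decoys — the same sites paired with miRNAs from families not
observed to interact with them — plus, for the CLIP side, canonical seed
matches without AGO evidence. A seed match's *anchor* (the UTR position
opposite miRNA nucleotide 2) is taken as the 3'-most base of the matched
window; for one-edit matches with indels this is the 3'-most position
consistent with the window-to-seed alignment, a deliberate tie-break.

Held-out evaluation removes one seed family entirely, together with every
example sharing a site with one of its positives, so that neither family
nor site information leaks into training.

## The binding model

Examples are canonical (exact) 6-mer seed matches of cataloged families,
labeled positive when they overlap (share at least one base with) an AGO
peak and negative when they overlap no read evidence; matches overlapping
reads that were not called as peaks are ambiguous and discarded. Each
example is represented by:

* two weighted-degree string kernels over the 30-nt flanks upstream and
  downstream of the seed match (positional $k$-mers, $k = 1..6$, weights
  $\beta_k = 2(d-k+1)/(d(d+1))$, the standard length-decaying choice —
  the kernel family fixes only the form, not $\beta$). Flanks are stored
  in UTR 5'→3' order; the downstream base nearest the seed lies opposite
  miRNA nucleotide 1 and the upstream base nearest the seed opposite
  nucleotide 8. Positions truncated at UTR boundaries are padded with a
  symbol that matches nothing, including itself;
* a radial basis kernel over three isoform-positional distances measured
  from the anchor: to the UTR start, to the next isoform 3' end, and to
  the previous isoform 3' end. Raw distances span 0 to ~10^4 nt and would
  saturate any single RBF width, so each is transformed to
  $\log_{10}(1+d)$ first; when no upstream isoform end exists the
  previous-end slot falls back to the distance to the UTR start and a
  fourth indicator component marks the fallback, rather than fabricating
  an isoform end. The width γ defaults to 1.0 on the log scale and can be
  tuned by the same cross-validation as μ below.

The soft-margin cost defaults to `C = 0.1`: the flank kernels compare
~165 positional windows of which a handful carry signal, and with a few
hundred training sites a weakly regularized fit memorizes that kernel
noise — large train/held-out gaps close, on held-out data, when C is
reduced to this range.

The three kernel matrices are summed. By default each component is first
divided by its mean diagonal (trace normalization) so that no component
dominates by scale — the two flank kernels have self-similarity around
3.2 while the RBF is bounded by 1; raw summation is available via
`binding_control(normalize = "none")`.

With more than one task (cell type / protocol), the kernel is modulated
as $K_{st}(x, z) = (\mu + \delta_{st}) K(x, z)$: same-task pairs receive
one extra unit of similarity, and μ sets how strongly tasks share a
common model. μ defaults to 1 and can be selected by 5-fold
cross-validation (stratified by task and class, maximizing mean held-out
auROC) over {0.1, 0.25, 0.5, 1, 2, 4}, a grid symmetric around equal
task/common weighting. Prediction offers a cell-type-agnostic mode using
only the shared part, $f(x) = \sum_i \alpha_i y_i \mu K(x_i, x) + b$, and
per-task modes adding $\sum_{i \in t} \alpha_i y_i K(x_i, x)$. The dual
problems are solved by kernlab's SMO on the precomputed kernel matrices.
In the simulated two-task datasets used by the tests, the tasks carry
disjoint transcript sets, as different cell types express different
3'UTRs; a site is only ever labeled against the peak evidence of its own
task.

Duplex and binding scores are combined, when a single ranking is needed,
by z-scoring each against its training distribution and summing
(`sum_z`); rank-based alternatives (`min_rank`, `product_rank`) need no
calibration. The combination scheme is not dictated by the model itself
and is recorded in the score output. Genes with several sites receive
their best site's score.

## Interpretation

The weighted-degree kernel's feature map is finite, so the dual solution
expands into explicit positional $k$-mer weights,
$w(z, j) = \beta_k \sum_i \alpha_i y_i \tau_i\, 1[x_i \text{ has } z
\text{ at } j]$ (per flank, divided by that component's normalization
constant, with $\tau_i$ the μ/δ task weighting of the chosen mode). From
these the package computes positional oligomer importance matrices
exactly: $Q(z, j)$ is the expected change in the flank score when $z$ is
clamped at position $j$ under a uniform i.i.d. background over
{A, C, G, U}. Features whose window is disjoint from the clamped window
cancel, and an overlapping feature of length $k'$ with overlap $o$
contributes $w' (4^{-(k'-o)} 1[\text{consistent}] - 4^{-k'})$, which
handles sub-, super- and partially overlapping $k$-mers in one formula;
every column is exactly centered under the background. The uniform
background is the conventional choice; the importance values are relative
to it and would shift under a composition-matched background. Positions
are ranked by the differential summary $D(j) = \max_z Q - \min_z Q$
(the range; the conventional reading of "highest differential
importance"), the top 5- or 6-mer position is selected, and the 15
highest-scoring $k$-mers at that position (ties broken lexicographically)
form the motif set.

Motif sets are tested against probe-intensity tables (one per RBP
experiment): among the 1000 highest-intensity probes, a one-sided
Wilcoxon rank-sum test compares probes containing at least one of the
$k$-mers with probes containing none (exact null below 50 probes per
group, continuity-corrected normal approximation otherwise). Restricting
the test to the top probes is one of two defensible readings of the
procedure; the alternative — top probes against all others — is available
via `restrict_to_top = FALSE`. The rank-sum (two-sample) form is used
throughout, as it is the operational description; a signed-rank test
would require paired observations that this design does not produce.

False discovery rates come from label permutations: the binding SVM is
retrained on permuted class labels (the kernel matrix does not depend on
labels and is reused), the top $k$-mers at the same $(k,$ position,
flank$)$ are extracted and tested, and the observed p-value is converted
to its empirical quantile, $(1 + \#\{p_{null} \le p_{obs}\}) /
(n_{perm} + 1)$. Full runs use 1000 permutations; the test suite and the
pipeline default use 100, which bounds the smallest reportable FDR at
~0.01 and keeps retraining tractable. By exchangeability, a model that
was itself trained on permuted labels receives an FDR that is uniformly
distributed — the pipeline assigns low FDR to noise only at its nominal
rate, which is the exact calibration guarantee one can make; no stronger
"always high FDR on noise" property holds, and the test suite documents
this behavior rather than asserting one.

Score decomposition attributes the discriminant to flank positions by
summing the weights of all matched $k$-mers *starting* at each position
(default; a variant spreading each $k$-mer's weight across the positions
it covers is available). Contributions plus the positional-kernel part
and the bias reproduce the discriminant to numerical precision, which the
tests assert for every example.

## Evaluation metrics

auROC is the Mann–Whitney statistic with ties counted 1/2. Precision–
recall areas use the step convention: the precision of a tied-score block
applies to the whole block and no linear interpolation is performed, so
the area is reproducible from the score multiset alone. auPR50 integrates
precision over recall in [0, 0.5] only — rewarding early retrieval when
positives are rare — and divides by 0.5 so its range is [0, 1]. Paired
per-family comparisons use the Wilcoxon signed-rank test.

## The synthetic data generator

The generator plants known structure so every claim the tests make is
checkable against ground truth:

* miRNA families share exact 2–7 seeds; UTRs are drawn from a slightly
  AU-rich composition (A/U 0.3, C/G 0.2, typical of 3'UTRs) with clipped
  log-normal lengths (median 600 nt, range 250–2000) and 1–3 isoform
  ends each;
* chimera-supported positives are sites written into UTRs whose alignment
  to their miRNA under a planted weight vector w\* — the initializer
  weights with seed-position pairing doubled and a positive m1A score —
  exceeds the 95th percentile of background windows; 40% carry a one-edit
  (non-canonical) seed. Each receives chimeric and non-chimeric read
  counts. The default scale is 300 UTRs, 8 families, 120 chimera
  positives with a 15× mispaired decoy pool (~2000 duplex examples), at
  which the full suite runs in minutes on one CPU;
* AGO-bound seed sites receive a planted 6-mer flank motif (UGUACA, a
  Pumilio-like element) at downstream offset 8 with probability 0.9 —
  a strong co-binding signal chosen so that motif recovery is a
  well-posed experiment at desk scale — and fall within 150 nt upstream
  of an isoform 3' end with 4:1 odds; unbound sites are placed uniformly.
  Peaks cover bound sites minus a 2% false-negative rate, plus 5%
  spurious peaks; bound/unbound sites are split across two tasks with
  disjoint transcript sets;
* probe tables are random probes with the motif written into a fraction
  and intensities shifted by a configurable effect size (0 gives a null
  table).

What passing these tests shows: the estimators recover structure they are
pointed at, at the noise levels configured, with correct bookkeeping and
calibrated statistics. What they do not show: performance on real CLASH
or CLIP libraries, whose label noise (ligation bias, peak-calling
artifacts, unmodeled RBP competition), sequence composition and
interaction diversity are richer than anything planted here; positives
defined through the same alignment grammar the model fits make parameter
recovery well-posed but cannot certify the grammar itself against
biochemistry.

## Degenerate inputs and numerical conventions

Unknown bases (N) never participate in pairing or $k$-mer features but
may be consumed by loop extensions; flank pads contribute to no feature;
empty alignments have exactly zero features; kernel matrices are accepted
as PSD down to an eigenvalue of −1e−8 (accumulated floating error);
score/feature identities are asserted to 1e−9; metric oracles to 1e−12.
All sampling goes through a package-internal RNG stream that restores the
caller's random seed, so library calls never perturb user code, and every
training function is bit-reproducible given its seed.

## Known limitations

The duplex grammar has no notion of target-site accessibility or
thermodynamic free energy; the alignment is purely sequence-driven. The
binding model sees 30-nt flanks only and cannot represent longer-range
context. The multi-task kernel shares one μ across all task pairs, not a
per-pair coupling. Genome-to-UTR projection is out of scope: all inputs
are required in transcript-relative UTR coordinates.
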