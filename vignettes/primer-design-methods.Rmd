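---
title: "Designing multiplex PCR primer sets by annealing on a dimer-likelihood loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multiplex PCR primer sets by annealing on a dimer-likelihood loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexanneal)
```

## The problem

An N-plex PCR reaction contains 2N primers, hence on the order of (2N choose 2)
pairwise opportunities for primer-dimer formation: two primers hybridizing to
each other — typically through 3'-end complementarity — and being mutually
extended by the polymerase. Dimers consume primers, dNTPs and, in sequencing
applications, reads: in an unoptimized 96-plex library the large majority of
reads can be dimers. With M ≈ 10–50 reasonable candidates per primer there are
M^(2N) possible primer sets, so exhaustive evaluation is hopeless, and the
fitness landscape is non-convex (fixing one dimer can create another), so
greedy descent stalls in poor local minima. `plexanneal` treats panel design
as stochastic combinatorial optimization: a cheap, hash-accelerated
dimer-likelihood loss over the whole set, minimized by simulated annealing
over the choice of one forward/reverse candidate pair per target.

## The pairwise score and the set loss

For two primers $p_a, p_b$ the score ("badness") sums over every pair of
positions at which a subsequence of $p_a$ of length 4–8 nt is the reverse
complement of a subsequence of $p_b$:

$$\mathrm{Badness}(p_a, p_b) = \sum \frac{2^{\mathrm{len}} \cdot 2^{\mathrm{numGC}}}{(d_1 + 1)(d_2 + 1)}$$

where $\mathrm{len}$ is the subsequence length, $\mathrm{numGC}$ its G/C
count, and $d_1, d_2$ are the distances from each hit's 3'-most base to its
primer's 3' terminus. The exponential terms are a deliberately crude stand-in
for a duplex partition function — each base pair roughly doubles the bound
fraction, G/C pairs counting twice an A/T pair — chosen over literature
nearest-neighbor enthalpies because buffer salinity and the extrapolation of
published $\Delta H^\circ/\Delta S^\circ$ values to PCR temperatures are both
uncertain. The distance attenuation encodes the mechanism: complementarity at
or near the 3' end is what a polymerase can extend. Three or fewer
complementary bases are ignored entirely (the 4-nt floor), since such short
overlaps do not seed appreciable dimer formation even in no-template
controls.

Two conventions needed fixing where the score's verbal definition is
ambiguous; both are configurable in spirit (the code isolates them in one
place) and stated here so results are interpretable:

* **Distance convention.** $d$ counts the bases strictly between the hit's
  3'-most base and the primer's 3' terminus, so a hit that includes the
  terminal base has $d = 0$ and maximal weight. Measuring from the 5'-most
  base instead would shift all weights by $\mathrm{len}-1$.
* **All substrings, not maximal runs.** Every substring of length 4–8
  contributes — a 6-nt complementary run also scores its internal 4- and
  5-mers. This is forced by the hash-table factorization below and makes
  long runs score super-linearly, which is the intended behavior.

The set-level loss is the sum over unordered primer pairs, self-pairs
included once:

$$L(S) = \sum_{b \ge a} \mathrm{Badness}(p_a, p_b)
       = \tfrac12 \sum_{a,b} \mathrm{Badness}(p_a, p_b)
       + \tfrac12 \sum_{a} \mathrm{Badness}(p_a, p_a)$$

The self terms are computed once per candidate at generation time and cached.

## Hash-table evaluation and incremental updates

Evaluating the double sum naively costs $O(N^2 P^2)$ for 2N primers of
length P. Because contributions are additive over subsequence occurrences,
the ordered double sum factorizes through a hash table $H$ mapping each
subsequence $s$ to $\sum 1/(d+1)$ over its occurrences in the set:

$$\sum_{a,b} \mathrm{Badness}(p_a, p_b)
  = \sum_{s} \frac{2^{\mathrm{len}} \cdot 2^{\mathrm{numGC}}}{d+1}
    \, H[\mathrm{revcomp}(s)]$$

which costs $O(NP)$ to build and to evaluate. When the optimizer swaps one
target's pair, only the four affected primers' subsequences are edited, an
$O(P)$ update. `loss_brute_force()` retains the direct pairwise evaluation
as a permanently available reference; the equivalence of the two routes on
randomized sets is the package's central invariant and is asserted to
1e-6 relative tolerance in the test suite. Incremental updates accumulate in
double precision; during long runs the cached cross sum is refreshed from
the hash table every 2000 generations to cap floating-point drift, and
`optimize_panel(debug_check_every =)` can assert against the brute-force
reference at any cadence.

Degenerate bases (IUPAC codes, N) are rejected at input: the score is
defined over exact complementarity only.

## Candidate generation

Each target is a template with a *pivot* interval — the positions that must
lie inside the amplicon insert, e.g. a mutation hotspot. Proto-primers are
enumerated with their 3' terminal base abutting the pivot (forward protos
end at `pivot_start - 1`; reverse protos, stored 5'→3' as synthesized, end
at `pivot_end`), one per 5' start over lengths 18–45 nt by default. Each
proto is then trimmed base by base from the 3' end, and every truncation
whose duplex free energy lies in the window is emitted as a candidate;
because stacks are coarse-grained, one proto can yield several candidates
with the same 5' end. Trimming stops at the first truncation less stable
than the window's upper bound — the free energy is monotone in length under
the default table, so nothing is missed. Candidates are then filtered to
G/C fraction within [0.25, 0.75] (inclusive at both bounds) and
deduplicated on (strand, sequence).

The free energy is a nearest-neighbor sum: unified dinucleotide
$\Delta G^\circ_{37}$ stacks plus per-end initiation penalties (1.03
kcal/mol for a terminal A·T, 0.98 for G·C), with no salt or temperature
correction — the design criterion is a fixed window, so only relative
consistency across candidates matters, and the table is swappable as data
(`nn_params()`, `read_nn_params()`). The default window is
[-12.5, -10.5] kcal/mol: primers near the middle of this window trade off
amplification efficiency (too weak binds inconsistently) against off-target
hybridization (too strong finds other loci). Note that under the 37 °C
table this window admits oligos of roughly 10–12 nt; windows quoted for
other temperature/salt conventions select correspondingly different
lengths, so users matching an established assay condition should set the
window (and, if desired, their own parameter table) accordingly.

Candidate pairs are the Cartesian product of forward and reverse candidates
filtered on (i) amplicon length — the span from the forward primer's 5'
start through the reverse primer's 5' start — within the target's bounds,
and (ii) containment of the whole pivot interval strictly inside the insert
between the two 3' ends. When no explicit minimum amplicon length is given,
the per-pair default `len(fP) + len(rP) + pivot width + 10` keeps the two
primers from crowding each other. Coordinates are 0-based half-open
(BED-style) everywhere, including all files written.

## The annealing loop

One candidate pair per target is drawn uniformly at random ($S_0$); each
generation proposes re-drawing the pair of one randomly chosen target
(mutating several targets at once is supported but disabled by default — in
practice it slows convergence). Improvements are always kept; a detrimental
proposal with loss $L(T) > L(S_g)$ is kept with probability

$$p = \begin{cases} e^{(L(S_g) - L(T))/C(g)} & g < g_t \\ 0 & g \ge g_t \end{cases}$$

where the tolerance $C(g)$ is positive and non-increasing. After $g_t$ the
search degenerates to strict stochastic descent, so the loss trace is
non-increasing from there on; runs extend to $1.5 \times g_t$ by default so
the descent tail settles into its local minimum. Only monotone
non-increase of $C$ is inherent to the method; the shape is a design
choice. The default here is geometric decay $C(g) = C_0 (C_{end}/C_0)^{g/g_t}$
with $C_0 = L(S_0)/20$ and $C_{end} = C_0/1000$ (a linear option is
provided). $L(S_0)/20$ makes early tolerance commensurate with typical
single-swap detriments regardless of panel size; three decades of decay
span "accept almost anything" to "effectively greedy" smoothly. The
generation budget defaults to 400 per target, scaling the search with panel
size. Multiple restarts (`n_restarts`) run independent chains — the restart
index is folded into the seed — and the best final set wins.

Because the score is a likelihood proxy, not ground truth, over-optimizing
it can select for its false negatives. The optimizer therefore returns the
last set, the best-seen set with its generation, the full loss trace, and
optional checkpoint selections, so users can inspect intermediate designs
rather than blindly taking the final generation.

## Read classification and accuracy evaluation

Given the designed panel and adapter-trimmed reads, classification runs in
two stages. Reads matching an expected amplicon within a bounded edit
distance (scaled per 100 nt of amplicon; exact when the tolerance is 0) are
*on-target*. For the remainder, the first bases are matched against all 2N
primers and the last bases against all primer reverse complements — forward
primers dimerize with forward primers too, so both ends face the merged
list, using 25-nt anchors. A read shorter than the sum of its two matched
primers' lengths is a *dimer* (the defining property of a mutually-extended
primer pair); longer is *non-specific*; no match at both ends is
*unassigned*. Suffix matching walks a truncation ladder (down to 8 nt)
because the 3' overlap that joins a dimer consumes part of the downstream
primer's image in the read; ties prefer the longest match, then the lowest
edit distance, then the lowest primer index. This internal matcher replaces
genome alignment: reads from off-panel genomic loci are non-specific or
unassigned here, and cannot be attributed to their true locus.

For accuracy evaluation, the universe is all $(2N)^2$ ordered primer pairs
including self-pairs, each carrying a badness value and an observed dimer
read count (both orderings share the symmetrized values). A pair is an
*observed* dimer when its reads strictly exceed a reads threshold —
conventionally the mean on-target depth, so "dimer as abundant as a real
amplicon" — and a *predicted* dimer when its badness strictly exceeds a
badness threshold. Both comparisons are strict; inclusive variants would
only matter for exactly-tied values. Sweeping the badness threshold over
all unique scores yields the ROC staircase and its trapezoidal AUROC (equal
to the Mann-Whitney concordance, and invariant under monotone transforms of
the score); `best_threshold()` picks the sensitivity + specificity
maximizer (the Youden point). Degenerate inputs are explicit: zero observed
positives give `NaN` sensitivity with a warning, and the ROC errors rather
than fabricating a curve.

## The synthetic-data generator

`make_targets()` emulates a panel of exon-sized targets: random-composition
templates (default 96 targets, 250 nt, G/C 0.5 — amplicons of roughly
40–90 nt under the default candidate geometry) with a centered 2-nt pivot,
fully determined by the seed. The adversarial mode plants, in paired
targets, forward candidates whose 3' termini carry a motif and its reverse
complement, tuned into the free-energy window by 5'-ward A/T extension so
they genuinely survive candidate generation; a planted pair's score is
bounded below by its $d_1 = d_2 = 0$ term, $2^{\mathrm{len}} \cdot
2^{\mathrm{numGC}}$, giving optimizer tests a known trap with known depth.
`simulate_reads()` synthesizes libraries with a planted class mixture:
on-target reads are exact amplicon copies; dimer reads join a primer to a
second primer's reverse complement through a 3' overlap of 1–8 nt (total
length below the summed primer lengths by construction, with the suffix
primer drawn long enough that its image stays at or above the classifier's
8-nt matching floor); non-specific reads insert 10–60 random bases between
two primer images. What the simulator does not model — sequencing error,
quality degradation, adapter read-through, chimeric amplicons, and real
off-panel genomic amplification — bounds what passing tests show: they
certify the classification logic and its boundary definitions, not
performance on real libraries, where the edit-distance tolerances exist to
absorb sequencing error and where genome-scale non-specific products arise
that the simulator never produces.

## Problem sizes and numerical tolerances used in the tests

The test suite checks hash/brute-force equivalence on 200 randomized sets
of up to 24 primers (15–35 nt) and 500 random swap/recompute rounds at
1e-6 relative tolerance; the pairwise score against an independently
written exhaustive substring-pair oracle on worked and randomized cases;
annealing optimality on an exhaustively enumerable instance (6 targets × 3
pairs, best of 5 restarts, 50 seeds, ≥90% required); the empirical
acceptance rate of detrimental moves on a two-state fixture at constant
tolerance (10,000 generations, 3σ binomial agreement with $e^{-1}$); and a
full 96-target design at 400 generations per target, required to end below
10% of its initial loss with most of the drop in the first half and
near-none in the last tenth. These sizes are the package's chosen
verification conditions: large enough to exercise the claimed scaling
behavior, small enough to run routinely.

## Known limitations

* The loss only predicts primer dimers. Non-specific genomic amplification
  is measured by the read classifier but not designed against; a loss term
  for it would require the sample genome and would trade off against dimer
  minimization.
* The score is deliberately not a thermodynamic partition function;
  mismatch stacking, dangling ends and melting temperatures are out of
  scope, and the 3'-distance attenuation is polymerase-dependent
  (proofreading enzymes chew back mismatched 3' ends, weakening the
  rationale for strong attenuation).
* Primer candidates are not screened for genome-wide uniqueness.
* The classifier's primer-anchored matching cannot recover the genomic
  origin of non-specific reads.
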