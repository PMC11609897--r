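---
title: "Structured RNA Bind-n-Seq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured RNA Bind-n-Seq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srbns)
```

## The assay and the quantities this package computes

Conventional RNA Bind-n-Seq incubates a fully randomized RNA pool with a
tagged protein, sequences the bound fraction, and scores k-mer enrichment
against the input library. Structured RBNS (sRBNS) instead randomizes only a
loop window presented on constant stem-loop scaffolds, so every pool member
displays a defined secondary structure. This makes the assay suitable for
proteins that read stem-loop *shape*, such as Roquin-1/2, whose ROQ domain
recognizes constitutive decay elements (CDEs: triloop stem-loops with a YRU
loop consensus) and alternative decay elements (ADEs: hexaloop stem-loops,
canonical GUUYUA) in 3'-UTRs and triggers mRNA degradation.

The analysis unit is the loop variant. For variant $v$ with input frequency
$f^{in}_v$ and pulldown frequency $f^{pd}_v$ (frequencies normalized over
all designed variants of a scope), the enrichment is

$$E_v = \frac{f^{pd}_v}{f^{in}_v},$$

and significance is assessed by standardizing the E-values within a scope
and concentration:

$$z_v = \frac{E_v - \bar E}{s_E}, \qquad \text{significant} \iff z_v > 3 .$$

Two properties of this statistic are worth keeping in mind and are enforced
by tests:

* **Conservation.** With full support and no pseudocount,
  $\sum_v f^{in}_v E_v = 1$ in every scope — the E-values are a reweighting
  of the input distribution, so the scope mean of $E$ under input weights is
  fixed and enrichment of one variant forces depletion elsewhere.
* **Bounded z.** A sample z-score can never exceed $(n-1)/\sqrt{n}$. In a
  4-variant scope nothing can reach $z > 3$; the rule is meaningful only for
  pools of tens of variants and larger, which the designed pools (64 to
  4096 variants) always are.

## Pool design

A scaffold is a constant 5' arm and 3' arm whose terminal bases form the
stem; the randomized loop of length $k$ sits between them, so each scaffold
contributes $4^k$ members per loop size and the pool size is
$n = \sum_k 4^k$ (64 for a trinucleotide pool, 1344 for a mixed
N3/N4/N5 pool, 4096 for hexaloops). When several loop sizes are combined,
the pools must be mixed with an excess of the more complex larger pools;
mass fractions proportional to $4^k$ (1 : 4 : 16 for sizes 3 : 4 : 5) are
the unique choice that gives every individual variant the same expected
abundance, and are the package default. Scaffolds receive equal total mass.
Loop variants are enumerated lexicographically (A < C < G < U) purely for
reproducible output ordering.

The arm sequences of the published UCP3/TNF/HOMEZ/ITCH scaffolds are not
part of this package; the shipped example designs
(`inst/extdata/synthetic_*_design.yaml`) use synthetic 6-bp Watson-Crick
stems that preserve the documented closing-pair orientations
(purine-pyrimidine for the UCP3-like scaffold, pyrimidine-purine for the
TNF-like one). Designs may be written as DNA; everything is transliterated
to RNA internally.

## Read counting

Reads are assigned by anchoring the constant arms at the read ends: a read
belongs to the scaffold whose arms match its prefix and suffix with at most
`max_mismatch_per_arm` mismatches each (default 1 — enough to absorb
sequencer error while the scaffolds' arms differ by far more than two
mismatches, so cross-scaffold bleed is not possible); ambiguous ties stay
unassigned. The interior substring is the loop; loops whose length is not in
the design are tallied under an `invalid_loop_length` QC total rather than
counted. Reads are used as-is (no quality trimming or deduplication),
matching standard RBNS practice, and interior indels are not modeled — the
arms are constant by construction. The QC identity
assigned + unassigned + invalid = total holds always, and counting is
order-independent.

## Enrichment scoring choices

* **Pseudocount** (default 0.5 per variant and condition). The published
  analysis does not state how dropout variants were handled; 0.5 keeps $E$
  defined for them while shifting well-covered variants negligibly.
  `pseudocount = 0` recovers raw ratios, with dropouts flagged as `NA`
  rather than dropped.
* **Scopes.** z-scores are computed on linear E, separately per scaffold
  *and* for a `COMBINED` scope that pools counts across scaffolds before
  normalizing; published panels show both per-scaffold and pooled views, and
  which one carried the z statistics is not stated, so both are emitted.
* **Sample standard deviation** ($n-1$) is used; no multiple-testing
  correction is applied beyond the $z > 3$ rule, mirroring the assay's own
  criterion.
* **Effective loops.** Pentaloops whose outer bases form a Watson-Crick pair
  are annotated with the collapsed loop they actually present (e.g. CUGUG is
  the triloop UGU on a one-bp-longer stem). Collapse is Watson-Crick only
  and never shortens a loop below 3 nt.
* **Logos.** The enrichment-weighted logo weights each variant's base
  contribution by its $E$: $w_{p,b} = \sum_{v: v_p = b} E_v / \sum_v E_v$,
  giving per-position probability vectors.

## The read simulator

The simulator exists so the whole pipeline can be validated end-to-end
without sequencing data, and its defaults are the assay's stated conditions:
protein concentrations 10, 50 and 500 nM, with per-variant dissociation
constants supplied by the user (e.g. the published ITC table via
`roquin_ade_affinities()`).

Capture of member $v$ in the pulldown is modeled as

$$p_v \propto a_v\,\bigl[\theta_v (1 - b) + b\bigr], \qquad
  \theta_v = \frac{[P]}{[P] + K_{D,v}},$$

with $a_v$ the input abundance, $b$ a uniform nonspecific background
(default 0.002), and $\theta_v$ the single-site equilibrium occupancy under
protein excess — the standard Bind-n-Seq regime; protein depletion and
RNA-RNA competition are deliberately not modeled. Input and pulldown
libraries are multinomial draws at the requested depth, written as DNA
FASTQ; identical seeds give byte-identical files. An optional per-base
substitution rate exercises the counting stage's mismatch tolerance.

What the simulator does *not* emulate: PCR amplification bias, positional
quality decay, misfolding of individual loop variants, partial occupancy
kinetics during washes. Passing simulation-based tests therefore
demonstrates the correctness of the counting and scoring arithmetic under
the equilibrium model, not robustness to every artifact of real libraries.

Two simulation designs are fixed as study conditions rather than tunables:

* **YRU recovery.** A two-scaffold trinucleotide screen with the four YRU
  loops at $K_D$ = 30, 40, 50, 60 nM (wild-type-like CDE affinities with the
  narrow spread suggested by their similar published enrichment),
  nonbinders at 5000 nM, 50 nM protein, depth $10^6$. Under these
  conditions the pipeline calls exactly the four YRU loops significant.
  The choice of a narrow $K_D$ range is analytic, not empirical: with four
  binders among 64 variants the binders themselves inflate the scope
  standard deviation, and a binder weaker than roughly 100 nM at 50 nM
  protein cannot clear $z > 3$ no matter the depth.
* **Stem contrast.** Giving the TNF-like scaffold's YRU loops 4-fold
  tighter $K_D$ (10 vs 40 nM), matching the reported affinity ratio of the
  wild-type stems, yields a simulated TNF stem enrichment of ~1.4-fold —
  the same magnitude the assay reports.

## Hairpin folding probability

The 3'-UTR scanner needs the probability that a candidate stem-loop is
actually folded. This package computes it inside a deliberately small,
fully specified thermodynamic model rather than a full nearest-neighbor
parameterization: each base pair contributes one energy by type (defaults
AU $-1.1$, GC $-2.4$, GU $-1.0$ kcal/mol; $RT = 0.616$ kcal/mol),
structures are pseudoknot-free, and every pair must enclose at least 3 nt.
For a pair-additive model this blanket minimum-span rule is *exactly* the
minimum-hairpin-loop constraint, because a pair enclosing fewer than 3 nt
cannot contain an inner pair and would itself be a short hairpin.

The folding probability of a candidate with loop window $[l_s, l_e)$ and
stem length $L$ is operationalized as the joint probability that all $L$
closing pairs are formed in the equilibrium ensemble:

$$p_{fold} = \frac{Z_{constrained}}{Z},$$

where $Z$ is the partition function over all structures (interval dynamic
programming, $O(n^3)$) and $Z_{constrained}$ factorizes into the stem's
Boltzmann weight times independent partition functions over the loop
interval and the exterior with the stem-enclosed block masked. Every
quantity the DP produces is validated against an exhaustive enumeration of
the structure ensemble (`enumerate_structures()`, guarded to sequences of
at most 20 nt) — the test suite checks agreement to $10^{-9}$ on hundreds
of random sequences, and monotonicity properties (more required stem pairs
never increase $p_{fold}$; more stabilizing pair energies never decrease
it).

Because the published scan's folding tool and parameters are not stated,
absolute probabilities here will differ from the published ones; the 19 %
high-confidence and 5 % exclusion thresholds are kept as the reported
operating points, but a genome-wide candidate list is not expected to
reproduce the published element count, and no such count is asserted
anywhere in this package.

## 3'-UTR scanning

Candidates are loci where (i) a loop motif matches and (ii) the contiguous
closing stem ([`stem_length_at()`]) reaches `min_stem` (default 6 bp,
Watson-Crick only by default with an opt-in wobble flag, since the assay's
loop-collapse logic is stated in Watson-Crick terms). The default motif set
is the six enriched ADE variant patterns (GUURUA, GUUYMA, GUUYUG, AUUYUA,
AUUYUC, AUUYUG — note these are the *novel* variants; the canonical GUUYUA
consensus is deliberately not among them) plus the CDE consensus YRU.
Folding probabilities are computed in a window of the hairpin plus
`fold_flank` (default 20) nt of context per side: the interval DP is cubic,
and a local window both bounds the cost on kilobase UTRs and matches the
local character of hairpin formation; very long-range competing structure
is outside the model anyway. Scanning is sense-strand only, coordinates are
0-based half-open throughout (BED's native convention), and overlapping
matches of different patterns are reported separately.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data:
the YRU recovery screen at depth $10^6$ reads per library, the stem
contrast at $5 \times 10^5$, saturation checks at $10^5$, oracle
equivalence on 500 random sequences of length 8–18, and rank-order recovery
of the published ITC affinities on the full 2 × 4096 hexaloop pool at
$4 \times 10^5$ reads. These sizes give sampling errors comfortably below
the effects being asserted while keeping a full validation run in the
low minutes on a single core.

## Known limitations

* The E-to-$K_D$ mapping is empirical; the simulator asserts rank-order
  consistency with the published affinity table, not absolute E
  reproduction.
* The folding model is pair-additive: no stacking, dangles or loop-length
  entropy terms. It is exact with respect to its own ensemble and
  oracle-checked, but its probabilities are calibrated differently from
  Turner-parameter partition functions.
* The scanner does not retrieve annotation (UTR extraction, conservation,
  CLIP overlap are out of scope) and does not search the reverse strand.
* Real libraries contain amplification and misfolding artifacts the
  simulator does not model; wet-lab data should be inspected with the QC
  totals the counting stage emits.
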