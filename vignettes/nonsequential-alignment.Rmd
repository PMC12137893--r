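---
title: "Non-sequential structure alignment as an entropic partial assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-sequential structure alignment as an entropic partial assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsalign)
```

## The problem

Classical pairwise structure alignment assumes residue order is conserved: if
residues $i$–$j$ and $i'$–$j'$ are aligned and $i < i'$, then $j < j'$. That
assumption powers dynamic-programming aligners but fails on circular
permutations and segment swaps, where two proteins share a 3D fold whose chain
topology differs. `nsalign` drops the ordering assumption entirely and
searches for the best *partial injective* residue correspondence between two
superposed C$\alpha$ traces.

## The model

### Partial assignment with explicit gap states

Given chains $u_1,\dots,u_m$ and $v_1,\dots,v_n$, each sequence is augmented
with a gap element. A correspondence is a gap-bi-permutation matrix
$X \in \{0,1\}^{(m+1)\times(n+1)}$: every real row and column carries exactly
one unit (to a real partner or to the gap state), and the gap-to-gap corner is
fixed at 1. With a similarity matrix $S$ — interior entries from the residue
pair score below, gap border entries holding the gap score $g$, corner 0 —
the alignment problem is

$$\max_X \sum_{i,j} S_{ij} X_{ij}$$

subject to those unit constraints. Unlike classical LSAP, leaving a residue
unaligned is an explicit, scored decision, not an inference-stage afterthought.

### Similarity: the SP-score model

After rigid superposition, a residue pair at distance $d$ (Å) scores

$$s(d) = \frac{1}{1 + d^2/d_0^2} - 0.2 \quad (d < 2 d_0), \qquad s(d) = 0
\text{ otherwise},$$

with a *size-independent* $d_0 = 4$ Å, so only genuinely close pairs ever
score, regardless of chain length. An alignment's aggregate SP-score is
$L^{\alpha-1} \sum_{d_i < 2 d_0} s(d_i)$ with $\alpha = 0.3$, where $L$
counts the pairs inside the cutoff. The printed definition of $L$ ("aligned
core residues") is ambiguous; we count core *pairs* (those inside the
cutoff), so pairs beyond the cutoff neither contribute nor dilute.

### Cost transform

Maximization becomes minimization through dual shifts: with every row and
column shift set to $c = \max S + \epsilon$ ($\epsilon = 0.5$) and the
gap–gap coefficient 0, the interior cost is $2c - S_{ij}$, gap borders
$c - S$, corner 0 — all entries non-negative by construction, with order
exactly reversed relative to $S$.

### Entropic relaxation and the semi-relaxed Sinkhorn iteration

The combinatorial problem is relaxed to the gap-bi-stochastic polytope and
regularized:

$$\min_P \sum_{ij} C_{ij} P_{ij} + \tfrac{1}{\lambda} \sum_{ij} P_{ij}
\log P_{ij},$$

with unit constraints only on the $m$ real rows and $n$ real columns (the gap
margins are free — "semi-relaxed") and the corner pinned at 1. The optimum
has the scaling form $P_{ij} \propto e^{f_i} e^{-\lambda C_{ij}} e^{g_j}$,
found by alternately normalizing constrained rows and columns of the kernel
$e^{-\lambda C}$ with the gap-state duals frozen at zero. Because the entropy
weight is $1/\lambda$, *larger* $\lambda$ sharpens the coupling toward the
exact assignment; smaller $\lambda$ spreads mass and favours coverage. (The
source material describes both directions in different places; we implement
the objective above literally, and the `run_sweep()` driver reports — never
asserts — the empirical coverage direction.)

### Inference and direction selection

The discrete alignment takes each row's argmax column (gap column = leave
unaligned), eliminating non-unique targets by keeping the largest coupling
mass (ties: smallest index); the column direction is symmetric. Both
candidates are re-superposed by Kabsch on their own pairs and the one with
the higher TM-score wins (ties go to the row direction). TM-score is
normalized by the shorter chain — it is used *only* for this binary choice,
never as the similarity model.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `lambda` | 100 | — | entropy sharpness; coverage–fidelity control |
| `epsilon_shift` | 0.5 | similarity | margin of the cost transform, keeps $C > 0$ |
| `tmax` | 5000 | iterations | Sinkhorn cap; best-effort result beyond it |
| `tol` | 1e-6 | — | maximum marginal violation at convergence |
| `alpha` | 0.3 | — | SP-score length exponent |
| `d0` | 4 | Å | SP-score normalization; cutoff is $2d_0 = 8$ Å |
| `gap_score` | 0 | similarity | reward for leaving a residue unaligned |
| SO threshold | 3.5 | Å | structure-overlap boundary (inclusive) |
| `seed_window` / `seed_stride` | 20 / 5 | residues | fragment seeding grid |

The gap score defaults to 0: a residue pair exactly at the similarity cutoff
ties with a gap. The source material never prints a numeric gap penalty (it
lives in unavailable supplementary code), so it is an exposed parameter
rather than a guess.

## Numerical choices

* **Log domain.** The kernel $e^{-\lambda C}$ underflows at $\lambda = 100$
  (costs are $O(1)$, so entries reach $e^{-300}$); all scaling is done on the
  dual potentials with log-sum-exp, in compiled code.
* **Convergence and degenerate ties.** Convergence is declared when both
  constrained margins are within `tol`. When the gap route for a pair
  *exactly* ties the direct route ($S_{ij} = 0$ against gap score 0 — the
  normal situation for every residue pair beyond the 8 Å cutoff), the local
  contraction rate degrades and the violation decays like $O(1/t)$: such
  problems hit `tmax` with `converged = FALSE` and a perfectly usable
  best-effort coupling. This is intrinsic to Sinkhorn at large $\lambda$,
  not a defect; the alignment inferred from the capped coupling is stable
  long before the margins reach $10^{-6}$.
* **Iteration budget vs. $\lambda$.** The iteration count needed for fixed
  accuracy grows roughly linearly with $\lambda$. The default `tmax = 5000`
  is calibrated to the default $\lambda = 100$; the sharp-limit test harness
  therefore scales the budget as $\max(5000, 50\lambda)$ when it pushes
  $\lambda$ to 800.
* **Monotonicity caveat.** The *entropic objective* improves monotonically
  with $\lambda$, but the argmax-*rounded* discrete alignment does not have
  to: on a small fraction of random instances the coupling at a mid-range
  $\lambda$ rounds to a worse total similarity than at a smaller $\lambda$,
  even at full convergence. The acceptance suite reports how many of its 100
  random instances are monotone rather than pretending this is a theorem.
* **Tie-breaks.** Argmax ties inside a row or column take the smallest
  index. The exact solver breaks optimum ties toward fewer matched pairs and
  then the lexicographically smallest pair set, implemented as an
  infinitesimal cost perturbation ($\sim 10^{-7}$ relative, far below every
  comparison tolerance).
* **Exact oracle.** The exact partial assignment is reduced to a square
  $(m+n)$ assignment problem (each row/column owns a private gap slot;
  gap–gap cells are free) and solved with a Jonker–Volgenant shortest
  augmenting path implementation. It exists to certify the Sinkhorn pipeline
  and is itself certified against exhaustive enumeration on small instances.
* **Degenerate inputs.** Chains with nothing under the 8 Å cutoff yield an
  empty alignment (CLI exit code 2, distinct from hard errors); RMSD of an
  empty alignment is an error, SO of one is 0 by logged convention;
  alignments with fewer than 3 pairs skip Kabsch re-superposition and are
  scored under the supplied frame.

## What the synthetic generator emulates — and what it does not

`make_helix_chain()` builds an ideal α-helical C$\alpha$ trace (radius
2.3 Å, rise 1.5 Å, 100°/residue — the textbook geometry, asserted only
through its 3.8 Å C$\alpha$ spacing). `rearrange_segments()` permutes
*record order only* (circular permutation or segment swap), leaving every
coordinate in place, so the ground-truth correspondence is exact and the
truth superposition is the identity; `jitter_coords()` then adds seeded
isotropic Gaussian noise (σ = 0.3 Å for the standard "divergent homolog"
fixture) to the target only, after rearrangement.

This stated world exercises exactly what the solver claims: recovery of
non-sequential correspondence under rigid-body geometry and moderate noise.
It does **not** emulate real proteins: no side chains, no secondary-structure
diversity, no conformational (flexible) change, no insertions of novel
residues. A green recovery test therefore establishes solver correctness on
rigid rearrangements, not benchmark performance on curated datasets. One
generator-specific trap is worth knowing: an ideal helix is translationally
self-similar, so *short* seeding windows (well under two turns) can lock onto
a wrong-shift registration whose SP-score is only marginally below the true
one. The default 20-residue window spans enough rise to disambiguate.

## Design decisions

* Internal residue indices are 1-based contiguous (idiomatic R); all file
  output uses author residue numbering from the PDB.
* PDB only (first model, first altloc, residues lacking a C$\alpha$
  skipped, HETATM C$\alpha$ such as MSE accepted — each logged at INFO);
  mmCIF is out of scope.
* The built-in fragment-seeded superposer is an intentionally simple
  stand-in for full superposition engines; for fidelity to an external
  engine, import its rotation matrix (`--matrix`, the `-m` dialect) — the
  solver is agnostic to where the frame came from. Whether to iterate
  alignment ↔ superposition or run a single pass is configurable
  (`max_rounds = 1` gives single-pass); the keep-best criterion is SP-score,
  the model's own final score.
* The ablation mode (`gap_modeling = FALSE`, CLI `--no-gap`) solves the
  classical entropic LSAP: gap states removed, the shorter chain's margin
  fully constrained, so every short-chain residue is matched before
  inference-stage elimination — the contrast that motivates explicit gap
  modeling.

## Known limitations

Flexible (multi-domain) alignment, secondary-structure-aware scoring,
sequence-order-aware hybrid modes and dataset-scale benchmarking are out of
scope. The Sinkhorn cap returns best-effort couplings on tied instances (see
above). The exact solver is practical to a few hundred residues but is an
oracle, not the production path.
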