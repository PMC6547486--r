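---
title: "An angle- and distance-dependent statistical potential for protein model quality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An angle- and distance-dependent statistical potential for protein model quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`andis` implements an atomic knowledge-based potential for ranking candidate
protein structures (decoys) against each other and against the native. The
score is a sum over heavy-atom pairs that are far in sequence (residue
separation $\ge 7$) but close in space (distance $< r_{cut}$). Each of the
167 residue-specific heavy-atom types carries a local right-handed frame
built from the atom and its two bonded neighbours ($V_x$ along the first
neighbour, $V_z$ normal to the neighbour plane, $V_y = V_z \times V_x$; the
next-neighbour bonded atom stands in when an atom has a single bonded heavy
neighbour, and the shipped connectivity table fixes the neighbour order so
frame construction is deterministic). An ordered pair $(a, b)$ is then
described by its distance $r_{a,b}$ and five angles: the polar/azimuth
angles of $r_{ab}$ in frame $a$ ($\theta_a$, $\varphi_a$), the same for
$r_{ba}$ in frame $b$ ($\theta_b$, $\varphi_b$), and the dihedral $\chi$
between the planes $(r_{ab}, V_z(a))$ and $(V_z(b), r_{ba})$ about the pair
axis.

Distances below 15 Å are split into 29 bins (one wide bin up to 2.2 Å,
0.4 Å bins to 7 Å, 0.5 Å bins to 15 Å) and every angle into 12 equal bins,
giving the $5 \times 167 \times 167 \times 29 \times 12$ count tensor. With
the angles treated as conditionally independent given the distance bin, the
angle potential is the inverse-Boltzmann log-ratio per angle kind

$$E^{AG} = -\sum_i \ln \frac{p^{OBS}[\mathrm{angle}_i(s) \mid r(d)]}
                           {p^{REF}[\mathrm{angle}_i(s) \mid r(d)]},$$

with the reference taken as the mean of the observed distribution over the
12 angle bins, i.e. $E = -\ln(12\,p^{OBS})$, in units of $k_BT \equiv 1$
(only rankings matter). Every bin starts from a 0.1 pseudocount, and any
(kind, type pair, distance bin) slice observed fewer than 20 times is set
to zero — too few observations to trust the inversion.

Two further ingredients make the distance cutoff a meaningful dial:

* **Effective atomic interactions** (cutoffs $\le 9$ Å). A pair is damped
  when a third heavy atom $x$ within 7 Å of both endpoints subtends an
  angle $\alpha = \angle a\,x\,b > 60^\circ$, by a factor
  $(180 - \alpha)/180$ per such shielder (weight 1 when none). Shielders
  closer than 2 residues to either endpoint, or closer than 7 residues to
  both, are ignored. Weights are applied both when accumulating training
  counts (the default `"weighted"` derivation mode, recorded in the matrix
  header) and when scoring.
* **Random-walk reference pair potential** (cutoffs $\ge 10$ Å). A
  distance-only energy $E^{RW}(r_{a,b}) = -\ln(N^{OBS}/N^{EXP})$ whose
  expected counts follow an ideal freely-jointed chain with rigid step
  (Kohn) length $l$: per training protein of length $L_p$ the reference
  density is proportional to
  $(r/r_{cut})^2 \sum_{n=1}^{L_p} e^{-3r^2/2nl^2} n^{-3/2}$, normalised at
  $r_{cut}$.

The total energy switches with the cutoff, which is the user's main dial:

* $r_{cut} \le 9.0$: $\sum w^{m,n} E^{AG}$ (shielding-weighted angle
  energies; sharpest native recognition),
* $r_{cut} = 9.5$: $\sum E^{AG}$ with $w \equiv 1$,
* $10 \le r_{cut} \le 15$: $\sum (0.5\,E^{AG} + E^{RW})$ (the combined
  potential; best decoy discrimination).

Pairs exactly at the cutoff are excluded (`distance < r_cut` throughout).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `r_cut` | 15 Å | scoring cutoff, 0.5 Å grid on [7, 15]; 7 Å recommended for native recognition |
| residue separation | $\ge 7$ | minimum sequence separation of interacting pairs |
| pseudocount | 0.1 | initial count of every angle bin |
| occurrence threshold | 20 | minimum raw observations for a usable angle slice |
| shielding radius / angle | 7 Å / 60° | third-atom window and activation angle |
| Kohn length `l` | 3.8 Å | random-walk step; the virtual CA-CA distance. The reference work names the constant but not its value, so it is exposed as an argument and recorded in the matrix header |
| RW cap | +10 | energy assigned to observed-zero cells, keeping scores finite |

## Numerical choices

* **Frame convention.** Any fixed orthonormal convention is self-consistent
  as long as derivation and scoring share it; ours is $V_x$ along the first
  listed neighbour. Energies are therefore not interchangeable with matrices
  produced by other implementations of orientation-dependent potentials.
* **$\chi$ range.** The dihedral is mapped to $[0, 360)$; under swapping the
  pair direction both plane normals and the axis flip, so the same value
  serves both directions. Degenerate geometries (pair axis parallel to
  $V_z$) set $\chi = 0$ by convention.
* **Binning.** Bins are half-open $[lo, hi)$ with the single exception
  $\theta = 180^\circ \to$ bin 12, making the partitions exact.
* **Mirror accumulation.** Each unordered pair is accumulated in both
  directions with types and angle roles swapped, so the count tensor is
  mirror-symmetric by construction and scoring one direction per pair is
  sufficient.
* **Random-walk expected counts.** The reference density is evaluated at
  each distance bin's midpoint, multiplied by the bin width, and normalised
  per protein so expected counts sum to that protein's observed pair total
  within the reference cutoff. Without the bin-width factor the unequal
  0.4/0.5 Å bins would leak $|\ln \Delta r|$-sized offsets into the
  energies; with count conservation a corpus actually drawn from the
  reference yields energies that vanish, which is the defining property of
  a reference state. `r_cut` in the reference is fixed to 15 Å at
  derivation (the maximum distance considered), since the combined mode
  only consults $E^{RW}$ and a single reference cutoff must match the
  accumulated per-protein totals.
* **Occurrence threshold on raw counts.** The threshold compares unweighted
  observation counts even in weighted mode — it is about statistical
  sufficiency, not about interaction strength.
* **Degenerate inputs.** Atoms whose frame neighbours are missing (trimmed
  decoys) or collinear are skipped and the affected pairs dropped;
  `score_structure()` reports the fraction of expected heavy atoms present
  as `coverage`. Chains with author-numbering gaps are accepted for scoring
  and renumbered consecutively; the separation rule always uses the index
  in the retained sequence. Population standard deviation (divide by $n$)
  is used in the Z-score; `enrichment20` uses $k = \max(1,
  \lfloor 0.2N \rfloor)$ with stable tie-breaking.
* **Terminal atoms.** `OXT` and other terminal variants are not among the
  167 types and are dropped on reading. Backbone `N` of residue 1 and `C`
  of the last residue use intra-residue fallback neighbours (`CA`,`C` /
  `CA`,`O`). Nonstandard residues (including selenomethionine) are
  rejected rather than remapped.

## What the synthetic generator emulates

Everything in the test suite runs on synthetic structures, because the
training sets and decoy collections used in production are external
downloads. `build_chain()` constructs all heavy atoms from standard
internal coordinates on ideal helix or extended backbones.
`make_training_corpus()` produces two-helix "hairpins": in the `"packed"`
pose the second helix sits antiparallel alongside the first (interaxial
offset ~9 Å with ~10° orientation scatter and 0.08 Å coordinate jitter),
giving the reproducible packing geometry that a statistical potential is
supposed to learn, concentrated on an alanine-rich background alphabet so
the pair statistics reach the occurrence threshold with ~50 chains — the
desk-scale stand-in for the statistical depth of a large non-redundant
training set. The `"random"` pose instead samples the relative orientation
uniformly, which makes cross-segment angle distributions nearly uniform —
the right null for testing that unbiased corpora give near-zero energies,
and the carrier for planted angular biases in parameter-recovery tests.

`make_decoys()` perturbs every coordinate with i.i.d. Gaussian noise at
levels 0.25/0.5/1/2 Å and writes a pseudo-quality score
$\exp(-\mathrm{RMSD}/3)$ (direct coordinate RMSD, no superposition). The
levels span near-native to badly wrong models, emulating the quality range
of real decoy sets; the score is a monotone stand-in for TM-score, which
is all the evaluation metrics consume.

What this does **not** emulate: real side-chain rotamer diversity, beta
sheets and loops, compact globular packing beyond a single helix pair,
physically plausible decoy error modes (fragment misassembly, register
shifts), or experimental coordinate error. Passing tests therefore
demonstrate the machinery — binning, inversion, reference states, metric
arithmetic, and the qualitative short-cutoff/long-cutoff trade-off — not
benchmark-grade performance on real proteins; for that, derive from a
few thousand experimental chains and score real decoy sets.

## Problem sizes in the shipped experiments

The test suite derives from corpora of 3-50 chains of 30 residues;
parameter recovery uses 20 corpora of 40 chains; random-walk
self-consistency uses $3 \times 10^5$ reference-sampled distances; the
end-to-end experiment derives from 50 chains and evaluates five 20-decoy
sets at cutoffs 7 and 15 Å. These sizes keep the full suite within a few
minutes on one CPU while leaving every statistical check comfortably
powered.

## Known limitations

* Single chains only: no symmetry mates, ligands, solvent or inter-chain
  scoring; no per-residue local quality profile.
* The potential matrices are convention-bound (frame axes, $\chi$ sign) and
  not portable to other implementations.
* TM-score/GDT_TS are consumed from sidecar tables, never computed.
* With sparse training corpora many angle slices fall below the occurrence
  threshold and score zero; the random-walk cap (+10) then dominates
  badly-perturbed structures. That is the intended failure direction
  (unseen geometry scores badly), but absolute energies from small corpora
  should not be compared across proteins — use `per_pair_normalize` or
  compare within a decoy set only.
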