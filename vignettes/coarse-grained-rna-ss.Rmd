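---
title: "Assigning RNA secondary structure to coarse-grained 3D models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning RNA secondary structure to coarse-grained 3D models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cssr)
```

## The problem and the model

RNA secondary structure (the set of canonically base-paired positions) is
usually annotated from full-atomic 3D coordinates by detecting hydrogen-bond
geometry between bases.  That route is closed for coarse-grained inputs:
phosphate-only chains in low-resolution experimental structures, or the
reduced representations used by many structure-prediction and simulation
programs.  `cssr` instead treats base pairing as a *statistical geometry*
problem over whatever atoms are available, restricted to ten types — P, the
eight sugar/backbone heavy atoms C5′–O3′, and the glycosidic nitrogen
(mapped from N9/N1 to a single type `N`).

For every candidate pair (i, j) — bases compatible with Watson–Crick or
wobble pairing, each nucleotide retaining at least one recognized atom, and
an intra-chain separation of at least `min_separation` — the score is

$$\mathrm{CSSR}(i,j) \;=\; \frac{1}{|T|}\sum_{t \in T}
  \exp\!\left(-\frac{\Delta_t^2}{2\sigma_t^2}\right),$$

where $T$ ranges over the evaluable sub-terms: per atom type, three
distances (the pair distance and the two stacking distances $i{+}1\!:\!j{-}1$
and $i{-}1\!:\!j{+}1$), two pseudo-bond angles (vertex at i and at j) and two
pseudo-torsions (i-side lead and j-side lead).  $\Delta_t$ is the deviation
of the observed value from the calibrated mean (computed on the circle for
angles and torsions) and $\sigma_t$ the calibrated spread.  All sub-terms
have equal weight.  The stacking-aware terms encode that canonical pairs
essentially always occur inside or at the edge of helices, which is what
lets a single atom type carry enough signal.

Two properties matter for coarse-grained inputs.  First, a sub-term that
cannot be computed (missing atom, missing neighbor, chain end) is dropped
and the mean is renormalized over what remains; with only a phosphate trace
at most 7 sub-terms contribute, yet the score still spans $[0,1]$ and the
fixed acceptance cutoff remains meaningful.  Second, the sub-term set maps
onto itself under $i \leftrightarrow j$ (pairs are canonicalized to $i<j$
before scoring), so the score is exactly symmetric.

Scored pairs are filtered greedily: all pairs with score ≥ `cutoff` are
sorted by descending score and accepted iff neither nucleotide is already
used.  There is no planarity constraint, so crossing (pseudoknotted) pairs
are assigned whenever the geometry supports them.  Score ties break by
smaller i, then smaller j — an arbitrary but deterministic rule.

### Assumptions and scope

* Only canonical A:U, C:G and G:U pairs are modeled.  Hoogsteen and
  sugar-edge pairs are out of scope: their geometries are not represented
  in the calibrated classes.
* Residues whose names cannot be mapped to a parent base (a bundled table
  covers common modifications such as pseudouridine or 1-methylguanosine)
  are retained in the chain but never enter a pair.
* Assignment is per model; multi-model files contribute one model chosen by
  `model_index`.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 0.5 | score | acceptance threshold of the greedy filter; 0.5 balances precision and recall across atom subsets |
| `min_separation` | 4 | nt | minimal intra-chain |i−j|; encodes the 3-nt minimal hairpin loop |
| `atoms` | all ten | — | atom-subset ablation (e.g. `"P"` for a phosphate trace) |
| `inter_chain` | FALSE | — | include pairs across chains (no separation rule is applied between chains, as there is no meaningful sequence separation there) |
| `sigma_floor` | 0.01 | Å / degrees | lower clamp on calibrated spreads; keeps scores defined when calibrating on noise-free ideal geometry |
| `average` | `"flat"` | — | equal weight per sub-term; `"nested"` averages within atom types first (sensitivity analysis) |
| `min_terms` | 1 | — | minimal number of contributing sub-terms for a pair to be scored |

## Calibration

`cssr_calibrate()` fits one (mean, spread, count) cell per
(pair class × atom type × sub-term) from structures with reference pair
annotations.  Distances use plain moments.  Angles and torsions use
circular statistics (mean direction, circular SD), because torsion
distributions can straddle ±180° where the linear SD explodes.  Cells with
fewer than two observations are omitted; a missing cell simply removes that
sub-term from scoring.  Design choices taken where the procedure was
genuinely open:

* Pair orientation is canonicalized to $i<j$ before bucketing, rather than
  pooling both orientations into symmetrized cells.
* The three distance offsets are estimated as separate cells even though
  they coincide on ideal helices — on real (or noisy) data they need not.
* No outlier trimming by default (plain moments); a `trim` fraction is
  available but off.
* Wobble and Watson–Crick classes are estimated independently.  Wobble
  observations are rarer, so any calibration set intended for closure-type
  use must guarantee G:U coverage (the bundled closure sets include a
  fixed-sequence duplex with two interior G:U steps for exactly this
  reason).

The packaged table (`cssr_default_params()`) is calibrated on a bundled
synthetic ensemble — 80 noisy ideal duplexes, 12–20 bp, coordinate noise
0.5 Å, 15% wobble steps — so the package works with no external data.  It
is *not* a substitute for statistics from annotated experimental
structures: users with real calibration data should fit and save their own
table (`save_params()` / `load_params()`, versioned TSV).

## The synthetic-data generator

The generators provide coordinate fixtures with exact ground truth for
calibration, testing and the simulated benchmark.

**Geometry.**  Chains are built from a cylindrical-template helix: each
atom type sits at a fixed (radius, phase, z-offset) in its nucleotide's
helix frame, with A-form-like rise (2.81 Å) and twist (32.7°); the partner
strand is the per-base-pair dyad image, so every interior pair is exactly
congruent.  The template constants are internally consistent configuration,
chosen to give realistic paired-atom distances (P–P ≈ 18 Å, C1′–C1′ ≈ 10 Å),
not literature atomic coordinates — the pipeline only ever compares
fixtures against statistics calibrated on the same generator.  Hairpin
loops and pseudoknot linkers place their first and last residues on the
helical continuation of the adjacent stem strand, so stem-closing pairs
retain exact stacking geometry; loop and linker bases are drawn from
{A, C}, which keeps unpaired regions free of incidental canonical
complementarity.  In the H-type pseudoknot, the two junction pairs where
stems abut have 3 of 7 sub-terms per atom type off-template; their
noise-free score is 4/7 ≈ 0.571, deliberately above the 0.5 cutoff, so
noise-free pseudoknots are recovered exactly.

**Noise.**  `add_noise()` applies i.i.d. isotropic Gaussian displacement
per atom, seeded and reproducible, with an optional per-atom-type scale.
The benchmark ensemble (`make_benchmark()`) uses a mobility profile
(P 1.15, O5′ 1.10, C5′/O3′ 1.05, C4′/C3′ 1.00, C2′/O4′ 0.95, C1′ 0.90,
N 0.85) emulating the backbone mobility gradient familiar from B-factors
and from coarse-grained model error: the phosphate, farthest from the
base-pairing interface, is the least accurately placed atom, the glycosidic
nitrogen the most.  Calibration ensembles use uniform noise at the same
base sigma.  Under matched calibration the per-pair recall of every atom
type would be statistically identical; the mobility gradient is what gives
the single-atom ladder its realistic ordering (all atoms ≥ P/C4′/C1′ ≥ C4′
≥ P), driven by the deterministic per-atom signal-to-spread ratio rather
than by tuned thresholds.

**What the fixtures do not emulate.**  Real helices are irregular
(sequence-dependent twist/rise, non-ideal sugar puckers), wobble pairs are
sheared rather than template-identical to Watson–Crick pairs, real noise is
anisotropic and correlated along the chain, and real structures contain
non-canonical pairs, bulges and multiloops.  Passing the synthetic suite
therefore demonstrates the correctness and robustness of the machinery —
scoring, renormalization under missing atoms, conflict resolution,
serialization — not the accuracy a particular calibration table will reach
on experimental data; that accuracy is a property of the calibration set
supplied.

**Problem sizes.**  The simulated benchmark uses 50 hairpin fixtures
(stems 6–14 bp, loops 4–8 nt, 10% wobble) at 0.5 Å base noise, and 30
fixtures per noise level for the degradation ladder — large enough that the
mean per-target F1 has a standard error of about 0.01, small enough that
the whole suite runs in seconds.

## Numerical choices

* Angles are degrees throughout; torsions follow the IUPAC sign convention
  and reverse-order invariance ($\mathrm{dih}(p_4,p_3,p_2,p_1) =
  \mathrm{dih}(p_1,p_2,p_3,p_4)$).
* Degenerate geometry (zero-length angle arms, collinear torsion frames,
  tolerance 10⁻⁶ Å) is an error in the scalar kernels and an *absent value*
  in vectorized scoring — a degenerate sub-term is simply not evaluable.
* A circular mean is refused when the resultant length is ≈ 0 (the mean
  direction is undefined).
* `sigma_floor` (0.01 Å/degrees) prevents division blow-ups for
  zero-variance calibration sets; on ideal fixtures every cell sits exactly
  at the floor and true pairs score exactly 1.
* Parameter files store numbers at full precision (`%.17g`), so
  `load_params(save_params(x))` reproduces the model exactly.
* CT/BPSEQ have no chain-break marker; CT encodes breaks via zeros in the
  previous/next columns (recovered on read), BPSEQ reads back as a single
  chain.  Dot-bracket uses `&` separators and assigns crossing pairs to the
  lowest non-crossing bracket level: `()`, `[]`, `{}`, `<>`, then `Aa` …

## Evaluation conventions

A predicted pair is a true positive only if the identical unordered index
pair is in the reference (no one-off slippage credit).  The true-negative
universe is all $L(L-1)/2$ unordered position pairs, giving the standard
MCC.  Two empty structures count as perfect agreement; one empty side gives
F1 = 0.  Per-target aggregation is an unweighted mean with SEM
(sample SD / √n; 0 for a single target).

## Known limitations

* No Hoogsteen/sugar-edge or other non-canonical pair classes.
* No base-pair edge or cis/trans orientation labels.
* No DNA support, no symmetry expansion of biological assemblies.
* The packaged parameter table is synthetic; real-data accuracy requires
  real-data calibration.
* The score is used here only for assignment; no gradient interface is
  provided for use as a simulation energy term.
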