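---
title: "A torsional model of DNA denaturation bubbles and single-deuterium scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A torsional model of DNA denaturation bubbles and single-deuterium scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`dnabubbles` treats double-stranded DNA as two chains of torsional pendulums.
Each nitrogenous base $i$ on chain $j \in \{1,2\}$ is a rigid body of
rotational inertia $I_{ji}$ that rotates by an angle $\varphi_{ji}(t)$ about
the sugar–phosphate backbone, at distance $R_{ji}$ from it. Newton's second
law for base $i$ of chain 1 (interior positions; chain ends couple to their
single neighbour) reads

$$
I_{1i}\ddot\varphi_{1i} =
  K\,(\varphi_{1,i-1} - 2\varphi_{1i} + \varphi_{1,i+1})
  - \delta_i k_{12,i} R_{1i}(R_{1i}+R_{2i})\sin\varphi_{1i}
  + \delta_i k_{12,i} R_{1i}R_{2i}\sin(\varphi_{1i}-\varphi_{2i})
  - \beta_{1i}\dot\varphi_{1i} + F_0\cos\omega t ,
$$

with the mirror-image equation on chain 2. The three force groups are the
backbone torsion (which also absorbs base-stacking stiffness into $K$), the
hydrogen-bond coupling to the complementary base, and the environment
(viscous dissipation $-\beta\dot\varphi$ plus a spatially uniform periodic
drive $F_0\cos\omega t$). The rest configuration is
$\varphi_{1i}=0,\ \varphi_{2i}=\pi$: bases facing each other across the
helix axis.

**Bond breaking.** Each pair carries an indicator $\delta_i \in \{0,1\}$.
The pair's *stretch energy*

$$ E_i = k_{12,i} R_{1i} R_{2i}\,\bigl(1 + \cos(\varphi_{1i}-\varphi_{2i})\bigr) $$

is zero at rest and maximal when the bases align. After every completed
integration step, $\delta_i \to 0$ wherever $E_i$ exceeds the pair's
critical energy $E_{cr,i}$, and a broken pair is restored
($\delta_i \to 1$) when $E_i$ falls back below it. Exact ties leave
$\delta_i$ unchanged, which prevents chatter at the threshold. $E_i$ is
evaluated from the angles regardless of the current $\delta_i$, since the
same quantity must decide both directions.

**Deuteration.** A single $^2$H/$^1$H substitution at position $i$
multiplies both $k_{12,i}$ and $E_{cr,i}$ by $k_D$ (default 1.05: the
deuterium bond is 5 % stronger). Inertia and dissipation are left alone —
one extra neutron on a whole base is negligible at this resolution.
Exactly two scalar entries of the parameter arrays differ from the
baseline, a property the tests assert.

## Sign conventions: conservative vs literal coupling

Writing the bond interaction as a potential

$$
V_i = \delta_i k_{12,i}\Bigl[(R_{1i}+R_{2i})\bigl(R_{1i}(1-\cos\varphi_{1i})
      + R_{2i}(1+\cos\varphi_{2i})\bigr)
      + R_{1i}R_{2i}\bigl(1+\cos(\varphi_{1i}-\varphi_{2i})\bigr)\Bigr]
$$

and taking $-\partial V_i/\partial\varphi_{ji}$ reproduces the chain-1
torques above exactly, but yields the *opposite* sign on the chain-2
relative-angle term from the traditional printed form of this model family.
The printed pair of equations is not jointly derivable from any single
interaction potential. The package defaults to the potential-derived
(**conservative**) torques, so that the rest state is a true energy minimum
and an energy audit is possible (with $\beta=0$, $F_0=0$ and no bond events,
total mechanical energy is conserved up to the integrator's truncation
error — a test checks this). A **literal** mode reproduces the printed signs
verbatim for comparison; both modes share the rest state.

Similarly, $\delta_i$ is traditionally printed only on the single-angle
coupling term. By default the package gates *both* coupling terms
(`delta_gates_both = TRUE`): a broken pair is mechanically decoupled from
its partner. The literal placement is available as a flag.

With per-letter backbone constants the conservative mode uses segment
springs $K_{seg}(i)$ between neighbours $i$ and $i+1$, so the backbone force
is again an exact gradient; with the uniform default $K$ this coincides
with the printed second-difference form.

## Parameters

The packaged default table (`inst/extdata/base_mechanics_default.tsv`)
carries representative values from the torsional-model literature for DNA;
it is a documented, overridable default rather than a measured input, and
every entry can be replaced through `base_mechanics()` or a key-value TSV:

| quantity | symbol | default | unit |
|---|---|---|---|
| rotational inertia (A/T/G/C) | $I$ | 7.61/4.86/8.22/4.11 ×10⁻⁴⁴ | kg m² |
| base-to-backbone distance (A/T/G/C) | $R$ | 5.8/4.8/5.7/4.7 ×10⁻¹⁰ | m |
| backbone torsional constant | $K$ | 2.27×10⁻¹⁸ | N m |
| dissipation coefficient | $\beta$ | 4.25×10⁻³⁴ | N m s |
| bond elastic constant (A–T / G–C) | $k_{12}$ | 0.062 / 0.096 | N/m |
| drive amplitude | $F_0$ | 0.526×10⁻²² | N m |
| drive frequency | $\omega$ | 0.4×10¹² | s⁻¹ |
| horizon / step | $T$, $\tau$ | 3×10⁻¹⁰, 10⁻¹⁴ | s |
| deuterium strength ratio | $k_D$ | 1.05 | — |

A–T and T–A pairs share $k_{12}$ and $E_{cr}$ (likewise G–C/C–G): bond
strength belongs to the pair kind, not the strand orientation. The critical
energy is scanned over the grid 0.250–0.600 ×10⁻²² N m in steps of
0.050×10⁻²² N m (`default_energy_grid()`); a scanned grid value replaces
the per-kind `ecr` defaults uniformly for that run. Config files carry
energies as exact decimal labels ("0.250") to avoid float-keyed joins.

## Bubble statistics

At each recorded sample $t_j = j\tau$ (the initial state is excluded;
$j$ runs from 1), the broken mask decomposes into maximal runs. A run of
length 1 is an *open state* (OS); longer runs are bubbles grouped as small
(2–4 bp), metastable (5–10 bp), large (11–30 bp), and very large (≥31 bp).
The occupancy fraction of a group is the summed length of its runs divided
by $n$, and the occupancy probability is the arithmetic mean over samples:

$$ P_\ell = \frac{1}{m}\sum_{j=1}^{m} q_{j\ell}. $$

Runs touching the sequence ends are ordinary maximal runs — a gene fragment
is linear, not circular.

## The substitution scan and the extremum-range classifier

For every grid energy and every position $i$, one deterministic simulation
with the substitution at $i$ yields $P_i$ per group, alongside the
all-protium baseline $P_0$ (recorded as position 0). The scan is
embarrassingly parallel, checkpointable, and involves no randomness.

Per (energy, group) cell the classifier splits positions into extremal
ranges around $P_i^{max}$, $P_i^{min}$, and $P_0$:

* **Maximum range** (requires $P_i^{max} > P_0 \ge P_i^{min} \ge 0$): the
  cut is $P_i^{max} - \tfrac1{10}(P_i^{max}-P_i^{min})$ when that still
  clears the midpoint $P_0 + \tfrac12(P_i^{max}-P_0)$, else
  $P_i^{max} - \tfrac14(P_i^{max}-P_0)$; members satisfy $P_i \ge$ cut
  (ties included).
* **Minimum range** (requires $P_i^{min} > 0$, $P_i^{max} \ne P_i^{min}$):
  mirror image around $P_i^{min}$.
* **Closed floor**: when $P_i^{min} = 0$ the members are the closed-state
  positions ($P_i = 0$) and the raw count $n^{CS}$ is reported alongside a
  corrected count $n^{CS}\bigl(1 - (n^{CS}/n_g)^2\bigr)$ — differentiated
  counting that discounts the range as closure becomes ubiquitous and
  vanishes when every position is closed. The typography of the source
  formula admits a second parenthesisation, $n^{CS}(1-n^{CS}/n_g)^2$; it is
  available behind the `correction` argument, both variants vanish at the
  all-closed boundary, and the minimal-parenthesisation reading is the
  default. Summary tables always show raw member counts; the corrected
  count sits in its own column.

Region summaries count members and A–T members per (energy, region, group),
with the all-closed "-" marker preserved, and aggregate to the A–T
percentages rounded half-away-from-zero to one decimal — presentation
rounding only.

## Association statistics

The 2×2 Yates-corrected chi-squared is implemented in its shortcut form
$N(|ad-bc| - N/2)^2/(N_A N_B N_S N_F)$ with the conventional clamp at zero
when $|ad-bc| \le N/2$ (the unclamped literal value is exposed for audit);
the suite cross-checks it against `chisq.test(correct = TRUE)` as an
independently coded textbook evaluation. The 3×2 omnibus test is the
Pearson statistic on 2 degrees of freedom with the three pairwise 2×2
comparisons Bonferroni-multiplied by 3. Kruskal–Wallis and Spearman wrap
the `stats` implementations behind the package's interface, with the
all-tied degenerate case returning $H = 0$, $p = 1$. Which margins populate
any particular published comparison (range counts vs region sizes) is
ambiguous in this analysis style; `range_contingency()` builds either
recipe and the package asserts neither.

## Synthetic data and what the tests do and do not show

`generate_sequence()` emulates only the composition structure of a real
gene: per-region A–T fractions hit their targets within half a pair, with
letters drawn uniformly within each class. It reproduces no dinucleotide
correlations, motifs, or biological structure, so passing tests demonstrate
the correctness of the machinery — not that any biological conclusion
transfers to a specific gene. The gene modelled in the packaged summary
tables is *not* shipped as a sequence (it is not public as part of those
tables); users supply their own FASTA to reproduce a full-gene scan.
`generate_mask_series()` produces prescribed bond-state trajectories
(constant, checkerboard, seeded Bernoulli) for exercising the run-length
statistics against closed forms; for a Bernoulli mask the expected
open-state count is $(n-2)p(1-p)^2 + 2p(1-p)$, which the suite checks to
within three standard errors.

## Numerical choices

* Classic fixed-step RK4 on the $4n$-dimensional first-order system;
  $\delta$ frozen within a step, bond update once per completed step.
  Sub-step event location is deliberately out of scope. The observed
  convergence order on a smooth two-pair problem is 4.0 (checked at
  $\tau_0 = 4\times10^{-15}$ s over 250 steps against a 16-fold refined
  reference).
* The stepping loop is compiled (Rcpp); the R-level `rk4_step()` /
  `update_bonds()` path is retained as the reference implementation and
  the suite asserts bit-level agreement between the two over a run with
  bond events.
* Strict inequalities in the bond rule; exact ties freeze the indicator.
* Monotone thresholding: re-thresholding one fixed stretch-energy
  trajectory at increasing $E_{cr}$ shrinks the broken set, so occupancy
  in runs of length ≥ L is weakly non-increasing for every L, and so is
  the total. Occupancy of an *exact* size band is not monotone — a
  shrinking long run can migrate mass into a smaller band — so the tests
  assert the tail/total law, which is the defensible content of
  "higher threshold, fewer bubbles".
* Toy test configurations use a stronger drive ($F_0 = 10^{-20}$ to
  $2\times10^{-19}$ N m) than the full-gene default, because short chains
  are much stiffer relative to the drive and would otherwise never cross
  the scanned thresholds; the choice only serves to exercise the breaking
  regime on 6–32-mers. Test problem sizes are $n \le 64$ with up to
  10,000 steps, and the end-to-end pipeline check runs a 24-mer over two
  energies and 2,000 steps, twice, comparing outputs byte for byte.

## Known limitations

* No thermal noise: the environment enters only through damping and a
  deterministic periodic drive, so every run is reproducible but thermally
  activated breathing is not modelled.
* No sub-step event detection; a bond that crosses the threshold inside a
  step breaks only at the step boundary.
* The helicoidal geometry, sequence-dependent stacking beyond the uniform
  $K$, and DNA–protein interactions are outside the model.
* Which of a pair's two or three hydrogen bonds carries the deuterium is
  not resolved; the substitution is a single multiplicative factor $k_D$
  on the pair's effective bond.
* A full-gene scan (per-position substitution × energy grid at
  $n \approx 10^3$, $m = 3\times10^4$) is an hours-scale computation;
  the checkpointing in `scan_positions()` exists for exactly that use.
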