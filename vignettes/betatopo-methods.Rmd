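---
title: "Methods: beta-sheet topology and replica-exchange thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-sheet topology and replica-exchange thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betatopo)
```

`betatopo` analyses the earliest ordered species on the amyloid
aggregation pathway: small oligomers (3–20 chains) of short peptides such
as the Sup35 fragment GNNQQNY, sampled by replica-exchange molecular
dynamics (REMD). This vignette documents the models and conventions the
package commits to, the tunable parameters, what the synthetic
generators do and do not emulate, and the known limitations.

## Hydrogen bonds

Bonds are assigned with the DSSP electrostatic energy between a donor
N–H group and an acceptor C=O group,

$$E = 27.888\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right)\ \text{kcal/mol},$$

with distances in Å and a bond wherever $E < -0.5$ kcal/mol. The −0.5
cutoff is DSSP's published constant and we keep it as the default
(`energy_cutoff` in `detect_hbonds()`) because it makes the criterion
reproducible without tuning. Two guards apply: any of the four distances
at or below 0.5 Å returns `Inf` (a clash is never a bond), and
same-chain pairs closer than 3 residues in sequence are excluded (the
DSSP convention; irrelevant for inter-chain sheets but it keeps helical
self-bonds out of β statistics). A 9 Å O–N pre-screen is a speed
optimization only — at that range the four reciprocal terms cancel to
well above the cutoff.

Coarse-grained backbones often lack the amide hydrogen the energy needs.
`reconstruct_amide_hydrogens()` places it 1.00 Å from N along the
normalized sum of the unit vectors C(i−1)→N(i) and CA(i)→N(i). Residue 0
of each chain gets no H — for GNNQQNY that residue is the N-terminal
glycine, which is excluded from bond counting anyway. The operation
never touches an existing H, so it is idempotent.

## Strand-attachment topology

The unit of clustering is the chain: a 7-residue peptide cannot form an
intra-chain sheet of interest, so one chain is one candidate strand.
Two strands are *attached* when at least one inter-chain backbone bond
survives the glycine exclusion — a deliberately permissive one-bond
cutoff, appropriate for a very short sequence. Sheets are connected
components of the attachment graph (computed with `igraph`; branched
attachments count as one sheet, since only sheet sizes are reported),
and the configuration type is the descending multiset of sheet sizes
(`"8 7 5"` = sheets of 8, 7, 5 strands; singletons are free chains).

Per adjacent pair:

* **Orientation** — sign of the least-squares slope of the bonded
  partner indices $j$ against $i$: positive = parallel, negative =
  antiparallel. A pair attached through a single distinct residue pair,
  or a tied fit, is *undefined*.
* **Register** — rounded median of $j - i$ (parallel) or
  $i + j - (L-1)$ (antiparallel, $L$ the strand length); 0 is
  in-register. The median resists a single stray bond; exact .5 ties
  round toward zero, a conservative bias toward "in-register" that we
  state rather than hide.
* **Sheet character** — fully parallel, fully antiparallel, or mixed;
  undefined pairs force mixed.

**β-content** is the fraction of residues participating in at least one
surviving inter-strand bond, with glycines included in the denominator
(they are excluded only from bond counting). We chose the hydrogen-bond
criterion over a dihedral one because the attachment analysis is
H-bond-topological throughout; a dihedral definition would import a
second, independent convention.

Two genuinely open table conventions were settled as follows:
"% parallel / % antiparallel" is computed over adjacent strand *pairs*,
not strands — a strand's orientation is only defined relative to a
neighbor — and is normalized including undefined pairs, so the three
fractions sum to 100 (consistent with published tables whose two printed
fractions sum to less than 100). Pair- and sheet-level statistics in
`tabulate_ensemble()` are pooled over all frames in the window
(equivalently, frame-averaged with weights proportional to the number of
pairs), which keeps every normalization invariant exact.

The default analysis window is the final half of the frames at each
temperature, overridable per call, mirroring the practice of averaging
over the converged tail of a run.

## Replica-exchange thermodynamics

Everything uses $k_B = 0.0019872$ kcal/mol/K and energies in kcal/mol.
The Metropolis exchange probability between replicas $(E_i, T_i)$ and
$(E_j, T_j)$ is $\min\!\big(1, e^{(1/k_BT_i - 1/k_BT_j)(E_i - E_j)}\big)$.

`twham()` solves the standard multiple-histogram equations in binless
(sample-based) form by fixed-point iteration on the log-normalizers,
with log-sum-exp throughout. Binless WHAM avoids the histogram bin width
as a hidden parameter. Defaults: tolerance $10^{-7}$ on the
log-normalizers, 10,000 iterations maximum (reaching the cap warns and
flags the result). Adjacent temperatures whose energy ranges fail to
intersect trigger a degraded-accuracy warning. This is the plain
temperature-WHAM; decorrelation-aware variants that exploit the exchange
trajectory are out of scope, as are error bars by block bootstrap.

`cv_curve()` evaluates $C_v(T) = (\langle E^2\rangle_T - \langle
E\rangle_T^2)/(k_BT^2)$ from the reweighted ensemble on a grid (default
spacing 0.5 K, never extrapolating beyond the ladder) and reads the
melting temperature off the grid argmax — matching how specific-heat
figures are read in practice — with ties resolving to the lowest
temperature. In the single-temperature case the weights are uniform and
the curve reduces to `specific_heat_direct()`, the population-variance
fluctuation formula.

Convergence (`specific_heat_convergence()`) compares Cv over two time
windows: converged iff the peak positions agree within `tol_T` (default
3 K) and the curves agree pointwise within `tol_c` (default 10%)
relative to the mean curve, evaluated only where the mean exceeds 10% of
its peak so that shot noise in the flat tails cannot fail an otherwise
converged run.

`demux_replicas()` replays the exchange log as permutation tracking —
each accepted swap exchanges the walkers in the two slots from that step
on — turning temperature-sorted frames back into continuous walker
trajectories. `detect_nucleation()` then reports, per walker, the first
frame at which any sheet reaches the seed threshold (default 2 strands),
reflecting the observation that aggregation is triggered by small
dimer/trimer/tetramer seeds.

`free_energy_difference(p1, p2, T)` $= k_BT\ln(p_1/p_2)$ converts two
populations into a free-energy difference; zero populations error by
default, with an explicit opt-in pseudo-count for sparsely sampled
states. Representative structures are selected by frequency of
occurrence: per dominant configuration type, the medoid frame under a
feature distance (sheet-size multiset, fraction of parallel pairs,
β-content), ties to the earliest frame. An alternative criterion
sometimes used in the literature — the structure that best resists a
temperature increase — has no operational definition we could commit
to, so `select_representatives()` implements only `mode = "frequency"`
and rejects anything else.

## Synthetic generators

The generators exist so that every analysis claim can be tested against
a known ground truth; they are first-class, tested code.

**Ideal sheets** (`build_sheet_assembly()`): flat, untwisted ladders —
strands along x at 3.4 Å rise per residue, the hydrogen-bond direction
along y at 4.8 Å strand spacing, sheets stacked 10 Å apart along z.
Antiparallel neighbors are reversed in x; register shifts are x-offsets
of shift × rise. The per-residue atom template was solved so that three
things hold simultaneously: backbone bond lengths sit inside the
validation ranges, the emitted amide H coincides *exactly* with the
bisector reconstruction convention, and the DSSP energy is ≈ −2.0
kcal/mol for every intended ladder bond while every unintended
donor/acceptor pair (neighboring residues, next-nearest strands at
9.6 Å, across sheets at ≥ 10 Å) stays above −0.5. The generator returns
bookkeeping (intended pairs, orientations, registers, bond lists,
bonded-residue fraction) that the tests compare against the classifier
output, demanding exact recovery. Sheet twist, side-chain packing and
thermal disorder are deliberately absent: passing these tests shows the
topology machinery is exact on its own definitions, not that it is
robust to distorted real-world geometry beyond what the H-bond cutoff
absorbs.

**Random coils** (`build_random_coils()`): chains built residue-by-
residue from backbone dihedrals drawn uniformly outside the β and
helical bands (rejection sampling), so initial sheet content is zero by
construction; placed with uniform random rotations at centroids 12–50 Å
apart (all pairs ≥ 12 Å, each chain's nearest neighbor ≤ 50 Å), in a
cubic box sized from the molar concentration (default 4.15 mM via
`box_edge_from_concentration()`; 3 chains → 106.3 Å, 20 chains →
200.0 Å). These are geometric starting configurations, not
Boltzmann-weighted coil ensembles.

**Temperature ladders**: logarithmic (constant neighbor ratio, e.g. 20
temperatures over 230–450 K) and Gaussian-quantile (equal quantiles of a
normal truncated to the bounds, concentrating replicas near a transition
at, e.g., 283 K). Published hand-tuned ladders will not be reproduced
exactly by the quantile construction; they can always be passed in
verbatim.

**Two-state REMD traces** (`simulate_two_state_remd()`): ordered state
stabilized by `delta_e` with the free-energy gap linearized around the
melting temperature, $\Delta G(T) = \Delta e\,(T/t_m - 1)$ — i.e.
constant $\Delta H = \Delta e$, $\Delta S = \Delta e/t_m$ — plus
Gaussian noise of width `sigma`; states resample from the Gibbs
distribution each step, and one random adjacent pair attempts a
Metropolis swap every `exchange_every` steps. The defaults used in the
tests, `delta_e` = 50 kcal/mol and `sigma` = 3 kcal/mol with
`tm` = 283 K, describe a sharp aggregation transition (logistic width
≈ 13 K) of the kind that shows up as a large potential-energy
discontinuity at ordering; they produce a single Cv peak within half a
grid step of `tm`. Because states are resampled independently each
step, the traces have no autocorrelation — WHAM sees effectively
independent samples, which is the clean regime for validating the
estimator, not a model of correlated MD output.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest
sizes chosen to exercise every code path with comfortable statistics:
100+ randomized sheet builds of up to 20 chains; two-state traces of
1,200–2,400 samples per temperature on a 12-temperature ladder
(240–340 K); closed-form Cv fixtures of 2,500–6,000 samples at 9
temperatures; 0.5 K Cv grids. WHAM converges in well under 200
iterations on all of these. Degenerate inputs are handled explicitly:
single-temperature traces reduce to direct averaging, empty pair tables
yield singleton sheets, windows that empty a temperature's series raise
errors rather than returning silent NaNs.

## Limitations

* The topology definitions are exact but convention-bound; a different
  register convention (e.g. mean-based) would shift borderline pairs.
* Plain T-WHAM assumes uncorrelated samples; on real MD data the
  reweighted Cv is a point estimate without error bars.
* The melting temperature is a grid argmax, so its resolution is the
  grid step (0.5 K by default).
* Side-chain interactions — the steric-zipper interface that
  distinguishes amyloid polymorphs at atomic detail — are outside the
  backbone representation entirely.
* PDB support covers the backbone dialect documented in
  `read_assemblies()`; exotic PDB features (insertion codes, altLocs)
  are ignored.
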