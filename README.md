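# betatopo

Analysis tools for the earliest stages of amyloid aggregation: given
backbone structures of small multi-chain peptide assemblies (trimers to
20-mers of short amyloidogenic peptides such as GNNQQNY) and per-replica
energy traces from replica-exchange simulations, `betatopo` classifies the
β-sheet topology of every configuration and computes the thermodynamics of
the order–disorder transition.

It is aimed at people running coarse-grained or all-atom REMD of peptide
oligomers who want reproducible answers to questions like: *how many
sheets, of how many strands? parallel or antiparallel, in or out of
register? what is the melting temperature, and has the simulation
converged? how strongly is one strand arrangement favored over another?*

## What it computes

**Hydrogen bonds.** Backbone N–H···O=C bonds are assigned with the DSSP
electrostatic criterion

E = 27.888 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)  kcal/mol,

a bond requiring E < −0.5 kcal/mol. Missing amide hydrogens are rebuilt on
the standard bisector convention (1.00 Å from N along the sum of the unit
vectors C(i−1)→N(i) and CA(i)→N(i)).

**Sheet topology.** Chains are clustered into β-sheets by strand
attachment: one surviving inter-chain hydrogen bond attaches two strands,
after discarding bonds through the N-terminal glycine. Sheets are the
connected components of this strand-attachment graph, and a structure's
*configuration type* is its multiset of sheet sizes written as descending
integers — `"8 7 5"` is three sheets of 8, 7 and 5 strands. Each adjacent
strand pair gets an orientation (sign of the least-squares slope of
bonded partner indices; single-bond attachments are *undefined*), a
register shift (rounded median of `j − i` for parallel pairs and
`i + j − (L−1)` for antiparallel ones), and each sheet a character
(fully parallel / fully antiparallel / mixed).

**Ensemble statistics.** `tabulate_ensemble()` turns classified frames
into per-temperature tables: configuration-type populations,
% parallel / antiparallel / undefined pairs, sheet-character fractions,
β-content and register fractions — each normalized block summing to 100.

**Thermodynamics.** Metropolis exchange probability
p = min(1, exp[(1/kT_i − 1/kT_j)(E_i − E_j)]), binless temperature-WHAM
reweighting across the ladder, specific-heat curves
Cv(T) = (⟨E²⟩_T − ⟨E⟩_T²)/(k_B T²) with the melting temperature at the
peak, convergence checks over two time windows, replica demultiplexing
into continuous walker trajectories, nucleation-event detection, and
population free-energy differences ΔΔG = k_B T ln(p₁/p₂)
(k_B = 0.0019872 kcal/mol/K).

**Synthetic fixtures.** Generators for idealized flat β-sheet assemblies
with prescribed sizes/orientations/registers (with full bookkeeping, so
every classifier claim is testable against a known ground truth),
random-coil starting boxes at a given molar concentration, log and
Gaussian-quantile temperature ladders, and a seeded two-state REMD energy
simulator with a placed melting temperature.

## Worked example

```r
library(betatopo)

# a 20-chain assembly: sheets of 8 (antiparallel), 7 (parallel), 5 strands
spec <- sheet_spec(c(8, 7, 5),
                   orientations = list(rep("antiparallel", 7),
                                       rep("parallel", 6),
                                       rep("antiparallel", 4)),
                   registers = 0L)
built <- build_sheet_assembly(spec)
rec <- classify(built$assembly)
print(rec)
#> topology: configuration type "8 7 5" (20 chains)
#>   17 strand pair(s), beta-content 76.4%
head(as.data.frame(rec$pairs), 3)
#>   a b n_hbonds  orientation register
#> 1 A B        5 antiparallel        0
#> 2 B C        5 antiparallel        0
#> 3 C D        5 antiparallel        0

# free-energy difference between antiparallel and parallel arrangements
# from their populations (24.1% vs 7.4%) at 300 K, in kcal/mol
round(free_energy_difference(24.1, 7.4, 300), 2)
#> [1] 0.7

# two-state REMD trace with a 283 K melting point; recover it by WHAM
ladder <- make_temperature_ladder("gaussian_quantile", 240, 340, 12,
                                  center = 283, width = 25)
sim <- simulate_two_state_remd(two_state_params(
  tm = 283, delta_e = 50, sigma = 3, ladder = ladder,
  n_steps = 1500, exchange_every = 10, seed = 1))
curve <- cv_curve(twham(sim$trace), seq(240, 340, by = 0.5))
print(curve)
#> cv_curve: 201 grid points (240.0-340.0 K), Tm = 282.5 K, peak Cv = 3.634 kcal/mol/K
```

The classifier read back exactly the topology the generator laid down
(17 adjacent pairs = 7 + 6 + 4; 76.4% of residues in inter-strand
hydrogen bonds), the population ratio 24.1/7.4 converts to 0.70 kcal/mol
at 300 K, and the specific-heat peak lands at 282.5 K, half a grid step
from the 283 K design value.

A thin shell front-end with the same functionality is installed at
`system.file("cli", "betatopo", package = "betatopo")`, with subcommands
`classify | table | cv | demux | synth`.

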