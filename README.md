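# markord

Marker ordering for genetic linkage maps by simulated annealing and rapid
chain delineation.

## The problem

After markers have been assigned to linkage groups, a genetic map still
requires the *order* of the markers within each group. With `k` markers
there are `k!/2` distinct orders (an order and its reversal are the same
map), so ordering is an open traveling-salesman problem over the pairwise
map-distance matrix `D`: find the permutation `(σ1, …, σk)` minimizing the
sum of adjacent recombination fractions,

    SARF(σ) = Σ_{i=1}^{k-1} D[σ_i, σ_{i+1}].

markord is for geneticists and methodologists who want to order markers
with either of two classic two-point orderers — and, importantly, to compare
them head to head on simulated populations with known truth:

* `anneal()` — simulated annealing: a Metropolis chain over orders that
  always accepts non-worsening candidates (ties included) and accepts
  worsening ones with probability `exp(-Δ/c_n)` under a cooling schedule
  `c_n` starting at `A = 2`.
* `rcd()` — rapid chain delineation: a deterministic greedy that seeds a
  chain with the closest marker pair (smallest estimated recombination
  fraction), grows it by appending the nearest unmapped marker at either
  terminal, then polishes with 2- and 3-marker window inversions ("ripple").

Supporting machinery: an F2 co-dominant population simulator over a
user-specified genome (`simulate_f2()`), two-point EM estimation of
recombination fractions with LOD scores (`est_rf_em()`, `recomb_matrix()`),
Haldane/Kosambi map functions (`cm_to_r()`, `r_to_cm()`), an exhaustive
brute-force oracle for small marker sets (`exhaustive_best_order()`), a
comparison harness (`run_comparison()`), genotype I/O (CSV and MAPMAKER raw)
and distance-matrix TSV I/O, plus a command-line wrapper
(`inst/scripts/markord`).

## Worked example

```r
library(markord)

genome <- demo_genome()   # the built-in 4 x 100 cM benchmark genome
genome
#> Genome specification: 4 linkage group(s), 89 markers
#>   LG1: 51 markers spanning 100.0 cM (m1 ... m51)
#>   LG2: 21 markers spanning 100.0 cM (m52 ... m72)
#>   LG3: 11 markers spanning 100.0 cM (m73 ... m83)
#>   LG4: 6 markers spanning 100.0 cM (m84 ... m89)

pop <- simulate_f2(genome, n = 200, seed = 42)  # 200 F2 individuals
D   <- recomb_matrix(pop, group = 3)            # pairwise EM estimates, LG3

fit_sa  <- order_markers(D, "sa", config = sa_config(seed = 1))
fit_rcd <- order_markers(D, "rcd")
summary(fit_sa)
#> Marker ordering by simulated annealing
#>   markers: 11
#>   SARF: 101.2693 cM
#>   evaluations: 100012 (accepted 1892, 1.9%)
#>   schedule: linear, A = 2, m = 9091, L = 11, neighborhood = reverse
#>   order: m73 m74 m75 m76 m77 m78 m79 m80 m81 m82 m83
print(fit_rcd)
#> Marker ordering (rcd): 11 markers, SARF = 101.2693 cM
#> Order: m73 m74 m75 m76 m77 m78 m79 m80 m81 m82 m83
```

Both orderers recover the generating order `m73 … m83` (the group was
simulated with 10 cM spacing, so its true map length is 100 cM; the
estimated SARF of 101.27 cM reflects sampling noise in the pairwise
estimates at n = 200). `coef(fit_sa)` returns the permutation and
`plot(fit_sa)` draws the annealing trajectory (current and best-so-far SARF
per iteration).

The head-to-head protocol — one simulated population, RCD once per group,
20 independently seeded annealing runs per group, ties counting as wins:

```r
cmp <- run_comparison(genome, n = 50, reps = 20, seed = 1)
print(cmp)
#> Orderer comparison: n = 50 individuals, 20 SA repetitions per group
#>   population_size group n_markers rcd_sarf sa_best_sarf sa_mean_sarf pct_win
#> 1              50   LG1        51    159.7        105.6        105.6     100
#> 2              50   LG2        21    105.7        105.7        105.7     100
#> 3              50   LG3        11    106.9        106.9        106.9     100
#> 4              50   LG4         6    106.1        106.1        106.1     100
```

On the sparser groups (LG2–LG4) the two methods find identical orders, so
every repetition ties. On the dense 51-marker group, 2 cM spacing is below
the resolution of recombination fractions estimated from 50 individuals:
here the greedy chain misplaces markers it cannot locally distinguish
(SARF 159.7 cM), while annealing reaches a much shorter order (105.6 cM) in
every repetition. `write_summary_tsv()` and `write_trajectory()` export the
table and per-iteration trajectories.

The same pipeline is scriptable from a shell:

```sh
inst/scripts/markord simulate --genome demo --n 200 --seed 42 --out pop.csv
inst/scripts/markord estimate --geno pop.csv --group 3 --out lg3.tsv
inst/scripts/markord order-sa --dist lg3.tsv --seed 1
inst/scripts/markord order-rcd --dist lg3.tsv
inst/scripts/markord compare --genome demo --sizes 50,100 --reps 20 --seed 1 --out out/
```

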