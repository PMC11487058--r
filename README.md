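# xolint — interference length for meiotic crossover data

Meiotic crossovers (COs) on the same chromosome are spaced more widely
than chance predicts — *crossover interference*.  Quantifying it reliably
is hard: the classical coefficient of coincidence (CoC) needs binning and
many double-COs, and the gamma shape parameter of adjacent CO distances
ignores chromosomes with fewer than two COs and is sensitive to random
CO-detection loss.  `xolint` implements the **interference length**
*L*<sub>int</sub>, a binning-free, sub-sampling-invariant statistic with
units of length, for geneticists and cytologists analysing per-chromosome
CO positions (Mb along the chromosome, or µm along the synaptonemal
complex).

## The statistic

For each chromosome dataset, let *N* be the CO count of a sample and
⟨*N*⟩ its mean over all samples (zero-CO samples included).  Observed
same-sample CO pairs number N̄<sub>obs</sub><sup>pair</sup> =
mean(*N*(*N*−1)/2) on average, against
N̄<sub>noInt</sub><sup>pair</sup> = ⟨*N*⟩²/2 expected under a Poisson
null in which COs are placed independently, sampled from the pooled
observed positions (so non-uniform CO landscapes are absorbed).  With

- φ = N̄<sub>obs</sub><sup>pair</sup> / N̄<sub>noInt</sub><sup>pair</sup>,
- *d*<sub>obs</sub> — mean distance over all observed same-sample CO
  pairs (every pair weighted equally),
- *d*<sub>noInt</sub> — mean distance over all pairs of pooled CO
  positions,

missing pairs are assigned the maximal observable distance, the
chromosome length *L*, giving

*L*<sub>int</sub> = φ (*d*<sub>obs</sub> − *d*<sub>noInt</sub>) + (1 − φ)(*L* − *d*<sub>noInt</sub>).

*L*<sub>int</sub> = 0 without interference; a single uniformly placed
obligate CO gives 2/3 *L*; identically placed single COs give exactly
*L*; *N* regularly spaced COs give *L*[1/*N* − 1/(3*N*²)].  The
normalized interference length
*L*<sub>int</sub><sup>norm</sup> = *L*<sub>int</sub>⟨*N*⟩/*L* is a
dimensionless measure of placement regularity.  Companion measures
(CoC curve with its 0.5-crossing distance *d*<sub>CoC</sub>, gamma shape
ν of adjacent distances), bootstrap SEMs, permutation and
parametric-bootstrap significance tests, space conversion (Mb ↔ µm) and
scenario simulators are included.

## Worked example

```r
library(xolint)

ds <- simulate_crossovers("renewal", n_samples = 2000, mean_count = 2,
                          shape = 5, length_L = 30.4,
                          chromosome_id = "chr1", seed = 42)
fit <- interference_length(ds, sem_replicates = 200, seed = 1)
summary(fit)
#> Interference length estimate
#>   chromosome: chr1  (dna_mb, L = 30.4)
#>   samples: 2000,  mean CO count <N> = 2.018
#>   L_int      = 9.635   (L_int / L = 0.3169)
#>   L_int^norm = 0.6396
#>   bootstrap SEM = 0.1113
#>
#> Pair bookkeeping:
#> <pair_statistics>  (2000 samples, L = 30.4)
#>          <N>   N_obs^pair N_noInt^pair   N_mis^pair          phi        d_obs
#>       2.0180       1.3190       2.0360       0.7172       0.6478      14.1700
#>      d_noInt        d_mis        d_int
#>      10.2500      30.4000      19.8900
```

The simulated chromosome (gamma renewal, shape 5 — strong interference)
loses ~0.72 CO pairs per sample relative to the Poisson null (φ = 0.65),
and observed pairs sit 3.9 Mb further apart than pooled random pairs;
together that yields *L*<sub>int</sub> = 9.6 ± 0.1 Mb, i.e. interference
pushes the average CO pair apart by about a third of the chromosome.
*L*<sub>int</sub><sup>norm</sup> ≈ 0.64 indicates near-regular placement.
The classical measures agree qualitatively:

```r
coc_curve(ds, bin_count = 15)$d_coc   # 6.06 Mb interference distance
gamma_shape(ds)                       # shape nu = 5.66 on 2057 distances
test_vs_null(ds, replicates = 999, seed = 2)
#>   statistic = 9.635,  p = 0.001  (999 replicates)
```

A thin CLI wraps the same functions
(`xolint simulate|compute|test ...`; see `exec/xolint` and
`?xolint_cli`).

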