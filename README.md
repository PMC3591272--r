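# threeprime

Tools for measuring how 3′ end (terminator/3′UTR) sequences shape gene
expression in yeast reporter libraries — strains that differ only in the
3′ end region cloned downstream of a fluorescent reporter, so that any
expression difference is attributable to that sequence alone.

The package covers the five analysis layers such a library needs:

1. **Plate-reader quantification** — background subtraction, point-outlier
   masking, automatic growth-phase segmentation, and the single expression
   value per induction curve:
   `P = ΔF(exponential phase) / ∫ OD dt`, the average rate of protein
   production per cell per second. A clone-concordance filter keeps only
   strains whose independent clones agree within 15%.
2. **Polyadenylation-site mapping from 3′RACE** — UMI/poly(T) trimming,
   a built-in exact-seed + ungapped-extension mapper for the tiny cloned
   reference, cleavage-site calling at the poly(T)/genome junction
   (resolution: the first non-A at or upstream of the true site), and
   per-gene site profiles with a strict >1000-read depth filter. The main
   site (most reads, upstream tie-break) defines the 3′UTR end.
3. **PolyA-anchored sequence features** — Pearson-correlation scans of
   windowed A/T (or G/C) content against expression over a grid of window
   sizes × positions anchored on the main polyadenylation site, with a
   permutation null for the grid peak; grouped positional G/C profiles;
   k-mer association; IUPAC motif scans for the 3′-processing efficiency
   (`TAYRTA`/`TATATA`) and positioning (`AAWAAA`) elements; whole-UTR
   features with a dynamic-programming base-pairing score.
4. **Nested-regression variance partitioning** — does adding 3′ end
   measurements to promoter measurements significantly improve prediction
   of endogenous mRNA levels? `F = (ΔRSS/Δdf) / (RSS_full/(n−df_full))`.
5. **Single-cell burst statistics** — scatter gating (median ± k·MAD),
   noise `η² = σ²/μ²` and noise strength `ν = σ²/μ`, and the gamma
   burst-model readouts: burst frequency `a = 1/η²`, burst size `b = ν`
   (protein levels ~ Gamma(a, b)), plus reference-strain plate correction
   using the `η² ∝ 1/μ` scaling.

Every input class has a synthetic generator with planted ground truth
(`generate_construct_library()`, `simulate_plate_timecourses()`,
`simulate_race_reads()`, `simulate_cell_population()`), so the entire
pipeline is validated by recovery tests: generate → analyze → compare to
the planted truth.

## Worked example

```r
library(threeprime)

# an 85-construct synthetic reporter library with a planted A/T effect
# 40 bp upstream of each main polyadenylation site
lib <- generate_construct_library(n = 85, seed = 1)
expr <- sapply(lib$constructs, function(x) x$expression)
round(max(expr) / min(expr), 2)
#> [1] 13.48

# where in the 3' end does composition explain expression?
grid <- feature_expression_scan(lib$constructs)
grid
#> <ScanGrid> at_content vs expression, anchored on cleavage_site:
#>   10 x 51 cells; peak r = 0.999 at size 30, offset -40
attr(scan_permutation_null(grid, n_perm = 200, seed = 2), "q95")
#> [1] 0.409

# map 3'RACE reads back to the construct that generated them
reads <- simulate_race_reads(lib$constructs[[1]], n_reads = 5000, seed = 2)
res <- run_race_pipeline(reads, lib$constructs, depth_threshold = 1000)
res$profiles[[1]]
#> <CleavageProfile> SYN001: 5000 reads over 2 site(s), main 113

# burst statistics from a gated single-cell population
pop <- simulate_cell_population(a = 10, b = 100, n_cells = 1e5,
                                spore_frac = 0.05, seed = 3)
population_noise_stats(pop)[c("burst_frequency", "burst_size")]
#>   burst_frequency burst_size      (spore cells bias the raw estimate)
#> 1        6.61       144.4
population_noise_stats(gate_cells(pop))[c("burst_frequency", "burst_size")]
#>   burst_frequency burst_size
#> 1       10.01       100.1
```

The fold range (13.5×) is the library's expression span; the scan peak at
window size 30 bp centered 40 bp upstream of the polyadenylation site is
exactly the planted effect window, and its correlation (0.999) far exceeds
the permutation-null 95th percentile (0.41). The cleavage profile's main
site is the planted one, and gating the spore subpopulation out restores
the true burst parameters (10, 100) from the contaminated raw estimates.

A thin command-line front end over the same functions is installed at
`inst/cli/threeprime.R` with subcommands `simulate`, `plate`, `polya`,
`scan`, `noise` and `regress`.

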