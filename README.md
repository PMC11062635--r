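# evokit

Analysis toolkit for serial-transfer experimental evolution of
genome-reduced bacteria.

When a large fraction of a bacterial genome is deleted, growth fitness
drops; evolving the reduced strain for ~1000 generations can recover it.
Quantifying that recovery, and asking what changed, needs four bespoke
computations that general-purpose packages do not provide in one place:

1. **Growth fitness from OD600 curves.** Interval rates
   `r_i = ln(C_{i+1}/C_i)/(t_{i+1}-t_i)` between consecutive plate-reader
   readings; the growth rate is the best window of three consecutive rates
   (largest mean subject to a coefficient-of-variation filter), the carrying
   capacity a robust top-3 mean. Generations across daily transfers follow
   `G = log2(Nt/N0)` and `mu = ln(Nt/N0)/dt`.
2. **Locational bias of fixed mutations.** Distances from mutations to the
   nearest genome-reduction scar on the circular chromosome, compared with
   1000 sets of uniformly placed mutations via two-sided Welch's t-tests;
   the decision statistic is the mean replicate p-value, `mu_p`
   (`mu_p > 0.05` = no bias).
3. **Chromosomal periodicity of the transcriptome.** Log-FPKM expression,
   globally mean-matched, binned at 1 kb, smoothed with a circular 100-kb
   moving average; periodogram peak wavelength T, Fisher's g exact
   significance, and a least-squares fit of `a·sin(2π(x+b)/T) + c` with T
   fixed at the peak.
4. **Binomial enrichment** of gene sets against category/regulon
   annotations (labels with >15 members), Bonferroni-corrected.

A synthetic-data module generates every input with the statistical
structure these analyses assume (circular reduced genome with scar
junctions, logistic growth, sinusoidal chromosomal expression signal), so
the whole pipeline builds and tests offline.

## Worked example

```r
library(evokit)

# a 3.67-Mb circular reduced genome: 3290 genes, 30 scar junctions
layout <- gen_genome_layout(sim_config(seed = 1))

# transcriptome carrying a six-period chromosomal wave at SNR 1
prof <- gen_expression_profile(layout, period_count = 6, amplitude = 0.2,
                               noise_sd = 0.2, seed = 2)
periodicity_pipeline(prof)
#> periodicity_fit 'S1': T = 611667 bp (6 cycles/genome), a = 0.1940,
#>   b = 610542 bp, c = 1.0002
#>   Fisher's g = 0.3542 on binned bins, p = 0
```

The planted six-cycle signal is recovered: the peak wavelength 611,667 bp is
L/6, the fitted amplitude 0.194 is the planted 0.2 times the moving-average
attenuation (~0.96), and Fisher's g rejects the white-noise null outright.

```r
# 65 mutations placed uniformly (the null): no locational bias expected
muts <- gen_mutations(layout, 65, model = "null", seed = 3)
randomization_test(muts, layout, n_replicates = 1000, seed = 4)
#> randomization_result: 1000 replicates, mu_p = 0.6064 (95% CI 0.5911-0.6217)
#>   no locational bias

# growth estimate from a noisy logistic curve (true r = 0.45, K = 0.9)
cv <- gen_growth_curve(r_true = 0.45, K = 0.9, od0 = 0.01,
                       noise_sd = 0.003, seed = 5)
estimate_growth(cv)
#> growth_estimate: r = 0.3633 /h (window 14-16), K = 0.9062 OD600
```

`mu_p = 0.61 > 0.05` correctly reads "no locational bias" for uniformly
placed mutations. The capacity estimate (0.906 vs true 0.9) is accurate;
the rate (0.363 vs true 0.45) illustrates the known downward bias of the
windowed rule on noisy plate-reader data — the CV filter rejects early
noisy windows, and later windows sit in the decelerating phase. The methods
vignette (`vignettes/evokit-methods.Rmd`) quantifies this and its
consequences.

```r
# per-lineage mutation summary (here: simulated records, totals row shown)
tail(summarize_mutations(muts), 2)
#>    lineage all intergenic genic_indel genic_snp  N S
#> 9       L9   7          0           0         6  5 1
#> 10     Sum  65          5          15        41 35 6

# essential-gene ratio test: 11/49 mutated vs 286/3290 genome-wide
essentiality_ratio_test(11, 49, 286, 3290)[c("ratio_mut", "ratio_all", "p")]
#> $ratio_mut  22.44898   $ratio_all  8.693009   $p  0.0005740592
```

## End-to-end replay and CLI

```r
run_pipeline(pipeline_config(outdir = "demo", seed = 1))
```

runs simulate → growth → generations → mutbias → periodicity → enrich and
writes TSV/JSON outputs plus a manifest of md5 hashes (same config, same
bytes). The same stages are exposed on the shell:

```sh
exec/evokit replay --seed 1 --outdir demo
exec/evokit growth --od demo/plate.csv --out rates.tsv
exec/evokit mutbias --genome demo/layout --mutations demo/mutations.tsv \
    --reps 1000 --seed 42 --out randomization.json
```

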