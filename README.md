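# tatakit

Quantitative analysis of TATA-binding protein (TBP) binding to
core-promoter DNA, for researchers studying how promoter SNPs shift gene
expression. The package covers the full path from sequence to verdict to
wet-lab cross-check:

* **Affinity prediction** — a calibrated three-component model (TATA
  weight-matrix recognition, minor-groove geometry, A/T sliding-tract
  content) scores promoter windows on the −ln K_D scale (K_D in mol/L)
  and returns the maximal-affinity window in a region with an uncertainty
  δ:

  −ln K_D = b₀ + w_pwm·S_pwm + w_groove·S_groove + w_slide·S_slide

* **Allele comparison** — Z = (β_minor − β_anc)/√(δ²_anc + δ²_minor),
  two-sided normal p, and a verdict: predicted gene-product **excess**
  (minor allele binds TBP more tightly), **deficiency**, or
  **insignificant**.

* **Association kinetics** — simulation and global fitting of
  pseudo-first-order EMSA time courses,
  signal(t) = A·L/(L + k_d/k_a)·(1 − e^−(k_aL+k_d)t),
  across probe concentrations with shared (k_a, k_d, A), plus derived
  constants K*_D = k_d/k_a, t_1/2 = ln2/k_d, −ΔG = −RT·ln K*_D.

* **Correlation statistics** — Pearson r, Kendall τ-b and Goodman–Kruskal
  γ with exact-permutation significance at small n, for confronting
  predicted and measured affinities.

Six 26-bp probe sequences for leptin (*LEP*) and glucagon (*GCG*)
promoter alleles and their measured rate constants ship as fixtures
(`probeKinetics()`).

## Worked example

```r
library(tatakit)

# 1. Score the LEP promoter region [-70, -20]
lep <- lepPromoterExample()          # synthetic promoter carrying the assayed probe
promoterAffinity(lep)
#> AffinityEstimate: -ln KD = 16.684 +/- 0.077 (KD ~ 5.68e-08 M)
#>   best window: start -46, strand +; 102 windows scanned

# 2. Compare the four assayed variant alleles against wild type
report <- scanVariants(list(lep, gcgPromoterExample()), exampleVariants())
report[, c("variant_label", "z", "p_value", "verdict", "fold_change")]
#>   variant_label       z  p_value       verdict fold_change
#> 1      LEP_-38a  0.2319 8.17e-01 insignificant       1.094
#> 2      LEP_-30t  0.0963 9.23e-01 insignificant       1.015
#> 3      LEP_-35g -7.0178 2.25e-12    deficiency       0.226
#> 4      GCG_-41g -0.3668 7.14e-01 insignificant       0.458

# 3. Fit simulated association kinetics at 10/20/40/60 nM probe
sim <- simulateExperiment(ka = 2.3e3, kd = 1.8e-4, seed = 42)
fitKinetics(sim)
#> KineticsFit (global, shared ka/kd/amplitude)
#>   ka = 2.34e+03 +/- 2.1e+02 1/(M s);  kd = 0.000162 +/- 1.4e-05 1/s
#>   K*D = 6.92e-08 M (69.2 nM);  t1/2 = 71.5 min;  -dG = 9.77 kcal/mol at 298.15 K
```

Reading the output: the best LEP window sits at −46 (the TATA-box-bearing
probe region), with K_D around 57 nM. The TATA-core disruption −35g is
called a deficiency — its predicted K_D fold-change of 0.23 means roughly
4-fold weaker binding — while the flanking variants move affinity in the
measured direction (fold-change above 1 for −38a/−30t, below 1 for −41g)
but by less than the six-point calibration's significance threshold, so
they are reported insignificant. The kinetics fit recovers the simulation
truth (k_a = 2.3×10³ M⁻¹s⁻¹, k_d = 1.8×10⁻⁴ s⁻¹) within its standard
errors.

A thin command-line front end is installed with the package:

```sh
tatakit=$(Rscript -e 'cat(system.file("exec", "tatakit", package = "tatakit"))')
Rscript $tatakit scan \
  --fasta  $(Rscript -e 'cat(system.file("extdata", "example_promoters.fa", package = "tatakit"))') \
  --variants $(Rscript -e 'cat(system.file("extdata", "example_variants.tsv", package = "tatakit"))') \
  --out report.tsv
Rscript $tatakit kinetics simulate --ka 2300 --kd 0.00018 --seed 42 --out sim.csv
Rscript $tatakit kinetics fit --timecourses sim.csv --out fit.json
```

See the vignette (`vignettes/tbp-affinity-and-kinetics.Rmd`) for the
model's assumptions, calibration provenance, numerical conventions, and
known limitations.

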