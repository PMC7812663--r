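# grmforge

Additive and dominance genomic relationship matrices for GBLUP when
genotype frequencies are **not** in Hardy-Weinberg equilibrium.

Crossbred populations — F1 pigs or poultry from divergent parental lines —
carry a genome-wide excess of heterozygotes, and the classical
relationship-matrix constructions quietly assume HWE: the usual dominance
centering leaves a per-marker mean of `pAa − 2pq`, biasing the dominance
relationship matrix and, through it, variance-component estimates. This
package is for quantitative geneticists who need additive (**G**) and
dominance (**D**) matrices, and additive/dominance variance partitions,
that remain correct under arbitrary genotype frequencies.

## What it implements

With per-marker genotype frequencies `(pAA, pAa, paa)`, each marker gets an
additive and a dominance *scale* — per-genotype centering coefficients,
like ANOVA contrasts — collected into n × m matrices `Ha`, `Hd`, and

    G = Ha Ha' / SC_a        D = Hd Hd' / SC_d

Six parameterizations of the scales and denominators are provided:

* **HW** — VanRaden additive `(2−2p, 1−2p, −2p)` and Su/Vitezica dominance
  `(−2pq, 1−2pq, −2pq)` (correct only under HWE);
* **NO-HW** — biological scales centered with observed genotype
  frequencies;
* **NOIA** — the natural and orthogonal interactions scales, which make
  additive and dominance effects uncorrelated at any frequencies, scaled by
  the realized trace `tr(HH')/n`;
* **GSP-A / GSP-D / GSP-N** — Gram-Schmidt orthogonalizations starting
  from the additive vector (algebraically identical to NOIA, expected-trace
  scaling), from the dominance vector, and the orthonormalized variant in
  which every marker contributes equally.

Around the core: a per-marker orthogonality diagnostic (the angle between
additive and dominance scale vectors, `cos θ = n(−pAa)(pAA−paa) /
(‖u‖‖v‖)`, 90° ⇔ orthogonal), the Levene-Haldane exact HWE test,
Kullback-Leibler divergence between relationship matrices, REML estimation
of `(σ²_a, σ²_d, σ²_e)` with `h²` and `d²`, and a simulator of crossbred
panels with controllable heterozygote excess. A `grmforge` command-line
script (in `inst/cli/`) exposes everything as subcommands
(`simulate`, `hwe`, `scales`, `angles`, `build`, `kl`, `reml`, `report`).

## Worked example

```r
library(grmforge)

# a crossbred-like panel: 300 individuals, 2000 markers
g  <- simulate_genotypes(n = 300, m = 2000, mode = "f1", seed = 42)
f  <- compute_frequencies(g)
heterozygote_excess(f)$mean_excess     # 0.152: strong heterozygote excess
hw <- hwe_test(f)
sum(hw$p_value < 0.05)                 # 929 of 2000 markers off HWE

# NOIA relationship matrices
sm <- build_scale_matrices(g, "noia")
G  <- build_grm(sm, "additive")
D  <- build_grm(sm, "dominance")
G
#> relationship_matrix [NOIA, additive]: 300 x 300
#>  avg diagonal 1.000, avg off-diagonal -0.003, eigenvalues [0.000, 1.982]

# phenotypes with known variance components, then REML recovery
ph  <- simulate_phenotypes(g, sigma2_a = 2, sigma2_d = 1, sigma2_e = 1,
                           seed = 43)
reml_fit(ph$pheno, G, D)
#> REML variance components (n = 300 )
#>   sigma2_a = 2.0756  sigma2_d = 0.8664  sigma2_e = 0.7821
#>   h2 = 0.5573  d2 = 0.2326  logLik = -616.835  converged: TRUE
```

The average diagonal of 1.000 is the trace-scaling identity; the average
off-diagonal is `−1/(n−1)` because every column of `Ha` sums to zero. The
REML estimates recover the simulated `(2, 1, 1)` within sampling error,
with `h² ≈ 0.56` of a phenotypic variance of about 3.7.

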