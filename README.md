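# sumraa: region-based association tests from either data level

Region-based association analysis (RAA) jointly tests all SNPs in a gene
or genomic region against a continuous trait. The classical formulation
needs individual-level data: an n×m dosage matrix G and an n-vector of
phenotypes y. Increasingly, however, only SNP-level GWAS summary
statistics are available — per-SNP Z scores, optionally beta standard
errors — together with a SNP-by-SNP correlation (LD) matrix U.

`sumraa` implements six method families — multiple linear regression
(MLR), principal-component regression (PCA), functional linear models
(FLM, Fourier or B-spline bases), burden, SKAT and SKAT-O — in **both**
formulations, connected by the linear compression of the standardized
model

    z = Ḡᵀ ȳ / √n,      U = Ḡᵀ Ḡ / n,

where ȳ and Ḡ are the standardized phenotype and genotypes. The
compression preserves the rank of the predictor matrix, so nothing the
region test uses is lost: with X = S̃⁻¹WC (S̃ = diag of beta standard
errors, W = SNP weights, C = the method operator),

- fixed effects (MLR/PCA/FLM):  R² = (1/n) zᵀX(XᵀUX)⁻¹Xᵀz, tested by
  F = ((n−1−r)/r)·R²/(1−R²) with r = rank(UX);
- random effects (burden/SKAT/SKAT-O):  Q = zᵀXXᵀz, with null
  distribution Σλᵢχ²₁, λ = eigen(XᵀUX).

When z and U are computed from the same genotypes, statistic,
eigenvalues and p-value are **identical** to the individual-level test —
this is a machine-checked property of the package, not an
approximation. Weighted-χ² tail probabilities use a characteristic-
function inversion (Davies-type) with a moment-matched fallback. A lasso
estimator of variant effects from (z, U), a generic combiner for
dependent Z scores of any level (SNPs, regions, traits), a
genotype/phenotype simulator with tunable LD, and a small CLI
(`exec/sumraa`) round out the package.

## Worked example

```r
library(sumraa)

## simulate a region: 300 individuals, 12 mostly-low-MAF SNPs in LD,
## one causal SNP (sample MAF 0.19) with effect 0.8
cfg <- simulation_config(300, 12, maf_range = c(0.02, 0.3),
                         ld_decay_rho = 0.6,
                         causal_indices = 5, effect_sizes = 0.8, seed = 42)
panel <- simulate_genotypes(cfg)
pheno <- simulate_phenotype(panel, cfg)

## individual-level SKAT with beta(1,25) MAF weights
w <- weight_spec("beta_density", beta_a = 1, beta_b = 25)
res_ind <- raa_test(panel, pheno, method = "skat", weights = w)
res_ind
#> region-based association test: skat
#>   Q = 15.574  [12 eigenvalues]
#>   p = 0.0258693

## compress to summary statistics (z, LD, beta SEs) and re-test
sumdat <- compress_to_summary(standardize_data(panel, pheno))
res_sum <- raa_test(sumdat, method = "skat", weights = w)
res_sum$p_value
#> [1] 0.02586926          # identical to the individual-level p

## SKAT-O over its rho grid, min-p calibrated by Monte Carlo
skat_o_summary(sumdat, weights = compute_weights(sumdat$mafs, w), seed = 1)
#> region-based association test: skat_o
#>   minP = 0.005235
#>   p = 0.00719928
```

The Q statistic measures phenotype variance attributable to the weighted
region kernel; its p-value comes from the eigenvalue-weighted χ²₁
mixture. The SKAT-O `minP` is the smallest per-ρ p-value over the grid
interpolating SKAT (ρ = 0) and burden (ρ = 1); the reported `p` corrects
it for the search over ρ.

The same pipeline is scriptable from a shell:

```sh
exec/sumraa simulate --n 300 --m 12 --ld-rho 0.6 --causal 5 --effects 0.4 \
    --seed 42 --out-prefix region
exec/sumraa compress --genotypes region.dosage.tsv --phenotype region.pheno.tsv \
    --out-prefix region
exec/sumraa test --mode summary --method skat --weights beta:1,25 \
    --summary region.summary.tsv --ld region.ld.tsv --n 300
```

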