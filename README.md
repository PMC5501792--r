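# csiscn

Cancer subtype identification with spectral clustering using the Nyström
approximation.

## The problem

Unsupervised discovery of molecular subtypes from gene-expression profiles
is a standard step in translational cancer studies: patients are clustered
from a genes × samples expression matrix, and a candidate subtyping is
considered meaningful when the groups differ in censored survival outcome
(distant relapse-free, relapse-free or overall survival).  Plain spectral
clustering handles the non-convex geometry of expression data well but
needs the eigendecomposition of an n × n similarity matrix; the Nyström
method replaces that with the eigendecomposition of a small landmark block,
making the approach practical while — on these data — often improving the
survival separation of the resulting subtypes.

`csiscn` implements the full workflow for R: microarray-style
preprocessing, the Nyström spectral embedding, k-means with a
relative-objective stopping rule, Kaplan–Meier / log-rank / hazard-ratio
evaluation, and the survival-driven selection of the kernel bandwidth.

## The method

Samples x_1, …, x_n (columns of the z-scored expression matrix) are
compared with the Gaussian kernel

    s_ij = exp(−‖x_i − x_j‖² / 2σ²),  s_ii = 0.

Only two blocks of S are evaluated over a random landmark set of size ℓ
(half the cohort by default): the ℓ × ℓ landmark block A and the
ℓ × (n−ℓ) cross block B.  The remainder of S exists only through its
Nyström approximation BᵀA⁻¹B.  Approximate degrees
D̃ = diag([A1 + B1; Bᵀ1 + BᵀA⁻¹B1]) normalize the blocks
(Ā = D̃_ℓ^{-1/2} A D̃_ℓ^{-1/2}, B̄ likewise), and one-shot
orthogonalization through

    R = Ā + Ā^{-1/2} B̄ B̄ᵀ Ā^{-1/2} = U_R Λ_R U_Rᵀ

yields the n × k row-normalized embedding
Ũ from Ṽ = [Ā; B̄ᵀ] Ā^{-1/2} (U_R)_{:,1:k} Λ_{1:k}^{-1/2}.  k-means (Lloyd
iterations, stop when the relative objective change drops below 0.001)
clusters the rows of Ũ into k subtypes.

For training, σ is swept over the candidate set {20, 30, 40, 50}: each
candidate is run 10 times (fresh landmarks and initialization per run),
each run is scored by the log-rank p-value of its subtypes against the
cohort's survival, and the σ with the smallest aggregated p-value is
selected, then applied to a validation cohort with ℓ = half that cohort.

## Worked example

```r
library(csiscn)

# a synthetic cohort: 150 patients, 500 genes, two subtypes whose hazards
# differ fourfold, 40% censoring
train <- generate_cohort(n = 150, p = 500, k = 2, g = 100, delta = 2.5,
                         lambdas = c(0.03, 0.12), censor_rate = 0.4,
                         seed = 11)
test  <- generate_cohort(n = 100, p = 500, k = 2, g = 100, delta = 2.5,
                         lambdas = c(0.03, 0.12), censor_rate = 0.4,
                         seed = 12)

sel <- select_sigma(train$expression, train$clinical, k = 2,
                    candidates = c(5, 10, 15, 20), base_seed = 13)
sel
#> sigma_selection: k = 2, 10 run(s) per candidate (median p)
#>  sigma summary_p
#>      5 1.000e+00
#>     10 4.445e-08
#>     15 7.335e-13
#>     20 7.335e-13
#> chosen sigma: 15

res <- apply_to_cohort(test$expression, test$clinical,
                       sigma = sel$chosen_sigma, k = 2, seed = 14)
res$logrank
#> log-rank: chi-square = 26.22 on 1 df, p = 3.052e-07
#>  group observed expected
#>      1       41     22.6
#>      2       19     37.4
res$hazard_ratio
#> HR (1 vs 2) = 3.570, 95% CI [2.118, 6.018]
label_agreement(res$assignment$labels, test$true_labels)
#> [1] 1
```

σ = 5 is too sharp for this cohort's distance scale — its runs fail with
degenerate Nyström degrees and score p = 1 — while 15 and 20 resolve the
subtypes identically and tie; the tie goes to the smaller σ.  On the
held-out cohort the two discovered subtypes reproduce the true ones
(ARI = 1) and split survival sharply (log-rank p ≈ 3e-7; subtype 1's
hazard is about 3.6 times subtype 2's).

The same workflow is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/csiscn.R", package = "csiscn"))')
Rscript $CLI simulate --seed 1 --out sim/
Rscript $CLI select --expr sim/cohort_n120_k3_expression.tsv \
    --clinical sim/cohort_n120_k3_clinical.tsv --k 3 \
    --sigmas 20,30,40,50 --runs 10 --seed 1 --out sel/
Rscript $CLI apply --expr sim/cohort_n120_k3_expression.tsv \
    --clinical sim/cohort_n120_k3_clinical.tsv --sigma 20 --k 3 \
    --seed 1 --out apply/
```

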