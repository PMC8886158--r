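# lncpairs

Rank-based lncRNA-pair prognostic signatures for tumor cohorts, built from
tumor-infiltrating T-lymphocyte-specific long non-coding RNAs.

## The problem and the method

Immune infiltration — T lymphocytes in particular — shapes outcomes in
solid tumors such as head-and-neck squamous cell carcinoma, and lncRNAs
are central regulators inside those infiltrating cells. `lncpairs`
implements a complete analysis that turns this biology into a prognostic
model without ever comparing expression values across samples or
platforms:

1. **T-cell-specific lncRNAs.** An immune-cell panel (T cells vs other
   immune cell types) is quantile-normalized and screened by moderated-t
   differential expression (|logFC| > 1, FDR < 0.05, both strict).
2. **Pair features.** The specific lncRNAs found in the tumor cohort are
   exhaustively paired; for each pair {A, B} and sample *s* the feature is

   ```
   z_{AB}(s) = 1  if  expr(A, s) > expr(B, s),   else 0
   ```

   so every feature is a within-sample comparison, invariant to monotone
   per-sample transforms. Pairs whose indicator is 1 in 20–80% of samples
   (inclusive) survive the prevalence filter.
3. **Staged Cox model.** Univariate Cox screen (Wald p < 0.01, Efron
   ties) → Lasso-Cox with 10-fold cross-validated λ → unpenalized
   multivariate refit. The risk score is `Σ_k z_k(s) β_k`.
4. **Cutoff and risk groups.** A Kaplan–Meier-based time-dependent ROC at
   a 3-year horizon (2/3/4-year AUCs reported); the cutoff maximizes
   sensitivity + specificity (Youden), and scores strictly above it define
   the high-risk group.
5. **Downstream biology.** Log-rank and clinical Cox analyses; a
   lncRNA–miRNA–mRNA ceRNA network whose hub mRNAs are consensus miRNA
   targets that are also tumor-differential (|logFC| > 2, FDR < 0.05,
   rank-sum); hypergeometric enrichment; weighted-KS GSEA between risk
   groups; infiltration, gene-correlate and drug-sensitivity (IC50)
   comparisons.

A fully seeded synthetic-data module generates every input with planted,
recoverable signal (planted specific lncRNAs, pair hazards under a Weibull
proportional-hazards model, interaction triads with rule-breaking decoys,
shifted gene sets, correlated infiltration, shifted IC50s), so the whole
pipeline is testable end-to-end with no downloads.

## Worked example

```r
library(lncpairs)

sim <- sim_config(seed = 42, n_lncrnas = 60, n_specific = 15,
                  specific_logfc = 3, noise_sd = 0.6, n_samples_per_type = 12,
                  n_patients = 150, n_normals = 25, n_mrnas = 150,
                  n_de_mrnas = 15, n_planted_triads = 3, n_mirnas = 12,
                  immune_program_size = 15,
                  planted_pairs = data.frame(lnc_a = c("LNC0001", "LNC0003"),
                                             lnc_b = c("LNC0002", "LNC0004"),
                                             beta = c(1.0, -1.0),
                                             prevalence = 0.5))
cfg <- pipeline_config(seed = 42, sim = sim, gsea_nperm = 200)
run <- run_full_pipeline(cfg)
str(run$summary$funnel)
#> List of 11
#>  $ n_panel_lncrnas    : int 60
#>  $ n_specific_lncrnas : int 15
#>  $ n_cohort_lncrnas   : int 15
#>  $ n_pairs_built      : int 105
#>  $ n_pairs_prevalence : int 41
#>  $ n_screen_candidates: int 2
#>  $ n_lasso_selected   : int 2
#>  $ n_signature_pairs  : int 2
#>  $ n_de_mrnas         : int 15
#>  $ n_predicted_mrnas  : int 4
#>  $ n_hub_mrnas        : int 2
run$artifacts$signature$model
#> signature_model: 2 pairs, cutoff -1.036637
#>   LNC0003|LNC0004                beta = -1.0366
#>   LNC0003|LNC0043                beta = -0.5937
unlist(run$summary$model$auc)
#>     t730    t1095    t1460
#> 0.713299 0.723495 0.752703
run$summary$model$logrank_p
#> [1] 7.769823e-08
```

Reading the output: 15 of 60 panel lncRNAs pass the specific-lncRNA
screen; their 105 pairs reduce to 41 after the prevalence filter and to 2
after the Cox/Lasso stages. One of the two planted pairs
(`LNC0003|LNC0004`, true β = −1) is recovered with β̂ = −1.04; the other
planted pair is lost at the panel stage (its first gene just misses the
|logFC| > 1 cut after quantile normalization) and is partly compensated by
a correlated proxy pair. The 3-year AUC of 0.72 and a log-rank p of
8e-08 between risk groups show the signature stratifies survival; the two
hub mRNAs are planted triad members recovered through the
target-consensus × differential-expression intersection.

Each stage is equally usable on its own (`quantile_normalize()`,
`differential_expression()`, `build_pair_matrix()`,
`univariate_cox_screen()`, `time_dependent_roc()`, `gsea()`, ... — see the
function reference), with TSV/GCT/GMT/JSON/SIF readers and writers for
every interface format. A thin command-line wrapper lives at
`inst/scripts/pairlnc.R` (`Rscript pairlnc.R run --seed 1 --out out/`).

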