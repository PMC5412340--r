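# toxsev — severity-sensitive toxicity marker discovery

`toxsev` identifies gene markers that track the **severity** of drug-induced
toxicity symptoms, not merely their occurrence. It is aimed at
toxicogenomics analysts working with cohorts that pair expression profiles
of drug-dosed animals with ordinal pathology grades per symptom (0 = absent,
1 = minimal, 2 = slight, 3 = moderate, 4 = severe, plus a flag for
spontaneous findings).

## The method

Markers are selected by **sparse linear discriminant analysis** with the
severity grades as a multi-group class label, via penalized optimal scoring.
With Y the n×K class-indicator matrix and D = YᵀY/n the diagonal
class-frequency matrix, each discriminant direction solves, alternately,

    β ← argmin ‖Yθ − Xβ‖² + λ₂‖β‖²   s.t. at most m active coefficients
    θ ← normalize((I − QQᵀD) D⁻¹YᵀXβ),  θᵀDθ = 1,

where Q holds the previously fitted score vectors and the trivial constant
score. The cardinality-constrained elastic-net step is a LARS path on the
ridge-augmented design stopped when the active set reaches m, so the number
of weighted genes — the number of markers — is a direct input parameter.
Genes are ranked by their maximum absolute loading across directions. In the
dense limit (m ≥ p, λ₂ → 0) the directions span the classical LDA
discriminant subspace exactly.

Selected markers are validated by a **balanced ensemble of regression
forests** (all cases + an equal-size random control subset per member,
default 100 members × 10 trees, averaged predictions — countering the
control-heavy imbalance of such cohorts), evaluated under **drug-unit
10-fold cross-validation** (folds partition drugs, with in-fold marker
selection): Spearman correlation (SCC) between actual and predicted
severity, and threshold-swept ROC/AUC for occurrence. Marker sets can be
screened for gene-set over-representation with an upper-tail hypergeometric
test against a GMT annotation (raw p < 0.01 screening, EASE variant and BH
adjustment available). One-way ANOVA (severity groups) and Welch/Student
t-test (occurrence groups) selection are included as comparators.

A synthetic cohort generator (`simulateCohort()`) provides the validation
world: multi-drug design, dose-monotone ordinal severities, control-heavy
imbalance, correlated gene blocks, planted severity-monotone markers
including a correlated weak pair, and a matching annotation with a planted
enriched term.

## Worked example

```r
library(toxsev)

cfg <- cohortConfig(nDrugs = 20, samplesPerDrug = 12, nGenes = 500,
                    nMarkers = 12, effectSize = 0.8, fracToxicDrugs = 0.5,
                    seed = 42)
sim <- simulateCohort(cfg)
ds  <- buildDataset(sim$expression, sim$samples, "necrosis")
ds
#> SymptomDataset for symptom: necrosis
#>   500 genes x 237 samples; 51 cases / 186 controls; 20 drugs
#>   severity grades: 0:186 1:28 2:9 3:11 4:3

mk <- selectMarkers(ds, "slda", m = 16)
mk
#> MarkerSet (slda, symptom 'necrosis'): 16 of m=16 genes
#>   top: g00015, g00338, g00112, g00372, g00106
mean(markerGenes(mk) %in% sim$truth@markerGenes)
#> [1] 0.6875

ev <- crossValidate(ds, "slda", m = 16, k = 5, nModels = 10, seed = 1)
ev
#> EvaluationResult (slda, m=16, symptom 'necrosis')
#>   pooled SCC: 0.658 | mean per-fold SCC: 0.665 | AUC: 0.954

ann <- simulateAnnotation(sim$truth, nTerms = 30, termSize = 20, seed = 42)
head(enrichMarkers(mk, ann$annotation, universe = rownames(sim$expression)), 3)
#>   term_id                        term_name k  K  n   N      p_value significant
#> 1 SET0001 planted severity-response module 8 20 16 500 1.484145e-08        TRUE
#> 2 SET0005                  random gene set 2 20 16 500 1.303998e-01       FALSE
#> 3 SET0006                  random gene set 2 20 16 500 1.303998e-01       FALSE
```

Reading the output: the dataset holds the samples retained for the symptom
(spontaneous positive findings removed) with their grades; the marker set
lists genes by decreasing discriminant loading (11 of the 16 are true
planted markers at this small cohort size — precision 0.69); the evaluation
reports the
pooled out-of-fold SCC between the actual grade (0–4) and the ensemble's
continuous severity prediction — 0.66 here means predicted severity rises
strongly with true severity on held-out drugs — and the AUC for calling
occurrence by thresholding the prediction. The enrichment table flags the
planted term (`SET0001`) at a hypergeometric p far below the 0.01 screening
level; `k` of the `n` markers lie in the term of size `K` within the
universe of `N` genes.

A full pipeline run (simulate → select → evaluate → enrich, with a manifest
and per-stage seeds) is available through `runPipeline()` /
`readRunConfig()`, or from the shell via
`Rscript inst/scripts/run_pipeline.R --config run.cfg`.

## Acceptance script

`scripts/acceptance.R` re-runs the end-to-end synthetic analysis from
scratch against the installed package — cohort simulation at the reference
size (40 drugs × 20 samples, 2,000 genes, 24 planted markers), sparse-LDA
selection at m = 32, balanced-ensemble drug-unit 10-fold cross-validation,
and the enrichment screen — logging the measured summary statistics, and
writes the JSON target report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
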