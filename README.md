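# tansurv

Five-year survival prediction for endometrial-cancer registry cohorts:
a tree-augmented naive Bayes (TAN) classifier versus the Cox
proportional-hazards model, implemented from first principles with a
calibrated synthetic-cohort generator, a Fussell–Vesely-style variable
importance ranking, and the full evaluation battery.

## Who this is for

Biostatisticians and epidemiologists who want a transparent, fully tested
implementation of the "Bayesian network versus Cox" comparison for coded
registry data: 13 categorical clinicopathological predictors (age group,
tumor site, grade, histological type, FIGO stage, radiotherapy/surgery
sequence, radiotherapy, chemotherapy, lymph-node resection, lymph-node
metastasis, tumor size, depth of invasion, distant metastasis), follow-up
months 1–60 and vital status. Patient-level registry extracts of this kind
are typically not redistributable, so the package ships a generator that
emulates such a cohort — published marginal level frequencies, a small
dependency DAG (stage → lymph-node metastasis → distant metastasis,
grade → histological type), and Weibull proportional-hazards survival
calibrated to a ~31% five-year mortality — and every simulation-based test
runs against it.

## The models

**TAN.** Every attribute has the class (five-year status) as a parent plus at
most one attribute parent, the attribute edges forming a spanning tree.
Structure is learned by maximizing class-conditional mutual information
I(Xi; Xj | C) over a maximum-weight spanning tree (Kruskal, deterministic
tie-breaks), oriented away from a root; conditional probability tables use
Laplace smoothing. Posterior inference is exact:
P(Alive | x) ∝ P(Alive) Πv P(xv | parents).

**Cox.** h(t, X) = h0(t) exp(βᵀX) on dummy-coded levels, fitted by
Newton–Raphson on the partial likelihood (Efron ties by default, Breslow by
flag), with Wald statistics, univariate likelihood-ratio screens, the Breslow
baseline, and five-year survival prediction S(60 | X) = S0(60)^exp(βᵀX).

**Importance.** For each variable V with states j, the fitted network yields
q_j = P(Dead | V = j) by inference; with q\* = min_j q_j,

    MMFV(V) = mean_j ( (q_j − q*) / q_j )

— the mean multi-state Fussell–Vesely importance, in [0, 1), zero exactly
under class-independence. Variables are ranked by MMFV and the network's
variable count is chosen by stratified cross-validated forward selection
along the ranking.

**Evaluation.** Confusion matrix (positive class Alive), accuracy, ROC/AUC
(trapezoidal = Mann–Whitney with half-ties), Youden threshold derived on
training predictions and frozen, and Harrell's C-index over comparable pairs.

## Worked example

```r
library(tansurv)

params <- default_generator_params()     # SEER-like study conditions
sim    <- generate_cohort(params, n = 618, seed = 1)
sim$cohort
#> Cohort: 618 records, 13 variables
#>   5-year status: 179 dead, 439 alive, 0 indeterminate

report <- run_pipeline(pipeline_config(n = 618, seed = 1))
report
#> Model-comparison report
#>   cohort n=618 (train 464 / test 154); TAN uses 11 of 13 variables
#>   internal test metrics:
#>  model   c_index accuracy_pct       auc
#>    CPH 0.6606576     62.98701 0.6951923
#>     BN 0.6739994     59.09091 0.7100000
```

The cohort draw reproduces the study design: 618 records split 464/154
(75%, round-half-up), with a death fraction near the calibrated 0.311. The
pipeline screens all variables univariately, fits the multivariate Cox model,
ranks variables by MMFV, selects the variable count by 5-fold
cross-validation (here 11 of 13), fits the TAN, freezes Youden thresholds on
training predictions, and evaluates both models on the held-out 154 records.
On this seed the network edges recover the generating dependencies
(stage → lymph-node metastasis → distant metastasis, grade → histological
type); the AUC and C-index land near the values the generator's signal
supports (population Bayes accuracy is 76.3% against a 68.9% majority rate),
and the Youden thresholds trade accuracy for balanced sensitivity and
specificity, as they are designed to.

Individual pieces are available directly:

```r
split <- split_cohort(sim$cohort, 0.75, seed = 1)
tan   <- tan_bayes(split$train)                  # TAN on all 13 variables
cox   <- cox_ph(split$train)                     # 25-column Cox fit
head(summary(cox), 5)
#>  variable level   coef exp.coef se.coef      z        p
#>       age   <50  0.000    1.000      NA     NA       NA
#>       age 50-59 -0.266    0.767  0.3615 -0.735 0.462000
#>       age 60-69  0.276    1.318  0.3472  0.796 0.426000
#>       age 70-79  0.685    1.985  0.3604  1.901 0.057200
#>       age   >80  1.478    4.385  0.3957  3.735 0.000188
```

`render_report(report, "out/")` writes the result tables (univariate screen,
Cox coefficients, importance table, confusion matrices, metric summaries) as
CSV plus ROC point files and a run log, byte-identical on re-render.

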