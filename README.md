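# tractstim

Tract-guided programming of subthalamic nucleus (STN) deep brain
stimulation (DBS) in R.

Modern directional DBS leads have eight contacts, which makes the clinical
monopolar review — sweeping each contact from 1 to 8 mA to find the effect
threshold (full rigidity reduction) and the side-effect threshold
(persistent capsular contractions) — slow and complex. Two pathways carry
most of the signal for this search: the **hyperdirect pathway (HDP)**,
cortico-subthalamic fibers ending in the dorsolateral STN, mediates the
therapeutic effect, while the **corticospinal tract (CST)** in the adjacent
internal capsule mediates capsular side effects. `tractstim` is for
researchers in DBS connectomics who want to turn weighted tractography of
these pathways into stimulation-parameter suggestions and to score those
suggestions against the clinical review.

## What it computes

For a volume of tissue activated (VTA) around a contact, the **activation**
of a pathway is the weighted streamline fraction

$$ a(\mathrm{VTA}) \;=\; \frac{\sum_{s\,\cap\,\mathrm{VTA} \neq \emptyset} w_s}{\sum_s w_s}, $$

with SIFT2-style streamline weights $w_s$. The default VTA kernel is the
thresholded homogeneous point-source field,
$r(I) = \sqrt{I / (4\pi\sigma E_t)}$ (σ = 0.33 S/m, E_t = 0.2 V/mm), with
directional segments clipped to an angular sector.

Two **stimulation models** — L2-penalized logistic regressions
$p(\text{effect}) = \operatorname{logit}^{-1}(\beta_0 + \beta_1 a)$ — are
trained per pathway on monopolar-review thresholds (HDP activation vs
effect, CST activation vs side effect) under nested leave-one-subject-out
cross-validation, with the inverse regularization chosen by subject-grouped
inner CV on balanced accuracy. The models then suggest, per lead, effect
and side-effect thresholds for every configuration and the best/worst
level and contact under three strategies (lowest effect threshold; the
same after excluding configurations whose side effects precede full
effect by more than 1 mA; widest therapeutic window). Suggestions are
scored with balanced accuracy
$\tfrac12(\mathrm{TPR}+\mathrm{TNR})$, right-tailed permutation tests and
threshold-error medians.

A synthetic-cohort generator (STN ellipsoid, HDP funnel, CST tube,
jittered directional leads, simulated reviews from known ground-truth
models) makes the whole pipeline runnable and testable without patient
data. Real inputs are supported through standard formats: MRtrix `.tck`
tracks with plain-text weights, NIfTI-1 VTA masks, and CSV dialects for
lead poses and review records.

## Worked example

```r
library(tractstim)

params <- synthetic_params(n_subjects = 6, seed = 1)
cohort <- generate_cohort(params, keep_bundles = FALSE)
cohort
#> <synthetic_cohort> 6 subjects, 12 leads, 120 review rows (seed 1)

cv_hdp <- loso_cv(build_training_samples(cohort$reviews, cohort$activations, "HDP"))
cv_cst <- loso_cv(build_training_samples(cohort$reviews, cohort$activations, "CST"))
cv_hdp
#> <loso_cv> 6 folds; mean accuracy 0.722 (95% CI 0.657-0.787); pooled boundary 0.1229
cv_cst
#> <loso_cv> 6 folds; mean accuracy 0.702 (95% CI 0.603-0.800); pooled boundary 0.0304

sugg <- suggest_cohort(cohort$activations, cv_hdp, cv_cst, "initial")
head(sugg$labels[c("lead_id", "best_level", "best_contact", "worst_level", "worst_contact")], 4)
#>   lead_id best_level best_contact worst_level worst_contact
#> 1   S01_R         L2           C3          L4            C7
#> 2   S01_L         L1           C2          L4            C6
#> 3   S02_R         L1           C1        none          none
#> 4   S02_L         L1           C1        none          none

evaluate_suggestions(list(initial = sugg$labels), cohort$reviews,
                     n_perm = 10000, seed = 1)
#>   strategy which granularity sensitivity specificity balanced_accuracy p_value n_leads
#> 1  initial  best       level       0.909       0.970             0.939  0.0001      11
#> 2  initial  best     contact       0.727       0.961             0.844  0.0001      11
#> 3  initial worst       level       0.778       0.963             0.870  0.0001       9
#> 4  initial worst     contact       0.364       0.922             0.643  0.0221      11
```

The pooled boundary is the cross-validated activation fraction at 50%
outcome probability: here about 12% of the HDP weight for therapeutic
effect and 3% of the CST weight for capsular side effects (this small
6-subject cohort was generated from ground-truth boundaries of 10% and
1%). The labels are per-lead programming suggestions — `worst_level =
"none"` means the CST model found no configuration reaching side effects
within the sweep — and the evaluation table reports how often suggestions
match the clinically best/worst levels and contacts, with permutation
p-values for the null that suggestions are random.

`run_pipeline(run_config("out_dir"))` runs all stages (including the
combined and window strategies and threshold-error reports) and writes
stamped CSV/JSON artifacts; `inst/scripts/run_pipeline.R` wraps it for the
shell, and `read_run_config()` reads YAML configurations.

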