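# bcibench

A benchmarking framework for classifier comparison in sensory-motor
EEG brain–computer interfaces (BCIs).

## The problem

Motor imagery modulates the power of the EEG's sensorimotor rhythms: imagined
movement desynchronizes the alpha (8–12 Hz) and lower beta (16–24 Hz) bands
over the contralateral motor cortex (event-related desynchronization, ERD).
A sensory-motor BCI turns these band-power changes into control signals,
either in cued trials (*synchronous* operation, scored by accuracy) or in
free-running streams containing No-Control periods (*self-paced* operation,
scored window-wise by ROC/AUC). Results in this field are notoriously hard
to compare across papers: different preprocessing, features, model-selection
protocols and evaluation conventions confound any comparison of the
classifiers themselves.

`bcibench` is a reusable, tested pipeline that holds all of those stages
fixed so that classifiers can be compared on equal footing, and that ships a
rank-based statistics layer for drawing conclusions across subjects. A
synthetic EEG generator with controllable class-dependent ERD makes every
stage testable without access to recorded data.

## What is inside

**Filtering.** A filter bank of fifth-order Butterworth band-pass blocks
(designed analytically in zero-pole-gain form and run as cascaded
second-order sections), applied forward–backward so filtering is zero-phase.

**Spatial filtering.** Common Spatial Patterns (CSP): given trace-normalized
class covariances Σ⁺ and Σ⁻, find filters *w* maximizing

    w Σ⁺ wᵀ / (w (Σ⁺ + Σ⁻) wᵀ)

solved by whitening Σ⁺ + Σ⁻ and eigendecomposing the whitened Σ⁺. Filters
are kept as symmetric top/bottom eigenvalue pairs; multiclass problems use a
one-against-others scheme.

**Features.** Band power (time-averaged squared amplitude plus its
logarithm) of the alpha and beta bands per surrogate channel, or Morlet
wavelet power at 26 center frequencies tiling 4–30 Hz per channel.

**Classifiers.** A uniform train / predict-probability contract over seven
standard learners: LDA, QDA, elastic-net logistic regression, RBF-kernel
SVM, random forest, AdaBoost and a single-hidden-layer MLP, each with its
tuned-hyperparameter grid as first-class data.

**Model selection.** Joint grid search over BCI parameters (time segment,
CSP pair count, window length/overlap) and classifier hyperparameters by
5×5 repeated stratified cross-validation, with all supervised stages refit
inside each training fold; then a final refit and one evaluation on held-out
data.

**Statistics.** Mean-tie per-subject ranks, the Friedman chi-square test,
Holm step-down post-hoc comparisons against the best-ranked control
classifier (z = (R_j − R_ctrl) / √(k(k+1)/6N)), and the partition into
recommended / not-recommended classifiers. The per-subject test performances
of a published seven-classifier comparison (21 synchronous and 8 self-paced
subjects, band-power and Morlet features) ship as CSV fixtures.

## Worked example

```r
library(bcibench)

## rank-based comparison on the bundled self-paced AUC table
perf <- read_performance_csv(benchmark_table_path("selfpaced", "bp"))
compare_classifiers(perf, alpha = 0.1)
```

```
Average ranks (1 = best):
  LR(1.81)  MLP(2.75)  LDA(3.06)  QDA(4.18)  RF(4.87)  BST(5.50)  SVM(5.81)
Friedman chi2 = 23.25, df = 6, p = 0.000717
Holm post-hoc vs control 'LR' (alpha = 0.1)
 classifier         z p_value  threshold rejected
        SVM 3.7032804  0.0002 0.01666667     TRUE
        BST 3.4139616  0.0006 0.02000000     TRUE
         RF 2.8353241  0.0045 0.02500000     TRUE
        QDA 2.1988227  0.0278 0.03333333     TRUE
        LDA 1.1572751  0.2471 0.05000000    FALSE
        MLP 0.8679563  0.3854 0.10000000    FALSE
Recommended: LDA, LR, MLP
Not recommended: BST, QDA, RF, SVM
```

Logistic regression has the best average rank (1.81) and is the control;
the step-down procedure rejects SVM, AdaBoost, random forest and QDA as
significantly worse, while LDA and the MLP cannot be distinguished from the
control — so the recommended set for this paradigm is {LR, MLP, LDA}.

```r
## end-to-end pipeline on synthetic two-class motor-imagery EEG
train <- extract_epochs(generate_synchronous(
  synth_config(trials_per_class = 50, seed = 1)), 0, 4)
test <- extract_epochs(generate_synchronous(
  synth_config(trials_per_class = 25, seed = 2)), 0, 4)
pipe <- bci_pipeline("bp", n_csp_pairs = 2,
                     classifier = classifier_spec("LR"))
fitted <- fit_pipeline(pipe, train)
pred <- predict_pipeline(fitted, test)
accuracy(predicted_labels(pred), test$labels)
#> [1] 1
```

With the generator's default contralateral alpha ERD (power factor 0.3) the
filter-bank → CSP → band-power → LR pipeline separates the two imagery
classes perfectly on held-out trials.

A command-line interface wrapping the same functions is installed at
`inst/cli/bcibench` (subcommands `simulate`, `run`, `compare`, `report`).

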