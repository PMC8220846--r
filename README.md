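# gaitpress

Recognition of common paediatric pathological gaits — **toe-in**,
**toe-out** and **flat foot** — against normal gait, from nothing but an
8×8 plantar-pressure sensor array sampled at 50 Hz. The package is aimed
at researchers in wearable gait analysis who want a fully reproducible,
end-to-end reference pipeline: it models the piezoresistive readout
electronics of such an insole (including row/column crosstalk and its
elimination), generates labelled synthetic walking and standing
recordings with the statistical structure the method assumes, and
implements the recognition chain with its evaluation protocol.

## The method

**Features.** Walking recordings are cut into Hann-tapered sliding
windows of *L* = 512 frames (≈10 gait cycles at 50 Hz). Per sensor the
DFT magnitudes

&nbsp;&nbsp;&nbsp;&nbsp;*S(k)* = |Σₙ *t(n)* · e^(−j2πkn/L)|,&nbsp;&nbsp;k = 0…L−1

are summed over five half-open bands (0,2], (2,4], (4,6], (6,8],
(8,10] Hz — the DC bin is excluded — and the 30 masked sensors'
band sums are concatenated into a 150-element vector, normalised to unit
L2 norm so that bodyweight cancels. Standing recordings keep only the
per-sensor DC (time-mean) load: a unit-norm 30-element vector.

**Reduction.** Either PCA keeping the minimal components that capture
90 % of variance, or a multiclass linear discriminant maximising the
scatter ratio J(**W**) = tr(**W**ᵀS_B**W**) / tr(**W**ᵀS_W**W**) via the
generalized eigenproblem S_B**w** = λS_W**w** (output dimension 3 for
four classes).

**Classification.** A soft-margin SVM (linear or RBF kernel,
*C* = 1, γ = 1/(n_features × variance)) trained by SMO-style pairwise
coordinate ascent on the dual with one-vs-one voting, or a 3-layer
feed-forward network with 10 hidden units trained by backpropagation.

**Evaluation.** Stratified tenfold cross-validation reporting per-class
recall, macro-averaged precision, averaged confusion matrices and
prediction time per reference batch; leave-one-subject-out (LOSO)
rounds for generalization to unseen individuals; Welch/pooled t-tests
between fold accuracies of competing variants.

**Sensor model.** A loaded cell follows R_x = K_{p−r}/P; the amplifier
and 10-bit ADC give D = 2^m (K_{p−r} + P·R_f)/K_{p−r} · V_ref/V_adc_ref.
`simulate_scan()` reproduces row/column sneak-path crosstalk by exact
nodal analysis of the resistive network, and its elimination drive
scheme (ground unselected rows, pull unselected columns to V_ref), under
which every reading equals the ideal single-cell output bit for bit.

## Worked example

```r
library(gaitpress)

ds    <- make_dataset(n_per_class = 50,
                      cfg = sim_config(section = "dynamic"), seed = 42)
feats <- extract_features(ds)
fit   <- gait_recognizer(feats, reducer = list(kind = "lda"),
                         classifier = list(kind = "svmlin"))
cv    <- evaluate_pipeline(feats, k = 10, seed = 42, batch_size = 100)
print(cv)
round(cv$confusion, 1)
```

```
Stratified 10-fold cross-validation: LDA + svmlin
  Recall (normal, toe_in, toe_out, flat): 1.00/1.00/1.00/1.00
  Average precision (%): 100.00   Accuracy (%): 100.00 +- 0.00
  Time cost (ms, per 100-sample batch): 1.40
         predicted
actual    normal toe_in toe_out flat
  normal       5      0       0    0
  toe_in       0      5       0    0
  toe_out      0      0       5    0
  flat         0      0       0    5
```

The dataset is 50 dynamic windows per class over a 17-subject synthetic
cohort; the recall vector lists the four classes in canonical order and
the confusion matrix holds average per-fold counts (5 test samples per
class per fold, all on the diagonal here — the generated classes are
well separated when train and test share subjects). `loso_evaluate()`
tells the harder story: held-out subjects with unseen cadences and
individual load patterns drop accuracy drastically, which is the
motivation for the within/between-subject comparison in the vignette.

A command-line wrapper over the same functions lives at
`inst/cli/gaitpress`:

```sh
gaitpress simulate --config cfg.json --seed 3 --section dynamic --out recs/
gaitpress extract  --config cfg.json --in recs/ --out features.csv
gaitpress train    --config cfg.json --in features.csv --out model.json
gaitpress predict  --model model.json --in features.csv --out labels.csv
gaitpress evaluate --config cfg.json --in features.csv --out results
```

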