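# ecgid — 12-lead ECG biometric identification via mutual-information lead graphs

`ecgid` identifies people from their 12-lead electrocardiogram. It is aimed
at researchers in biosignal processing and biometric security who want a
fully reproducible, desk-scale implementation of the MI-graph GCN approach:
the twelve leads become nodes of a weighted graph whose edges are the
mutual information between lead time series, and a graph convolutional
network classifies recordings by subject.

## Method at a glance

For leads $X, Y$ with empirical histogram probabilities:

$$I(X;Y) = \sum_{x,y} \Pr[x,y]\,\log_2\frac{\Pr[x,y]}{\Pr[x]\Pr[y]}
         = H[X] + H[Y] - H[X,Y]$$

The 12×12 MI matrix $M$ is thresholded, $A_{ij} = M_{ij}\,[M_{ij} > \tau]$,
and symmetrically normalized, $\hat A = D^{-1/2} A D^{-1/2}$. The
classifier stacks graph convolutions

$$H^{(l+1)} = \mathrm{ReLU}\!\left(\hat A\, H^{(l)} W^{(l)}\right)$$

over a per-node input projection of each lead's denoised, z-scored 10 s
window (12×2,570 at 257 Hz), followed by a dense head and a softmax over
subjects. Denoising: zero-phase Butterworth band-pass 0.5–40 Hz, LOESS
baseline removal, 1-D non-local means. Evaluation: 70/15/15 hold-out,
k-fold/LOO cross-validation, accuracy / macro-P/R/F1 / ROC-AUC / EER, and
paired t-tests between depth variants (GCN-MI-5/10/15).

A built-in simulator generates labelled 12-lead cohorts (per-subject
Gaussian-sum PQRST morphology, powerline / baseline / muscle / motion
noise) so everything is testable without external data; WFDB-format
records (e.g. the INCART 12-lead arrhythmia database at 257 Hz) are read
with the bundled reader.

## Worked example

```r
library(ecgid)
cohort   <- generate_cohort(n_subjects = 6, recordings_per_subject = 4,
                            seed = 11)
features <- lapply(cohort, preprocess_recording)

g <- lead_graph(features[[1]])         # normalized 12x12 MI graph
round(g$values[1:3, 1:3], 3)
#>         I    II   III
#> I   0.158 0.080 0.072
#> II  0.080 0.139 0.074
#> III 0.072 0.074 0.178

cfg    <- gcn_config(n_graph_layers = 5, epochs = 100, seed = 11)
report <- evaluate_holdout(features, cfg, seed = 11)
report
#> <evaluation_report fold=1 n=3 acc=1.0000 P=0.3333 R=0.3333 F1=0.3333
#>  AUC=1.0000 EER=0.0000>
```

All three held-out recordings are assigned to the right subject
(`acc=1`), and genuine/impostor scores separate perfectly (`AUC=1`,
`EER=0`); macro precision and recall of 1/3 reflect the documented
convention that the subjects absent from a 3-record test set contribute
zero — not a classification error. The diagonal of the normalized graph
holds the degree-scaled lead self-entropies; off-diagonal entries are
normalized inter-lead MI.

Comparing depth variants on per-fold accuracies reproduces the published
statistics:

```r
paired_t_test(c(94.16, 98.46, 97.14, 100), c(90.00, 96.92, 98.57, 100))
#> <paired t-test: t=0.8926 df=3 p=0.4378 -> retain H0 at alpha=0.05>
```

## Command line

```sh
Rscript -e 'ecgid::ecgid_cli()' simulate   --out raw --subjects 20 --per-subject 6 --seed 42
Rscript -e 'ecgid::ecgid_cli()' preprocess --manifest raw/manifest.csv --out feat
Rscript -e 'ecgid::ecgid_cli()' graph      --features feat/s01_r01_features.csv --out mi.csv
Rscript -e 'ecgid::ecgid_cli()' evaluate   --manifest feat --mode kfold --k 10 --out cv.json
```

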