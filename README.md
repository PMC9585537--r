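# cardiodx

Binary heart-disease risk classification from tabular clinical records, for
researchers working with UCI-dialect cardiology tables (13 mixed-scale
clinical attributes such as age, chest-pain type, resting blood pressure,
serum cholesterol, ST depression, plus an integer 0–4 disease-severity
target). The package chains four stages into one reproducible pipeline:

1. **K-means denoising** — Lloyd's algorithm over standardized records;
   rows whose Euclidean distance to their assigned centroid exceeds a
   quantile threshold (default 0.95) are dropped as sensor noise.
2. **Discriminant feature extraction** — linear or kernel discriminant
   analysis. With between-class scatter `S_b = Σᵢ Cᵢ(μᵢ−μ)(μᵢ−μ)ᵀ/N`, a
   whitening basis `U = V_b Λ_b^{−1/2}` (so `Uᵀ S_b U = I`) projects records
   into `M = min(C−1, rank S_b)` dimensions; in the kernel case the same
   projection is computed from Gram-matrix blocks only. Class covariances
   are regularized by a pair `(α, γ) ∈ [0,1]²`:
   `Σᵢ(α,γ) = (1−γ)Σᵢ(α) + (γ/M)·tr[Σᵢ(α)]·I`,
   `Σᵢ(α) = [(1−α)Sᵢ + αS] / [(1−α)Cᵢ + αN]`,
   and classification uses the Mahalanobis/Bayes rule
   `dᵢ(q) = (q−ȳᵢ)ᵀ Σᵢ⁻¹(α,γ) (q−ȳᵢ) + ln|Σᵢ(α,γ)| − 2 ln πᵢ`.
3. **Patient-similarity graph** — kNN graph with Gaussian edge weights over
   the extracted features; combinatorial Laplacian `L = D − W`.
4. **Spectral graph convolutional network** — layers
   `H^{[l+1]} = σ(Σ_k θ_k L^k H^{[l]} + b)` (degree-K polynomial Laplacian
   filters, computed by repeated sparse multiplication, never by
   eigendecomposition), trained transductively with cross-entropy on
   labelled nodes plus a normalized-min-cut auxiliary loss
   `L_cut = Σ_{i>j} [(Y⊘Γ)(1−Y)ᵀ]ᵢⱼ Aᵢⱼ + Σ_k (1ᵀY − n/g)²_k`
   on a soft cluster head. An optional graph-transformer attention layer
   with edge-feature modulation is provided as a standalone operation.

A synthetic-table generator (class-conditional Gaussians, injected
heavy-tailed outliers, random missingness) provides a controlled world for
testing every stage, and a metrics module computes confusion counts,
sensitivity, specificity, precision, F-score and Mann–Whitney ROC AUC at
epoch checkpoints.

## Worked example

```r
library(cardiodx)
report <- run_pipeline(list(seed = 42))
print(report)
```

```
cardiodx run 7970f30d seed 42
rows: input=282 train=198 test=84 removed_noise=10 train_kept=188
class prevalence: 0: 157 (55.67%), 1: 125 (44.33%)
 epoch  accuracy sensitivity specificity precision   f_score       auc
   100 0.6666667   0.5135135   0.7872340 0.6551724 0.5757576 0.6894767
   200 0.6666667   0.5405405   0.7659574 0.6451613 0.5882353 0.6877516
   300 0.6547619   0.5405405   0.7446809 0.6250000 0.5797101 0.6900518
   400 0.6547619   0.5405405   0.7446809 0.6250000 0.5797101 0.6906268
   500 0.6547619   0.5405405   0.7446809 0.6250000 0.5797101 0.6871765
```

With no data path configured the pipeline simulates its default world: 282
records (125 disease-present, 44.33%; 157 absent, 55.67%), 13 unit-variance
features with a one-standard-deviation class shift, 5% injected outliers.
That world is deliberately hard — classes overlap heavily — so mid-60s
accuracy against a 55.67% majority baseline is the expected outcome; the
row counts show 84/282 records held out and 10 training rows removed as
noise. On well-separated data (class means 4σ apart) the same pipeline
reaches ≥ 95% test accuracy at the 500-epoch checkpoint (this is asserted
by the acceptance suite). To run on a real UCI-format file:

```r
report <- run_pipeline(list(
  seed = 1,
  data = list(path = "processed.cleveland.data"),
  classifier = "gcn"        # or "lqda" for the Mahalanobis/Bayes rule
))
write_report(report, "out/")
```

## Command line

```sh
inst/cli/cardiodx run      --config cfg.yaml --out results/
inst/cli/cardiodx simulate --out table.csv --seed 3 --n-pos 125 --n-neg 157
inst/cli/cardiodx cluster  --data table.csv --quantile 0.95 --out removed.csv
```

(after installation the script lives at
`system.file("cli/cardiodx", package = "cardiodx")`). Config files are YAML
overriding `default_config()`.

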