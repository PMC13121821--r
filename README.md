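# irtstream

Real-time online estimation of item and ability parameters in 2PL and
multidimensional 2PL (M2PL) item response models.

## The problem

Item response theory (IRT) calibration is classically a batch job: the
Bock–Aitkin EM algorithm revisits every examinee in every cycle, so when
responses arrive continuously — online testing platforms, rolling
assessments — keeping item parameters and examinee scores current means
refitting from scratch, at a cost that grows with the archive.
`irtstream` instead maintains a **truncated stochastic Newton** recursion
that touches each examinee exactly once, at arrival, in constant memory:

* **TSNA** — per item $j$, one Newton-type step per arriving examinee $n$,

  $$\beta_{n,j} \;=\; \beta_{n-1,j} \;-\; \nu_n\, \bar H_{n-1,j}^{-1}\, \nabla f_n(\beta_{n-1,j}), \qquad \nu_n = c_\nu (n + n_0)^{-\gamma},$$

  where $f_n$ is the examinee's negative log marginal likelihood on a
  fixed Gauss–Hermite grid, and $\bar H_{n,j} = S_{n,j}/(n+1)$ averages
  the accumulated per-sample curvature
  $S_{n,j} = S_0 + \sum_{i\le n} \Phi_{ij}$, with each
  $\Phi$ a posterior-weighted cross-information whose Bernoulli term is
  floored at a decaying truncation level
  $\lambda_n = c_\lambda (n+1)^{-\alpha_\lambda}$ so $S$ stays positive
  definite along the whole stream;
* **TASNA** — the same recursion plus weighted iterate averaging
  $\bar\beta_{n} = (1-\tau_n)\bar\beta_{n-1} + \tau_n \beta_n$ with
  $\tau_n = \log(1+n)^w / \sum_{i \le n}\log(1+i)^w$, which smooths the
  trajectory and is the recommended estimator;
* **online EAP scoring** — each examinee's ability is the posterior mean
  of $\theta \sim N(0, I_Q)$ on the quadrature grid under the
  just-updated item parameters, available the moment the record arrives;
* **standard errors** — square roots of the diagonal of $S^{-1}$ at the
  final sample size;
* a fixed-quadrature **Bock–Aitkin EM** baseline, a synthetic-data
  generator with Béguin–Glas anchor constraints for M2PL, a bias/RMSE
  replication harness, and CSV/JSONL streaming IO with a small CLI.

## Worked example

Simulate a 2PL stream (abilities N(0,1), discriminations U(0.5, 2),
difficulties N(0,1)) and fit it online:

```r
library(irtstream)

sim <- generate_dataset(sim_config(N = 5000, J = 10), seed = 1)
fit <- fit_online(sim$responses, estimator_config("tasna"))
fit
#> Online TASNA fit: 5000 examinees streamed, J = 10 items, Q = 1
#> Averaged item-parameter estimates (slope-intercept form):
#>     item1   item2   item3   item4  item5   item6   item7  item8  item9  item10
#> a1 0.9159  1.1135  1.3799  2.1222 0.8616  1.9423  2.0972 1.6648 1.6336  0.5429
#> d  0.7493 -0.5578 -0.8987 -1.1658 0.2036 -2.8328 -0.7915 0.9701 3.2744 -0.6466
```

Rows are the discrimination `a` and intercept `d` of
$P(\text{correct}) = \sigma(a\theta + d)$; the classical difficulty is
$b = -d/a$ (reported by `write_parameter_table()`). Against the known
truth, the pooled item-parameter RMSE of this single run is 0.105 after
5,000 examinees. Standard errors from the inverse accumulated Hessian:

```r
round(fit$se[, 1:5], 4)
#>       item1  item2  item3  item4  item5
#> [1,] 0.0377 0.0406 0.0457 0.0634 0.0356
#> [2,] 0.0332 0.0331 0.0366 0.0442 0.0307
```

`fit$eap` holds the real-time ability score of every examinee as it was
scored at arrival; over the last 1,000 examinees of this stream (items
nearly converged) the scores correlate 0.85 with the true abilities —
the accuracy ceiling set by a 10-item test, not by the estimator.

The EM reference on the same data is one call, and the two agree:

```r
em <- em_fit(sim$responses, K = 11)
mean(abs(coef(fit) - vapply(em$params$items, function(it)
  c(it$loadings, it$intercept), numeric(2))))   # ~0.035
```

A replicated recovery study across estimators (paired seeds, bias/RMSE
per parameter class) is `run_replication_study()`; the command-line
surface (`inst/cli/irtstream`) exposes `simulate`, `fit`, `em`,
`benchmark`, and `score` for shell pipelines, e.g.

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "irtstream", package = "irtstream"))')
Rscript $CLI simulate --N 2000 --J 20 --seed 7 --out-dir data
Rscript $CLI fit --config cfg.yaml --input data/responses.jsonl --out-dir run
```

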