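# trnscreen

Screening for **core transcription factors** from two bulk transcriptomic
snapshots — an initial and a reference state — plus genome sequence, TF
motifs and chromatin-accessibility intervals. No predefined network
structure or edge weights are required: the TF regulatory network (TRN)
is built *de novo* and a single per-TF parameter, the dissociation
constant K\_d, is learned; factors whose fitted K\_d moves away from its
initial value are the core-TF candidates driving the transition (e.g. a
differentiation step or drug response).

## The model in brief

Per learning step, each TF concentration follows

```
x[m, n+1] = f(x[1,n], ..., x[M,n]) + g(x[m,n])
```

* **Occupancy** of a TF (concentration A, constant K_d) on its top
  binding sites (scores Sp, weights `w = 10^(-a (1 - Sp))`, at most 4
  non-overlapping sites per promoter):
  `r = Σ_p w_p A / (K_d + w_p A + w_q (K_d/K_i) R)`, where the last
  denominator term is the site's strongest competing repressor; promoters
  whose summed site scores exceed a threshold switch to a cooperative
  (Hill-type, super-enhancer) form with the same bounds.
* **Activation flux** `k_c · exp(-1/r)`, summed over promoter-bound TFs;
  repressor-only TFs and all gene-body-bound TFs are subtracted; negative
  totals clamp to 0.
* **Degradation** is Michaelis–Menten decay integrated exactly over one
  step via the Lambert-W closed form `g(x) = W(exp(x + log x - d))`.
* **Fitting**: gradient descent on log10-K_d (central finite differences,
  clipped, with Armijo backtracking) so that iterating the model from the
  initial state approaches the reference state under a
  reference-weighted squared error on `log1p` expression.

Outputs follow the field's conventions: binding-site CSVs, K_d
trajectories, `Act_list.csv` / `Rep_list.csv` derivative-factor edge
lists, GraphML digraphs, and a core-TF table.

## Worked example

Everything below runs on the package's self-contained synthetic fixture
(30 TFs, 60 genes, 1 kb promoters, known ground-truth network); no
downloads are needed. We weaken one TF's binding a hundred-fold when
generating the reference state, then ask the screen to find it.

```r
library(trnscreen)

fx  <- generateFixture(fixtureConfig(seed = 1))
ros <- roster(fx$model)
fx  <- perturbReference(fx, c(TF07 = 100), seed = 99)

fit <- fitKd(fx$model, fx$xInit[ros], fx$xRef[ros], fitConfig())
coreTFs(fit, tolerance = 0.5)
#>   tf_id kd_init kd_final log10_change
#> 1  TF07       1 8.681465     0.938593
```

TF07 — and only TF07 — is reported as a core TF: its fitted dissociation
constant rose from 1 to ≈ 8.7 (log10 change 0.94, i.e. strongly
*inhibited* binding), pointing at the planted hundred-fold perturbation
while every unperturbed constant stayed within the 0.5-decade tolerance
(20 descent steps rank the driver reliably; they do not recover the full
perturbation magnitude). A
condition-versus-control report and the digraph files come from the same
fit:

```r
ctrl <- fitKd(fx$model, fx$xInit[ros], fx$xInit[ros], fitConfig())
rep  <- kdRatioReport(fit, ctrl)
rep$mostInhibited
#> [1] "TF07"
digraphExport(actMatrix(fit), repMatrix(fit), dir = "network_out")
```

The same analysis runs from the shell via the thin CLI
(`inst/scripts/trnscreen`) with subcommands `fixture`, `regions`, `bind`,
`fit` (including `--fix TF07=100` clamping and the `--grid` parameter
sweep) and `report --control <dir>`.

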