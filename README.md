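# donorNet

Donor organ quality shapes long-term kidney transplant outcomes, but
molecular markers proposed for it are rarely validated. donorNet implements
a two-stage workflow for researchers in transplant nephrology and systems
biology:

1. **Donor organ status molecular model.** Gene feature sets from several
   evidence sources (literature-mined chronic allograft nephropathy genes
   plus transcriptomics signatures of twelve-month graft function) are
   merged into a catalog, projected onto a protein–protein interaction
   network, reduced to the subgraph of features with at least one
   interaction to another member, and clustered into densely
   interconnected "molecular processes" with the MCODE algorithm
   (vertex weight = *k* · density of the highest *k*-core of the closed
   neighborhood; expansion threshold `seedWeight · (1 − vwp)`; haircut to
   the 2-core). Cluster members are tested for GO-style term
   overrepresentation (hypergeometric or the conservative EASE variant,
   Benjamini–Hochberg FDR).
2. **Post-transplant eGFR prediction.** Twelve-month eGFR
   (MDRD: `175 · Scr^−1.154 · age^−0.203 · 0.742^female · 1.212^black`)
   is modeled by ordinary least squares on clinical covariates and log2
   marker expression. Model search minimizes the leave-one-out
   cross-validated RMSE, computed exactly through the PRESS identity
   `PRESS = Σ (eᵢ / (1 − hᵢᵢ))²`: exhaustive enumeration for the nine
   pre-transplant clinical parameters, simulated annealing over
   6–8-predictor subsets for the combined clinical + marker pool,
   followed by significance pruning and an extra-sum-of-squares F-test
   against the clinical-only model. Post-operative parameters (delayed
   graft function, rejection) are evaluated as add-ons.

A synthetic-data module generates every input with known ground truth —
planted dense network clusters, planted enriched annotation terms, and a
76-subject cohort whose clinical margins, marker correlation structure and
planted linear eGFR signal are calibrated in closed form (clinical-only
population R² 0.17, true-model R² 0.33). Expression preprocessing
(platform merge on shared probes, quantile normalization, median
probe-to-gene summarization, correlation-based outlier exclusion) is
exercised through a probe-level simulator with planted outlier samples.

## Worked example

```r
library(donorNet)

cs <- simulateCohort(seed = 1)     # cohort + markers + planted truth
fit <- fitModel(cs$cohort, c("donor_age", "donor_gender", cs$truth$causal),
                markers = cs$markers)
fit
#> ModelFit: 7 predictor(s), n = 76
#>   adj R2 = 0.2690, LOOCV R2 = 0.1855, LOOCV RMSE = 18.4328, overall p = 0.000148
#>               estimate       se       t      p
#> (Intercept)  -111.1768 169.8580 -0.6545 0.5150
#> donor_age      -2.4839   1.3390 -1.8550 0.0679
#> donor_gender   16.2989   4.1858  3.8938 0.0002
#> CD2BP2         29.2220  18.8438  1.5508 0.1256
#> SF3B1          44.0476  31.0022  1.4208 0.1599
#> EGF            13.5060   6.7219  2.0093 0.0485
#> RALBP1        -34.0047  14.2779 -2.3816 0.0200
#> DDX19B        -18.8233  20.8035 -0.9048 0.3688
```

The fitted coefficients estimate the planted effects (donor age −2.69 per
decade, donor gender +13.95, marker betas as configured) within sampling
noise at n = 76; `adj R2` estimates the planted population R² of 0.33 for
this single replicate, and `LOOCV RMSE` is the selection objective. Adding
the five markers to the clinical base is tested by the nested F-test:

```r
anovaNested(fitModel(cs$cohort, c("donor_age", "donor_gender")), fit)
#> F = 2.36, p = 0.0488  (df 5, 68)
```

The network stage on a planted graph (three 8-node clusters at edge
probability 0.9 over a sparse background):

```r
sim <- simulatePlantedGraph(seed = 1)
ann <- simulateAnnotations(igraph::V(sim$graph)$name,
                           planted = setNames(sim$clusters,
                                              paste0("PL", 1:3)), seed = 1)
model <- buildMolecularModel(sim$graph, igraph::V(sim$graph)$name, ann)
model
#> MolecularModel (donor organ status)
#>   input features:     84
#>   connected features: 79
#>   clusters:           3
#>   cluster members:    23
#>   enriched terms:     3
```

All three planted clusters are recovered and their planted annotation
terms are the top enriched rows (q < 0.05). The same stages run behind one
entry point with file artifacts (`runPipeline()`), with every JSON output
stamped with the seed and a configuration hash so identical runs are
byte-identical.

## Acceptance script

`scripts/acceptance.R` exercises the installed package end to end: it
simulates the full synthetic input world for the given seed, builds the
molecular model, preprocesses the probe-level expression, runs the clinical
and combined model selection with the post-operative add-on analysis,
writes the consolidated report, and then writes the result JSON to the
path given by `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
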