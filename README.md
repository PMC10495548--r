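# figwasp

Host specificity of fig-pollinating wasps, estimated from sticky-trap
counts and COI barcodes.

Strangler figs (*Ficus*, subgenus *Urostigma*) are pollinated by
species-specific *Pegoscapus* wasps that must find a receptive tree of
their host species across a tropical forest. Given (i) trap counts at
receptive fig trees, vegetative fig trees and non-*Ficus* controls and
(ii) COI barcodes for a subsample of trapped individuals, this package
answers three questions: how strongly does tree class predict wasp
arrivals; how host-specific are the arriving wasps at each phase; and how
abundant is each wasp *species* at each class of tree.

The analysis chain is:

1. **Zero-inflated Poisson models** for pooled per-event counts
   `y ~ ZIP(lambda, p)` with `log lambda = x'beta + log(days) + b_species +
   c_date` and `logit p = w'gamma + u_species` — fixed tree-type effects,
   a log-exposure offset confined to the conditional part, and Gaussian
   random intercepts integrated by a Laplace approximation
   (`fit_zip_glm()`, `fit_zip_mixed()`), compared by AIC and summarized
   with Wald z-tests, likelihood-ratio tests and single-step
   Tukey-adjusted pairwise intervals.
2. **Barcode species assignment**: invertebrate-mitochondrial pseudogene
   screen, Tamura–Nei (TN93) distances with pairwise deletion, a strict
   nearest-reference `< 2%` rule, and a neighbor-joining audit tree
   (`check_coding()`, `tn93_distance()`, `assign_species()`,
   `neighbor_joining()`).
3. **A joint bootstrap**: 200 resampled stratum capture rates × 200
   resampled barcode compositions, multiplied and summed into four
   categories per wasp species (receptive/vegetative × usual/other host),
   with 95% percentile confidence intervals (`abundance_bootstrap()`).

A synthetic-data generator (`sim_config()`, `simulate_trapping()`,
`simulate_barcodes()`, `simulate_sequences()`) reproduces the statistical
structure of the field campaign — rates calibrated to the published
per-trap-day totals, specificity probabilities 284/316 (receptive) and
138/215 (vegetative), 503-bp COI fragments with >2% interspecific and
<2% intraspecific divergence — with full knowledge of the truth, so every
stage is testable end to end. The wasp–fig association registry
(`host_registry()`) ships as a plain CSV transcribing the published
association table, with a historical/current switch.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic campaign at the scale of the field study (13 fig species,
~760 trapping events, ~1300 barcoded individuals) and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R      # events + barcodes + COI FASTA
Rscript analysis/02_assign.R        # pseudogene screen, TN93, <2% rule
Rscript analysis/03_count_models.R  # tree-type model ladder + per-species
Rscript analysis/04_specificity.R   # binomial GLMs + LRTs
Rscript analysis/05_bootstrap.R     # joint bootstrap, Table-style grid
```

Selected output from one run (seed 20230911):

```
Captures per trap-day by tree type:
  tree_type count_pegoscapus exposure_days     per_day
  non_ficus                8           303  0.02640264
  receptive             9179           144 63.74305556
 vegetative              780          1209  0.64516129

1326 queries assigned; 0 pseudogene flags; 1 new sp.
Agreement with generator truth: 99.9%

Tukey-adjusted conditional contrasts (log scale):
               contrast estimate        se         z      lower    upper
 vegetative - non_ficus 1.426701 0.6832154  2.088215 -0.1099033 2.963305
  receptive - non_ficus 5.213132 0.6818110  7.646007  3.6796865 6.746578
 receptive - vegetative 3.786431 0.0462059 81.946922  3.6825107 3.890352
Qualitative pattern (receptive >> vegetative ~ non-Ficus): TRUE

Observed usual-host fractions: receptive 0.903, vegetative 0.624
Tree-type LRT: chi-square(1) = 144.49, p = 2.78e-33
Receptive - vegetative (logit scale): 1.72 [1.42, 2.02]

95% percentile intervals (captures/day attributable to each species):
                 P. syntheticus 01 P. syntheticus 02
receptive_usual  "24.92-56.63"     "10.89-84.93"
receptive_other  "4.139-22.58"     "2.76-19.53"
vegetative_usual "0.1888-0.8667"   "0.1508-0.538"
vegetative_other "0.2408-0.5684"   "0.05294-0.3163"
```

Reading the output: receptive fig trees capture roughly two orders of
magnitude more wasps per trap-day than vegetative trees, which in turn sit
close to the non-*Ficus* controls (overlapping adjusted intervals); wasps
trapped at receptive trees belong to the local host's usual pollinator
species far more often than those at vegetative trees (90% vs 62%, LRT
p < 0.001); and per species, estimated arrivals concentrate overwhelmingly
at receptive trees of the usual host, with the one query beyond 2%
divergence correctly reported as "new sp." rather than forced into a
reference species.

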