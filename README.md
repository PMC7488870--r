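# branchzones

Branching-zone analysis of apple shoots with constrained hidden semi-Markov
chains.

Apple shoots carry one axillary bud per node; in the season after the parent
shoot grows, each bud either stays latent (`0`), forms a short (`1`) or long
(`2`) vegetative shoot, or flowers as a bourse with a short (`3`) or long
(`4`) bourse shoot, with bud scars (`5`) marking a within-season growth
cessation.  Read base-to-tip, these fates form zoned categorical sequences.
`branchzones` asks how that zonation depends on the parent shoot's growth
rhythm (monocyclic vs bicyclic), growth duration (GD) and growth period
(GP), for researchers in tree architecture and orchard management.

The package implements, end to end:

* **Shoot categorization** from weekly length records: growth cessations
  (length gain < 0.5 cm over a trailing two-week window), start dates
  (first crossing of 5 cm), GD classes split at 30/90 days, GP classes
  split at calendar thresholds (June 3 / July 18).
* **Hidden semi-Markov chains** over bud fates: `K` transient left-to-right
  states plus an absorbing end state, each state with an explicit zone-length
  (occupancy) distribution `d_j(u)`, `u ≥ 1`, a masked categorical emission
  `b_j(y)`, and transitions `a_{ij}` restricted to `j > i`.  The likelihood
  of a sequence `y_1..y_T` sums over segmentations,

  `P(y) = Σ π_{j1} d_{j1}(u_1) Π b_{j1} · a_{j1 j2} d_{j2}(u_2) Π b_{j2} ··· a_{jm, end}`,

  with `u_1 + … + u_m = T`.  Exact forward likelihood, explicit-duration
  Viterbi decoding and constrained forward–backward EM (multiple restarts,
  masked M-steps, BIC) are provided, with compiled inner loops.
* **Zone statistics**: occurrence probabilities (fraction of decoded shoots
  visiting a zone), negative-binomial GLM comparisons of zone lengths,
  Fisher-exact comparisons of lateral-type mixtures, Pearson correlation of
  zone length with shoot length.
* **Category statistics**: count GLMs with Tukey-style contrasts and compact
  letter displays, Kruskal–Wallis with Dunn/Holm post hocs, Mann–Whitney,
  chi-square/Fisher proportion tests.
* A **synthetic-data generator** with a fully specified ground truth
  (category mix 71/29, published zone-visit probabilities and floral-zone
  lengths), so the whole pipeline is exercised and validated by parameter
  recovery without any field data.

## Worked example

```r
library(branchzones)

st  <- simulate_study(227, seed = 1)            # growth series + sequences
res <- run_pipeline(st$sequences, growth = st$growth,
                    out_dir = "study_out")
res
#> branchzones pipeline: 227 decoded shoots; 2 model(s) fitted
#>  - categorize: 227 classified, 0 excluded
#>  - cohort A: 142 sequences; loglik -1196.9665; BIC 2505.2058
#>  - cohort B: 85 sequences; loglik -2066.4784; BIC 4384.5813

res$occurrence$A
#>           group  n S0   S1    S2
#> 1  one-GU_short 98  1 0.34 0.071
#> 2 one-GU_medium 44  1 0.73 0.250

res$node_number_test$letters
#>   one-GU_long one-GU_medium  one-GU_short       two-GUs
#>           "a"           "b"           "c"           "a"

res$correlations$B$r_squared
#> [1] 0.6221662
```

Reading the output: the 227 simulated shoots are categorized from their
weekly growth curves, split into the two model cohorts (monocyclic
short+medium GD vs monocyclic long GD + bicyclic), and each cohort's chain
is fitted and decoded.  The occurrence table shows every shoot starting in
the basal latent zone (S0 = 1) while the diffuse floral zone S1 appears in
34% of short-GD but 73% of medium-GD shoots — branching increases with
growth duration.  The letter display groups long-GD monocyclic with
bicyclic shoots ("a"): their node numbers are statistically
indistinguishable, unlike the short- and medium-GD classes.  The `R²` of
0.62 is the correlation between diffuse-floral-zone length and first-GU
length among shoots possessing that zone.  `study_out/` contains the
occurrence/zone-length/lateral-type tables as TSV, both fitted models as
YAML, and a text report.

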