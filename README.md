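# edphenotype

Computational phenotyping of opioid-related emergency department (ED)
presentations from electronic health record (EHR) data.

Patients with opioid-related conditions are heterogeneous — chronic use
disorder, acute overdose, psychiatric crises, and heavy comorbidity burdens
all arrive through the same ED door. `edphenotype` discovers data-driven
visit phenotypes instead of imposing preconceived labels: clinical concepts
extracted from notes are merged with structured-data tokens, filtered into a
cohort-contrastive vocabulary, topic-modelled, embedded on the topic
simplex, clustered, and finally profiled by survival and utilization
outcomes. A synthetic EHR generator with planted ground truth makes every
stage testable without access to protected health data.

## The method

For each ED encounter the pipeline builds a term-frequency bag combining

* **note concepts** — deterministic longest-match lexicon extraction to
  concept identifiers, filtered by UMLS-style semantic types (a transparent
  stand-in for MedCAT-class extractors; real extractor output can be
  substituted at the same interface),
* **structured tokens** — diagnosis-group and medication-class names, plus
  laboratory tokens where a value beyond two standard deviations of the
  matched background-cohort mean gains a `high <lab>` / `low <lab>`
  modifier.

Vocabulary selection is two-cohort contrastive. A token is dropped if its
document frequency exceeds 5% in **both** the opioid and background
corpora (note-template and care-process noise); surviving tokens are tested
for cohort independence with an uncorrected Pearson chi-square on the
document-level 2x2 table, and *keep words* are those with p < 0.05.

Keep-word bags feed latent Dirichlet allocation fitted by collapsed Gibbs
sampling with conditional

    p(z_i = k) ∝ (n_dk + α) · (n_kw + β) / (n_k + Vβ)

The number of topics K is chosen at the coherence plateau: the smallest K
whose mean UMass coherence is within ε of the grid maximum (relative to the
coherence range). Each encounter's embedding is its posterior-mean
topic-proportion vector θ_d, a point on the (K−1)-simplex.

Embeddings are clustered with K-means (k-means++ seeding, best of 10
restarts), validated by silhouette coefficients and the Dunn index, and the
cluster count maximizes mean silhouette. Each cluster is then profiled:
Kaplan-Meier one-year survival, Charlson comorbidity index (Quan ICD-10
mapping), 6-/12-month all-cause and opioid-related ED return rates,
buprenorphine/methadone/naloxone prescription rates, chi-square
increased/decreased flags against the remaining population, and the
relative risk of every structured variable,

    RR = (a / n_c) / ((A − a) / (N − n_c))

for a cluster of size `n_c` holding `a` of the `A` variable-positive
encounters among `N` total.

## Worked example

Percentages and relative risks recomputed from a published nine-cluster ED
opioid cohort feature table shipped with the package:

```r
library(edphenotype)

pct <- summary_from_counts(ed_cohort_counts())
dplyr::filter(pct, variable == "substance_use_disorders",
              cohort %in% c("overall", "cluster_9"))
#>   variable                cohort    count     n percent
#> 1 substance_use_disorders overall   63413 82577    76.8
#> 2 substance_use_disorders cluster_9  5869  6506    90.2

relative_risk(3605, 6506, 28233, 82577)   # cluster-9 alcohol-related disorders
#> [1] 1.711525
```

Cluster 9 carries substance-use-disorder documentation on 90.2% of its
encounters against 76.8% overall, and its alcohol-related-disorder rate is
1.71 times that of the remaining population.

A full synthetic run — two cohorts of 800 encounters, five planted topics,
four planted clusters:

```r
run <- run_pipeline(sim_config(n_opioid = 800, n_background = 800, seed = 11),
                    n_topics = 5, n_clusters = 4, n_iter = 400, seed = 3)
run
#> <phenotype_run>
#>   keep words: 137 | topics: 5 | clusters: 4

run$outcomes$summary[, c("cluster", "n", "survival_1yr", "cci_median",
                         "return12", "methadone")]
#>   cluster     n survival_1yr cci_median return12 methadone
#> 1       1   202        0.851          1    0.307     0.129
#> 2       2   184        0.973          0    0.234     0.342
#> 3       3   210        0.986          0    0.148     0.448
#> 4       4   204        0.912          1    0.328     0.211

adjusted_rand(run$assignment$cluster,
              run$dataset$truth$cluster[run$assignment$encounter_id])
#> [1] 0.997
```

The template words planted in both cohorts are removed by the 5% filter
(137 keep words survive), the planted topics are refit from the notes, and
K-means on the simplex embeddings recovers the planted clusters almost
exactly (adjusted Rand index 0.997). The outcome table shows the planted
gradient: clusters differ in one-year survival (85--99%), comorbidity
burden, 12-month ED returns and methadone prescribing. `tidy()`, `glance()`
and `autoplot()` methods cover the fitted model, the coherence profile, the
cluster selection and the outcome report; `plot_rr_heatmap()` draws the
red/teal cluster-profile map.

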