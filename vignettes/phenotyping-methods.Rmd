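---
title: "Phenotyping ED opioid presentations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping ED opioid presentations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(edphenotype)
```

## The problem

Opioid-related ED presentations span chronic use disorder, acute overdose,
psychiatric crises and multimorbid decline. `edphenotype` derives visit
phenotypes bottom-up: encounters are represented by what their notes and
structured records actually say, embedded in a low-dimensional topic space,
and grouped by unsupervised clustering. The clusters are then judged by
outcomes a clinician cares about — survival, comorbidity burden, ED
returns, and medications for opioid use disorder.

## Pipeline model, stage by stage

### Concept extraction

Extraction is deliberately the simplest component: greedy longest-match
dictionary lookup on token boundaries against a normalized lexicon
(lowercase, punctuation to spaces, collapsed whitespace). It is
deterministic and idempotent, matches never overlap, and a lexicon entry
can never fire inside a longer word (`tension` does not match
`hypertension`). Neural or self-supervised extractors are strictly more
capable — they handle misspellings and ambiguity — but they are not
reproducible test subjects. The mentions interface (`encounter_id`,
`concept_id`, span, `semantic_type`) is the substitution point: outputs of
a production extractor can be dropped in and everything downstream is
unchanged. Mentions are filtered by a semantic-type allow-list (packaged as
an editable YAML covering disorders, findings, procedures, chemicals/drugs
and anatomy); only surviving concept tokens enter the corpus, which is how
non-clinical note text is discarded.

### Corpus construction

Structured data contribute tokens alongside note concepts: diagnosis-group
names, medication-class names, and laboratory tokens. A lab always
contributes its plain name; it additionally contributes a single combined
token `high <lab>` or `low <lab>` when the value lies strictly beyond two
standard deviations of the background-cohort mean (sample SD, n−1
denominator, computed on the demographically matched background cohort).
Values exactly at a boundary take no modifier. Whether within-range labs
should contribute their plain name at all is genuinely open; we add it: the
plain token is cohort-neutral and the downstream
frequency filter removes it when it is ubiquitous, so the choice is
self-correcting.

Within an encounter all notes are pooled as a multiset: repeated mentions
each increment the term frequency, because the corpus is a term-frequency
corpus; all *document-level* statistics (the filters below) use presence
only.

### Vocabulary selection

Two filters, both at the document level:

* **Ubiquity filter.** A token is removed iff its document frequency
  exceeds the threshold (default 0.05) in *both* cohorts. "Appears in" is
  read as document frequency, not token share, because the filter's purpose
  is to strip note templates and care-process boilerplate, which are
  properties of documents. The inequality is strict; a token in exactly 5%
  of both corpora stays.
* **Keep-word test.** Each surviving token's 2x2 table (cohort x
  document-level presence) is tested with Pearson's chi-square, 1 df, no
  continuity correction, keep iff p < 0.05. No multiple-testing correction
  is applied — the procedure is a vocabulary screen, not an inferential
  claim, and raw p < 0.05 is the intended behaviour. All decisions (kept or
  not, with statistics) are returned for audit.

### Topic model

LDA is fitted by collapsed Gibbs sampling (the inference scheme of the
Mallet toolkit), single chain, default 1000 sweeps. Estimates are posterior
means of the final assignment state — deterministic given the seed — with
averaging over post-burn-in sweeps available as an option
(`average = TRUE`, burn-in 200). Hyperparameters are symmetric
α = 5/K and β = 0.01, Mallet's own defaults (Mallet distributes a total
document-topic mass of 5.0 over topics; the frequently quoted 50/K belongs
to a different heuristic tradition). Mallet's hyperparameter optimization
is not implemented. Encounters with no keep words are retained with an
empty document and embed at the uniform simplex point 1/K, so every
encounter always has an embedding.

Topic count selection uses intrinsic UMass coherence on the top 10 words
per topic: for ranked words the pair (i < j) contributes
log((D(w_i, w_j) + 1) / D(w_j)) with D the document (co-)occurrence counts.
"Coherence plateau" is made operational as: *the chosen K is the smallest
grid value whose mean coherence is within ε times the coherence range of
the grid maximum* (ε = 0.05 by default). With a flat profile this
degenerates to the smallest K, which is the conservative choice. Selection
fits use 500 sweeps (ranking stabilizes long before the final estimates
do); the final model is refitted at full length.

### Clustering

K-means with k-means++ seeding, Lloyd iterations to a 1e-6 centroid-shift
tolerance, best of 10 restarts by within-cluster sum of squares, and
empty-cluster repair by seizing the point farthest from its centroid.
Distance is Euclidean on the raw simplex embedding — the simplest
defensible choice; compositional alternatives (Aitchison, Hellinger) would
be reasonable refinements but change none of the package's interfaces.
Quality is assessed by mean silhouette (with the conventions: singleton
clusters score 0, and 0/0 is 0) and the Dunn index (minimum inter-cluster
distance over maximum intra-cluster diameter). The cluster count maximizes
mean silhouette, ties broken by higher Dunn, then smaller k. There is no
single canonical way to aggregate the three quality criteria; this
hierarchy is our operationalization and is recorded in the selection
output.

### Outcomes

Per cluster: Kaplan-Meier survival from ED discharge (product-limit, the
standard censoring-after-events convention at ties, administrative
censoring at a configurable end of follow-up), Charlson comorbidity index
under the Quan (2005) ICD-10 prefix mapping with original weights
(longest-prefix match, each category once, metastatic cancer superseding
other malignancy, severe liver disease superseding mild, complicated
diabetes superseding uncomplicated), ED return rates over (0, 183] and
(0, 365] days (inclusive right boundary), medication rates per encounter
(a per-patient reading is a one-line aggregation away and left to the
caller), the relative risk of each variable versus all remaining
encounters, and chi-square increased/decreased/neutral flags versus the
remaining population at α = 0.05. Pairwise log-rank tests back
between-cluster survival statements — the standard test for comparing
survival curves.

## The synthetic generator

`simulate_ehr()` is first-class, tested code, not a fixture: it encodes the
statistical structure the pipeline assumes, with planted ground truth.

* **Two cohorts.** Opioid encounters carry a planted cluster (categorical
  draw), a document-topic vector θ from a Dirichlet centred on the
  cluster's topic profile (precision 30 by default — documents are faithful
  to their cluster but not caricatures), and note tokens drawn token-wise
  (topic from θ, word from the planted topic-word row). Background
  encounters draw from a separate background topic. Every topic, including
  the background one, spends 15% of its mass on a small block of shared
  "template" words — these exceed 5% document frequency in both cohorts and
  give the ubiquity filter real work. Planted topics anchor 75% of their
  mass on disjoint Zipf-weighted word blocks, so pairwise total-variation
  separation is high by construction.
* **Default cluster profiles** put 0.7 on one "own" topic per cluster and
  spread 0.3 uniformly (pairwise TV 0.7, comfortably above the 0.5
  separation under which cluster recovery is expected).
* **Demographic matching** of the background cohort is emulated by
  resampling demographics from the opioid cohort's empirical distribution;
  the original matching procedure is not specified in detail, and the
  background:opioid ratio is a config knob rather than a constant.
* **Document lengths** are negative-binomial (mean 100, dispersion 20) —
  clinical notes vary widely in length and a fixed length would hide
  length-robustness bugs.
* **Outcomes** are cluster-conditional: exponential death hazards per day
  (defaults 8.6e-5 to 4.7e-4, i.e. one-year survivals of roughly 96.9% down
  to 84.2%, the span published cohorts report), 6-/12-month return
  probabilities planted exactly (a single return day is drawn uniformly in
  the earlier or later half-window), medication flags as Bernoulli draws
  (methadone up to 0.43), and ICD-10 codes from a pool mixing
  Charlson-scored chronic disease with mental-health and substance-use
  groups at cluster-conditional prevalences. Opioid-related returns are
  planted as an independent stream; in real data an opioid return would be
  defined by the return visit's diagnosis codes against the packaged
  opioid code list.
* **Dates** are ISO-8601 calendar dates; all interval arithmetic is integer
  days; follow-up ends 730 days after discharge.
* **Determinism.** One integer seed drives everything; the same config and
  seed give byte-identical datasets.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: realistic clinical language (rendered text is
lexicon surface forms with filler), extractor noise (missed or spurious
mentions), correlation between comorbidity burden and death beyond the
cluster label, competing risks, informative censoring, within-patient
correlation across repeat visits, and drifting documentation practice over
calendar time. Results on real EHR extracts depend on extractor quality and
code-mapping choices in ways the synthetic benchmark cannot certify.

## Numerical and testing choices

* Strict inequalities at the 5% filter and the ±2 SD lab boundaries; a
  value exactly on a boundary takes the lenient branch.
* Equal topic-word probabilities in ranked word lists break ties
  lexicographically; vocabulary indices are sorted lexicographically.
* Degenerate inputs fail loudly: empty corpora, empty keep sets, k beyond
  the number of distinct points, coincident zero-diameter clusters for the
  Dunn index. Labs with an SD of 0 in the reference contribute only their
  plain token, with a warning.
* The test suite and acceptance script use scaled problem sizes chosen to
  exercise the asymptotics that matter: 500 documents x 100 tokens
  (vocabulary 200) for topic recovery, 2000 encounters for cluster
  recovery and outcome rates (binomial 3-SE bounds), 8000 encounters
  (~2000 per cluster) for survival checks, and 2000+1000 encounters for
  the end-to-end pipeline. Recovery is measured by Hungarian-matched
  total-variation distance for topics and the adjusted Rand index for
  clusters.

## Limitations

Beyond the generator's idealizations listed above: the dictionary extractor
has no negation or uncertainty handling, so "denies chest pain" contributes
a chest-pain token — in production use, extractor output should carry such
filtering before it reaches the corpus; topic models assume exchangeable
tokens within a document; K-means assumes roughly isotropic clusters in
embedding space and the silhouette criterion inherits that bias; and the
uncorrected p < 0.05 keep-word screen is intentionally liberal and should
not be read as hypothesis testing. UMass coherence selects the topic count
reliably on note-only corpora, where co-occurrence is driven by topics; on
corpora that mix in structured tokens, whose co-occurrence follows the
cluster rather than the topic, the coherence profile can flatten or
mislead, and the topic count is better fixed from a note-only selection
run or domain knowledge. The published cohort counts bundled for
the worked examples support arithmetic reproduction only; the underlying
patient-level data are not public, and no claim of reproducing that cohort
end to end is made.
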