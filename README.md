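# semcoh

Semantic coherence metrics for clinical speech transcripts.

Disorganized, incoherent speech is a hallmark of formal thought disorder in
non-affective psychosis (schizophrenia-spectrum disorders). Clinical
ratings of incoherence are filtered through a listener's comprehension;
`semcoh` implements the standard distributional alternative for researchers
in computational psychiatry: score the transcript geometrically in a
word-embedding space. It targets structured emotion-interview transcripts
(four sections — sadness, fear, anger, happiness — of question/answer
exchanges), but any sectioned transcript works.

## The metrics

Each retained sentence becomes a vector $s_i$ — the mean of its
in-vocabulary token embeddings — giving a sequence $s_1,\dots,s_N$ per
section. With $\cos$ the cosine similarity:

- **local (first-order) coherence**
  $\;\frac{1}{N-1}\sum_{i=1}^{N-1}\cos(s_i, s_{i+1})$ — how well each
  sentence follows from the previous one;
- **global coherence**
  $\;\frac{1}{N}\sum_{i=1}^{N}\cos(s_i, \bar s)$, with
  $\bar s = \frac{1}{N}\sum_i s_i$ — how much each sentence stays on the
  overall topic.

Section scores are averaged over the four emotion sections; with two
embedding models this yields four metrics per participant. A `"verbatim_n"`
denominator mode reproduces the alternative $/N$ convention found in parts
of the literature (identity case scores $(N-1)/N$ instead of 1); see the
methods vignette (`vignettes/semcoh-methods.Rmd`) for why the
average-of-terms convention is the default.

Around the metrics sits the full study chain:

- transcript I/O (structured JSON and plain marker formats) with
  guideline-faithful sentence-boundary annotation;
- preprocessing: verbal-filler removal, German-stopword removal, pluggable
  lemmatization (shipped lexicons under `inst/extdata/`);
- loaders for word2vec-text and GloVe-text vector files, with a declared
  out-of-vocabulary policy (OOV tokens are excluded, never zero-filled);
- a validation layer: Pearson correlations, partial correlations
  (residualization, with independent-oracle tests), Welch/pooled t-tests,
  and report tables with descriptive, uncorrected p-values;
- a synthetic-data module: topic-structured toy embedding spaces,
  topic-drift transcripts with ground-truth topic labels, and simulated
  clinical cohorts with planted score–outcome effect sizes;
- `run_config()`/`run_pipeline()` for reproducible, provenance-stamped run
  directories.

## Worked example

Generate a toy embedding space and two transcripts — one that stays on
topic, one that drifts — and score them:

```r
library(semcoh)

space <- topic_space()                               # 8 topics, 50 dims
model <- make_embedding_model(space, seed = 7, name = "toy")
steady <- generate_transcript(space, drift_profile(p_switch = 0.05),
                              seed = 1, participant_id = "steady")
drifty <- generate_transcript(space, drift_profile(p_switch = 0.60),
                              seed = 1, participant_id = "drifty")
score_transcripts(list(steady, drifty), list(model),
                  lex = space_lexicons(space))
#> # A tibble: 2 × 4
#>   participant_id toy_local toy_global words
#>   <chr>              <dbl>      <dbl> <int>
#> 1 steady             0.655      0.793   271
#> 2 drifty             0.321      0.537   280
```

The low-drift speaker scores local coherence 0.66 — adjacent sentences
share a topic, so their vectors align — while the high-drift speaker drops
to 0.32; global coherence falls in step (0.79 vs 0.54) because the drifting
transcript has no single centroid to stay near. `words` is the raw
transcript length, kept as a nuisance variable for the validation stage.

## The analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin script
over package functions, writing its tables under `results/`:

1. `01_simulate_study.R` — simulate the study materials: two toy embedding
   models and a 71-participant cohort whose clinical table carries planted
   latent-coherence effects (|r| ≈ 0.1–0.35).
2. `02_score_coherence.R` — run the scoring pipeline end-to-end into a
   provenance-stamped run directory.
3. `03_validate_scores.R` — the correlational validation: score–score and
   score–outcome matrices, T2 partial correlations controlling T1, group
   t-tests, nuisance screen.
4. `04_method_properties.R` — ground-truth experiments: shuffle
   degradation, drift monotonicity, and parameter recovery at n = 500.

Run them in order with `Rscript analysis/01_simulate_study.R` etc.

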