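---
title: "Semantic coherence scoring: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic coherence scoring: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Disorganized speech — the loss of meaningful connection between one
utterance and the next — is a core feature of formal thought disorder in
non-affective psychosis. Clinical ratings of incoherence depend on a
listener's ability to follow the patient, which makes them subjective and
hard to standardize. `semcoh` implements the standard distributional
alternative: represent each sentence of an interview transcript as a point
in a word-embedding space and quantify coherence geometrically. The package
covers the full chain — transcript ingestion and sentence annotation,
preprocessing, sentence embedding, the two coherence metrics, and the
correlational validation of the resulting scores against clinical outcome
tables — plus a synthetic-data layer that makes the chain testable with
known ground truth.

## The metrics

A section of a transcript yields an ordered sequence of sentence vectors
$s_1, \dots, s_N$, each the arithmetic mean of the embedding vectors of the
sentence's in-vocabulary tokens. With $\cos(u, v) = u \cdot v / (\lVert u
\rVert \, \lVert v \rVert)$:

**Local (first-order) coherence** averages the similarity of adjacent
sentences,

$$\mathrm{local}(S) = \frac{1}{N-1} \sum_{i=1}^{N-1} \cos(s_i, s_{i+1}),$$

**global coherence** averages the similarity of each sentence to the
centroid $\bar{s} = \frac{1}{N}\sum_i s_i$,

$$\mathrm{global}(S) = \frac{1}{N} \sum_{i=1}^{N} \cos(s_i, \bar{s}).$$

Section scores are averaged, unweighted, over the four emotion sections of
the interview; with two embedding models this gives the four-metric design
(local/global × model).

### The denominator conventions

Published formulations of these metrics do not always divide the summed
similarities by the number of summed terms: one convention divides the
$(N-1)$-term local sum — and a global sum running only to $N-1$ — by $N$.
Under that convention a perfectly self-similar text scores $(N-1)/N$
rather than 1, and the score depends on length even when content does not.
We treat the *average-of-terms* reading (`denominator = "pairs"` for local,
`"terms"` for global) as the default, because the verbal definition of both
metrics is an average over pairs/sentences; the `"verbatim_n"` modes
reproduce the $/N$ convention exactly for comparability with work that used
it. Both modes are computed by the same code path and tested against
independent brute-force loop oracles to $10^{-9}$. We deliberately assert
neither convention as the "true" one used by any particular study.

### Missing values are values

A sentence whose tokens are all out of vocabulary has no direction, so it
has no sentence vector: it is dropped and counted, never replaced by a zero
vector (a zero vector would poison the cosine). Likewise `local` is `NA`
for $N < 2$ (no adjacent pair exists), `global` is `NA` for $N = 0$ or a
zero-norm centroid (exactly opposed vectors), and participant means are
taken over the sections that have scores. Nothing downstream ever coerces
`NA` to 0; the validation layer uses pairwise-complete observations for
plain correlations and listwise deletion for partial correlations.

### Invariances

Both metrics are invariant under a common positive rescaling of all
sentence vectors. Local coherence is additionally invariant under
*independent* positive per-sentence rescaling (each cosine is scale-free in
each argument), but global coherence is not: independent scales change the
direction of the unnormalized centroid. Global coherence is invariant under
permutation of sentence order; local coherence deliberately is not — order
sensitivity is what makes it "local". The test suite asserts exactly these
statements.

## The preprocessing chain

The chain is fixed: verbal-filler removal, then stopword removal, then
lemmatization, applied to annotated answer sentences only (interviewer
questions never enter the token stream). The order matters and is not
configurable: lemmatizing first could map inflected forms onto stopword
citation forms and silently change what is removed. Lexicon matching
lowercases both sides (German stopwords routinely appear capitalized
sentence-initially) while emitted tokens keep their casing, because some
embedding models are case-sensitive; embedding lookup tries the exact form
first and falls back once to the lowercased form.

Shipped German stopword and filler lists are versioned resource files. The
exact inventories used by any external study are rarely published, and
coherence scores are sensitive to them — analyses that must match another
pipeline should pass their own lists via `lexicons()`. The package's own
tests never depend on the shipped lists; they pass explicit toy lexicons.

Sentence annotation has two modes. `marker` mode — the reference path —
splits exactly at sentence-final punctuation, which is how manually
annotated transcripts encode boundary decisions (main clauses grouped with
their subordinate clauses; coordinated main clauses separated; incomplete
clauses closed with a period). `automatic` mode is a rule-based
convenience splitter that additionally breaks at a comma or semicolon
followed by a listed coordinating conjunction; subordinating conjunctions
are deliberately absent from that list, so subordinate clauses are never
split off. It approximates, and cannot replace, syntax-aware manual
annotation.

## What the synthetic data emulates — and what it does not

No patient recordings are distributed with coherence studies, so the
package generates its own study materials with known ground truth.

**Topic space.** `topic_space()` builds the one property the metrics rely
on: words of a topic cluster in vector space. Topic centers are random unit
vectors with pairwise cosine below a ceiling (default 0.5); word vectors
add spherical Gaussian noise with per-component SD $1/\sqrt{\kappa}$
(dispersion $\kappa = 40$ by default) and are renormalized. With the
default 50 dimensions this puts the within-topic mean word cosine near
0.45 and the between-topic mean near 0 — and transcript-level score means
near the 0.55–0.75 range reported for real interview cohorts, which is the
realism criterion the default was chosen by. Stopwords receive unrelated
unit vectors; fillers are deliberately out of vocabulary.

**Topic drift.** `generate_transcript()` draws each sentence's words from a
latent topic that switches with probability `p_switch` per sentence.
The default profile — four sections of 6–14 sentences of 3–9 word slots,
35% stopwords, 4% fillers — was sized once to the surface statistics of
emotion-interview speech (about 240 raw words and about 150 unique words
per transcript) and is not tuned thereafter.

**Cohorts.** `generate_cohort()` draws each participant's `p_switch` from
Beta(1.5, 6) (mean 0.2, SD ≈ 0.14) and defines the latent coherence trait
as its standardized negative. Outcomes are linear-Gaussian links at stated
target correlations, rescaled to instrument-like means and SDs and clamped
to plausible ranges; day-count outcomes are floored at zero and rounded,
which realistically skews them and slightly attenuates their realized
correlations (the realized values are recorded in the ground-truth table).
The Beta's spread is a deliberate design choice: with roughly 40 sentences
per transcript, the binomial realization of topic switches limits how well
any score can measure the latent trait, and the chosen spread puts that
reliability near 0.9 so that planted effects of $|\rho| \approx 0.3$
survive measurement attenuation at cohort scale.

Follow-up (T2) outcomes satisfy a stated T1–T2 autocorrelation (default
0.6) and a stated latent-coherence correlation (default 0). One subtlety
worth knowing when reading the partial-correlation report: with the default
*marginally* null T2, partialling out a T1 that is itself negatively linked
to coherence induces a small *positive* expected partial correlation — a
suppression effect of the generative structure, not a bug in the
statistics.

What the generator does **not** emulate: real lexical statistics (words are
pseudo-words with Zipf-free uniform use), syntax, disfluency structure
beyond filler insertion, rater behavior, item-level structure of the
clinical instruments, or context-dependent token vectors. Passing tests on
this material therefore demonstrate that the pipeline measures what it
claims on data whose generative process matches its assumptions — they say
nothing about the validity of coherence scores on real clinical speech,
which is precisely the open question validation studies exist to answer.

## Statistics layer

Pearson correlations use `stats::cor.test` on pairwise-complete pairs.
Partial correlations residualize both variables on the controls (least
squares with intercept) and correlate the residuals, with $n - 2 - k$
degrees of freedom; the test suite checks this against the
inverse-correlation-matrix identity to $10^{-9}$. The group-difference
t-test defaults to Welch — the variance assumption costs nothing when
variances are equal and protects when they are not — with the pooled test
available by flag. No multiple-testing correction is applied anywhere:
the validation layer is exploratory by design, every rendered table says
so, and p-values are descriptive.

## Numerical and degenerate-input choices

- Cosine values are clamped to $[-1, 1]$ after division to absorb
  floating-point overshoot on nearly parallel vectors.
- Zero-norm vectors are a domain error in `cosine_similarity()`; upstream
  construction guarantees they cannot reach it.
- Tokenization is NFC-normalized, whitespace-split, with edge punctuation
  stripped and case preserved.
- Empty answers annotate to zero sentences with a warning, never an error;
  sections that lose every sentence in preprocessing are kept as empty,
  counted records.
- Duplicate words in a vector file keep the first occurrence (with a
  warning); ragged lines are format errors naming the line.
- Every generator is a pure function of (specification, seed); per-purpose
  seeds derive from a root seed via a named-stream hash, so adding a
  generator never perturbs existing streams.

## Problem sizes

The default experiment sizes — 100 transcripts for the shuffle and drift
experiments, a 71-participant cohort for the worked analysis, 500
participants for parameter recovery, 200 random sequences for the metric
oracle — were chosen as the smallest sizes at which the quantities of
interest are stable to well under their effect sizes, and they run in
about a minute on a single core.

## Known limitations

- Both boundary-annotation modes operate on punctuation; neither verifies
  the subject-and-verb definition of a sentence syntactically.
- The lemmatizer is pluggable (identity or lookup-table by default); no
  morphological analyzer ships with the package, and German inflection is
  rich enough that the identity default under-lemmatizes real text.
- Binary word2vec files are not supported — text dialects only.
- The aggregation default scores one sequence per emotion section; if the
  three questions within an emotion are delimited separately in the input,
  they are concatenated rather than scored per question. Both readings of
  "per question" aggregation exist in the literature; per-section is the
  one implemented.
- Context-sensitive (transformer) sentence embeddings are out of scope; the
  package abstracts every model as a static word-to-vector map.
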