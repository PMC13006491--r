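---
title: "Methods: hybrid semantic-keyword triage of regulatory corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid semantic-keyword triage of regulatory corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regfed)
```

## The problem

Drug regulators publish at a pace no manual review team can follow: hundreds
of thousands of guidance documents, discussion papers, technical reports and
notices, of which only a small fraction — on the order of 3% — concern
artificial intelligence and machine learning in a regulatory context. The
triage task is rare-event detection under a hard asymmetry: a missed
AI-relevant document can mean missed compliance obligations, while a false
positive merely costs a reviewer a few minutes. The classifier is therefore
optimized for *recall subject to a bounded review burden*, not for accuracy.

`regfed` implements this triage as a pipeline of small, separately testable
stages: corpus ingestion and funnel filtering, per-document scoring,
OR-ensemble classification, recall-constrained threshold optimization,
decision-boundary validation, cross-agency bias auditing, and incremental
monitoring. A seeded synthetic-corpus generator makes the whole pipeline
exercisable offline.

## The dual-scoring model

Every document receives two families of scores.

**Semantic similarity.** Documents are embedded and compared against a
curated reference set of exemplar documents plus one *synthetic ideal
document* — the deterministic concatenation of the whole keyword taxonomy —
yielding three scores per document: the mean cosine similarity over the real
references (`avg_ref_score`), the maximum (`max_ref_score`), and the
similarity to the ideal document (`ideal_score`). The average and maximum
are computed over the real exemplars only; the ideal document contributes
its own score, since it is a different kind of anchor (a bag of concepts,
not a document). Embeddings come from a pluggable backend whose only
contract is determinism: same text, same vector. The default backend is a
hashed lexical embedder — normalized tokens and token bigrams are hashed
into 1024 signed buckets, weighted by `log(1 + count)` and L2-normalized.
Bigram features matter: multi-token phrases become distinctive coordinates,
which sharpens the contrast between topical content and the regulatory
boilerplate that all documents share. The backend needs no model download
and embeds a few thousand documents per second, which keeps the whole test
suite self-contained; a transformer sentence-embedding backend can be
registered behind the same contract where infrastructure allows.

**Keyword coverage.** A taxonomy carries three term lists — AI,
legal/regulatory, and biomedical terminology. For one domain with weighted
terms $t$ the score is

$$ s = \frac{\sum_t w_t \,\min(c_t, C)/C}{\sum_t w_t}, $$

where $c_t$ counts non-overlapping case-insensitive matches of the term
(multi-token terms as contiguous token phrases) and $C$ is a saturation cap,
default 3. The form is the minimal one with the properties a thresholdable
score needs: bounded in $[0,1]$, monotone in every count, and saturating so
that a document mentioning one term fifty times cannot outrank one that
covers the vocabulary broadly. The `ai_keyword_combined_score` is the
equal-weighted mean of the three domain scores.

**Classification** is an OR-ensemble over named scores: a document is
positive if *any* clause `score >= threshold` holds, thresholds inclusive.
The OR rule has a theorem-level property the tests assert on every
generated corpus: the ensemble's positive set is exactly the union of the
per-clause positive sets, so ensemble recall can never fall below any
constituent's recall. Seven default configuration templates are evaluated:
each of the four scores alone, and the keyword score OR-paired with each
similarity score.

## Threshold optimization

Three metrics drive optimization: **Test Recall** (fraction of a labeled
relevant test set captured), **High Priority Recall** (the same, restricted
to a high-confidence subset), and **Positive Rate** (fraction of the whole
corpus labeled positive — the manual review burden). A grid search over all
templates (default step 0.01 on $[0,1]$) keeps configurations meeting a
recall floor (default 70%) and ranks them by ascending positive rate. Ties
are broken by higher High Priority Recall, then higher Test Recall, then
fewer clauses, then a deterministic lexicographic key on clause names and
thresholds, so the ranking is a pure function of the score table and never
depends on enumeration order. For one- and two-clause templates the search
is computed exactly via cumulative count matrices over grid ranks (a
10,201-point OR-pair grid on a 5,000-document corpus evaluates in well
under a second); the unit tests verify the fast path against a literal
per-grid-point loop, including tie-break order.

Two diagnostics accompany optimization. *Error correlation* builds, for
each method, the binary miss indicator over the test set and reports
pairwise Pearson (phi) correlations; moderate correlation between the
keyword and similarity methods is the empirical justification for the OR
design — the methods fail on different documents. The package computes phi
over error indicators rather than correlating raw scores because the design
question is precisely whether *errors* coincide. *Sigma position* reports
where a threshold sits in corpus-distribution units, $z = (\theta - \mu) /
\sigma$, with $\sigma$ the population standard deviation — informative
because workable thresholds in this problem sit far in the upper tail of
the corpus distribution.

## Boundary validation, bias audit, monitoring

**Boundary analysis** restricts evaluation to documents whose score lies
within a window around a clause threshold, where uncertainty concentrates:
narrow windows are ±0.01 absolute, wide windows ±0.5 population standard
deviations of that score. Within a region the report compares each method's
recall (over test-labeled members) and positive rate (over all members)
against the ensemble's, with deltas in percentage points. Window membership
is inclusive, with a $10^{-9}$ absolute tolerance so that edge cases such
as $|0.32-0.33| \le 0.01$ behave as written rather than as binary floating
point would have it. Boundary positive rate is computed over *all* corpus
documents in the region, recall only over test-labeled ones; regions
without labeled documents report recall as undefined rather than zero.

**Bias audit.** Positive rates are reported per source agency with pairwise
gaps and ratios. The mitigation mechanism is reference diversification:
appending exemplars in the under-detected agency's style and re-scoring.
One subtlety the synthetic experiments expose: with only 8 shifted-style
exemplars among 35, the rate gap closes mostly from the over-detected side
(the majority agency's similarity scores settle once the reference set is
no longer purely its own style); detection inside the shifted agency rises
only weakly unless its exemplar share grows or the keyword taxonomy is
extended with its terminology. Both levers are exposed.

**Monitoring** consumes local sitemap snapshots — (url, last-modified,
optional digest) listings — and diffs them into new/updated/removed sets.
Batches of new or updated documents run through the same scoring and
classification pipeline; the state keeps an append-only ledger (an updated
document gets a second entry, never an overwrite), per-batch positive
rates, and is persisted by atomic replace-on-write. The invariant that
matters — and is tested — is incremental/batch equivalence: classifying a
corpus in k batches yields exactly the labels of a single pass.

## The synthetic corpus generator

The generator is first-class, tested code, not a fixture. Documents are
token mixtures over four pools: regulatory boilerplate (with an aligned
"European-style" variant used for agency style shifts), biomedical filler,
explicit AI phrases drawn from the default taxonomy, and contextual AI
phrases built to be disjoint from the taxonomy — phrases like "automated
decision support" that describe AI systems without using any taxonomy term.
That disjointness is the load-bearing design choice: it guarantees, by
construction, documents the keyword method cannot see but reference
similarity can, which is exactly the failure mode the OR-ensemble exists to
cover. A test asserts the disjointness so taxonomy edits cannot silently
break the construction.

Default conditions: 3% prevalence assigned exactly (`round(n * prevalence)`
documents relevant, so small corpora cannot drift below a usable test-set
size), 60% of relevant documents explicit / 40% contextual-only, agency
mixture 0.72/0.23/0.05, document lengths 120–240 tokens, and a per-document
AI-content fraction drawn uniformly from 0.15–0.55 so relevance is a
continuum rather than a cliff — that continuum is what populates decision
boundaries. Five percent of irrelevant documents carry one stray explicit
AI phrase as background noise. Metadata (dates, languages, categories,
including a tail predating the date window and a few unknown dates) feeds
the funnel-filter stages. Generation is a pure function of the parameters
and seed, and the caller's RNG stream is left untouched.

What the generator does *not* emulate: real regulatory prose (no syntax,
no discourse structure), document-length extremes, PDF extraction noise,
multilingual content, and topic drift over time. Passing tests therefore
demonstrate that the pipeline's logic is correct and that its qualitative
behaviors (ensemble synergy, boundary asymmetry, bias response) follow
from the assumed corpus structure — not that any particular recall level
will transfer to a live corpus. On real data the reference set and
taxonomy do the domain work, and they are curated inputs.

## Numerical and design choices

* Thresholds compare with exact floating-point `>=` — no epsilon — so
  classification is bit-for-bit reproducible per backend. Boundary windows,
  which are measurement rather than decision, use the tolerance above.
* Unknown dates are kept by default during filtering (agency timestamps can
  reflect technical rather than content updates); unknown languages are
  dropped by default. Both are flags on `filter_config()`.
* Filter stages are applied in a fixed order — language first, then
  time + category — and the funnel report counts per agency after each
  stage, percentages relative to that agency's initial collection, one
  decimal on display.
* Empty text embeds to a flagged zero vector (similarity 0 to everything)
  rather than an error, because unextractable documents are a normal state
  in document pipelines.
* The population (not sample) standard deviation is used for sigma
  positions and wide boundary windows; with corpus-scale n the difference
  is negligible, and the population form matches the "distribution of the
  corpus in hand" reading. Configurable where it appears.
* Grid-search tie-breaking (positive rate, then High Priority Recall, then
  Test Recall, then clause count, then lexicographic) is a package
  convention; only the constraint and objective are principled, the rest
  exists to make results reproducible.
* `avg_ref_score` averages over the real references only. Whether the
  ideal document should join that average is genuinely arguable; keeping it
  separate preserves it as an independent signal (and configuration
  templates can use either).

## Problem sizes used by the test suite

The package's own validation runs at desk scale, chosen so the full suite
completes in minutes: oracle-equivalence and property tests on corpora of
up to 1,000 documents; the recall-constraint reproduction and
boundary-asymmetry experiments on 5,000-document corpora with 127/38 test
sets (the smallest scale at which narrow boundary regions are reliably
populated); bias experiments on 2,000-document two-agency corpora; and
incremental-equivalence on 2,000 documents in four batches. The
`scripts/acceptance.R` script reruns the 5,000-document optimization
end-to-end and reports the recomputed Test Recall of the winning
configuration.

## Known limitations

The hashed lexical embedding captures vocabulary and phrase overlap, not
meaning; paraphrases with zero lexical overlap defeat it, which on real
corpora argues for registering a sentence-embedding backend. Keyword
scoring is exact-match after normalization — no stemming, no fuzzy
matching. Precision is deliberately never estimated: in the intended
deployment the negatives are never reviewed, so only recall against a
curated test set and the positive rate are measurable. Monitoring trusts
URL identity; a document whose URL changes but whose content does not will
be re-scored as new (digests catch the converse case).
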