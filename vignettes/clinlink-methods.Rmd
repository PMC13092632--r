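---
title: "From clinical notes to SNOMED-CT concepts to a heart-failure diagnosis: methods"
author: "clinlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From clinical notes to SNOMED-CT concepts to a heart-failure diagnosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinlink)
```

## The problem

Clinical notes carry most of a patient's record but resist automated use:
abbreviations are ambiguous ("HT" may be hypertension or head trauma),
synonyms and paraphrases hide concepts from keyword systems, and downstream
models need standardized inputs. `clinlink` implements a zero-shot pipeline
that (1) disambiguates abbreviations from context, (2) links free-text spans
to concepts of a clinical terminology (SNOMED-CT or UMLS shaped), and
(3) classifies patients into four heart-failure diagnosis groups (no heart
failure, HFrEF, HFmrEF, HFpEF — the ejection-fraction-defined subtypes) from
TF-IDF weighted concept bags fused with structured EHR features. "Zero-shot"
means no labeled training data for the linking task itself: everything rests
on semantic text similarity plus per-concept context collections that grow
through online learning.

## Embedding backend

Every similarity in the pipeline is a cosine between unit text embeddings
behind one provider interface. The default, and the provider every test runs
on, is a deterministic character 3-gram feature-hashing embedder: the text is
lowercased and whitespace-collapsed, padded with one leading/trailing space,
each trigram of Unicode code points `(c1, c2, c3)` is hashed as
`h = 961*c1 + 31*c2 + c3`, accumulated into bucket `h mod 256` with sign
`(-1)^(floor(h/256) mod 2)`, and the vector is L2-normalized. The recipe is
seedless and uses only integer arithmetic that is exact in doubles, so two
processes on any platform produce bit-identical vectors. Two texts score 1.0
exactly when their normalized forms are equal, and score highly when they
share character n-grams — a lexical-overlap notion of similarity.

Neural semantic-similarity providers (e.g. a biomedical sentence embedder
for English and a multilingual one for other languages) can be registered by
name at run time (`registerEmbeddingProvider`); the package never bundles
weights, and every downstream code path is identical under either provider.
Retrieval (`topKHits`) is an exact dense scan — scores are dot products of
unit vectors, sorted descending, ties broken by ascending description id —
because index sizes in this package's scope never justify an approximate
index, and exactness makes the retrieval testable against a brute-force
oracle.

What the hashing fallback does *not* model is true semantics: it cannot rank
"myocardial infarction" near "heart attack". Tests passing under the
fallback therefore demonstrate the *mechanics* of every stage (span
handling, filtering rules, thresholds, learning updates), not the semantic
quality a neural provider supplies on real notes.

## Terminology store

`loadRF2` ingests SNOMED-CT RF2 snapshot tables (concepts, descriptions,
relationships), keeping only active rows and only "is a" (`116680003`)
relationships as hierarchy — the ancestor expansion used by the classifier
is purely hierarchical, so other relationship types are ignored. The concept
category comes from the semantic tag of the fully specified name. `loadRRF`
ingests UMLS MRCONSO/MRSTY tables; UMLS concepts get empty ancestor sets
(ancestor expansion is a no-op there), because the hierarchy reasoning in
this pipeline is SNOMED-CT's.

Descriptions are deduplicated case-insensitively per concept, and an
identical (normalized) text shared by several concepts becomes one
*ambiguous* description carrying all of their ids — about 40% of concepts in
large biomedical corpora need such disambiguation, which is what the context
collections resolve. Ancestor closure is a memoized DFS; it is tested against
an independent brute-force transitive closure on random DAGs and is monotone
under edge addition.

## Abbreviation disambiguation

Detection is dictionary pattern matching at token boundaries, longest key
first (so "CAP" is never pre-empted by its nested "AP"), then leftmost;
retained matches never overlap. All-uppercase keys match case-sensitively —
"AP" must not fire inside lowercase words — while mixed-case entries from
curated lists match case-insensitively. Dictionaries can be harvested from
hyphenated terminology entries ("AP – abdominal pain") with an
initial-letter rule.

Expansion is context comparison: the sentence containing the match is scored
against up to 30 stored context samples per candidate expansion (sentences
from a reference corpus that contain the expansion verbatim — reverse
substitution), and the arg-max expansion is chosen iff its best sample
clears the similarity gate. The gate defaults to 0.3; sweeping it trades
recall against attempted-expansion precision, and the package exposes the
full sweep. A sense with no context samples is never selectable. Tie-breaks
on equal scores are lexicographic on the expansion text, for determinism.
The sentence splitter is deliberately simple (periods, `!`, `?`, newlines);
the context window is the containing sentence — a design choice, since no
canonical window exists.

`expandAbbreviations` rewrites the text and returns a piecewise offset map
(`mapToOriginal`, `originalSpan`, `expandedPosition`) so entity-link spans
can always be reported in original-document coordinates.

## Entity linking

Candidate identification (recall phase), in exactly this order:

1. build the abbreviation table (spans + context-chosen expansions);
2. tokenize on non-alphanumeric boundaries and form all n-grams of 1–30
   tokens (30 accommodates the longest pre-coordinated clinical phrases);
3. drop n-grams containing a prohibited infix — `". "` and `"- "` by
   default, which signal sentence or bullet boundaries — then expand
   abbreviations inside the survivors while preserving the original
   character spans;
4. retrieve the top-10 most similar terminology descriptions per n-gram; a
   hit on an ambiguous description fans out to one candidate per concept,
   leaving disambiguation to the context filter.

Candidate selection (precision phase), four steps, each a pure filter so the
final links are always a subset of the thresholded candidates:

1. **Threshold filter** — keep candidates with similarity at or above the
   selection threshold. The method is intended for high thresholds
   (0.90–0.99); the package default is 0.95.
2. **Concept pinpointing** — among overlapping candidates for the *same*
   concept, keep only the maximum-similarity one. "Overlapping" is
   non-empty character-interval intersection, grouped as connected
   components of the overlap graph; ties prefer the shorter, then leftmost
   span. Non-overlapping repeats elsewhere in the document all survive.
3. **Context-collection filter** — a concept with only negative samples is
   blacklisted; with both kinds, the candidate is dismissed when the best
   negative-sample similarity to the candidate's sentence exceeds the best
   positive-sample similarity; with no samples it passes. Online learning
   feeds this filter: after a document is linked (never before — that
   ordering prevents leakage), gold-confirmed concepts gain the surrounding
   sentence as a positive sample and falsely linked concepts gain it as a
   negative one.
4. **Nesting minimization** — for an inner candidate strictly inside an
   outer one, the outer n-gram is re-scored against its matched description
   with the inner text removed. If similarity drops, the inner text was
   information the outer link already carries ("hypertension" inside
   "family history: hypertension") and the inner link is dismissed;
   otherwise both are kept. The re-scoring target is the outer candidate's
   *matched description* (not the concept's preferred name) — the quantity
   the original similarity was computed against, so the comparison is
   like-for-like.

Pinpointing runs before context filtering, per the step order above; when
pinpointing removes a candidate the context filter would have kept, the
remaining candidate for that component still represents the concept, so no
information is lost. Evaluation is strict: a link is correct only when span
*and* concept id match the gold annotation exactly. Readers for PubTator and
pipe-delimited standoff formats convert to this convention; gold annotations
with disjoint spans are skipped and counted (the linker does not support
them), as are "CUI-less" annotations.

## Classification

Each patient's linked concepts are expanded with *all* is-a ancestors (each
occurrence contributes itself plus every ancestor), which lets a linear
model generalize from rare specific concepts to broader categories and keeps
test-time vectors from being entirely unseen. Bags are TF-IDF weighted with
the conventional smoothed variant — `idf = ln((1+N)/(1+df)) + 1`, raw term
frequencies, L2-normalized rows — fit on training folds only; test-fold
concepts outside the training vocabulary contribute nothing. EHR features
are median-imputed and z-scored (numeric) or one-hot encoded with an
explicit "missing" level (categorical), again with training-fold statistics
only.

The learner is a hinge-loss linear SVM with balanced class weights
(`n / (2 * n_class)` per one-vs-rest problem), decomposed one-vs-rest over
the four classes; prediction takes the largest decision value. Evaluation is
stratified 5-fold cross-validation with the fixed seed 2026: fold
assignment shuffles within each class and deals round-robin, so every fold's
class proportions match the cohort within one patient and reruns are
bit-identical. Test-fold predictions are pooled across folds before
computing support-weighted precision/recall/F1 (macro-F1 is also reported,
since the averaging convention behind single-number reports is often left
unstated) and the row-normalized confusion matrix. The hinge model produces
no probabilities; where scores are needed they are softmax-calibrated
decision values, explicitly labeled non-probabilistic.

## Metric suite

`prf` (0/0 = 0 by convention), expansion accuracy = correct / attempted
expansions, total accuracy = recall x expansion accuracy (the end-to-end
disambiguation score), exact-match link scoring with micro-averaged counts
across documents, Cohen's kappa `(p_o - p_e) / (1 - p_e)` (degenerate
`p_e = 1` returns 1), absolute agreement (share of unanimous items), and
row-normalized confusion matrices. Percentages render at one decimal, round
half up. The kappa paradox — kappa far below raw agreement under imbalanced
marginals — is demonstrated in the tests because it matters when reading
survey agreement numbers.

## Synthetic fixtures and what they show

The real corpora this method is normally run on are licensed or private, so
the package ships seeded generators that emulate their *shapes* with planted
truth: an RF2-dialect terminology (random is-a tree of configurable depth,
synonyms from disjoint word pools, a configurable fraction of descriptions
shared between two concepts, plus "history of X" composites whose text
contains another concept's synonym verbatim — the nesting scenario);
a CASI-style snippet set with sense-discriminative context words; a
MedMentions/ShARe-style annotated corpus whose mentions are verbatim
descriptions; and a DARIO-shaped cohort with the class mix
41.5 / 22.8 / 20.7 / 15.0% (the printed prevalence of the reference cohort
of 846 patients), five exclusive marker concepts per class and
class-conditional EHR normals (ejection fraction foremost). Default sizes —
30 concepts, 20 documents with 3 mentions each, 200 patients — keep the full
suite and the acceptance script within seconds on one CPU while leaving
every planted structure (ambiguity, nesting, class signal) present; they are
the package's chosen test conditions, stated here once and not tuned.

Each generator draws from its own stream seeded by (master seed, generator
name), so adding one generator never shifts another, and identical spec +
seed gives byte-identical output. Because mentions are verbatim descriptions
and the hashing embedder scores verbatim matches at exactly 1.0, the planted
corpus is *fully recoverable*: end-to-end linking at threshold 0.9 reaches
micro precision = recall = 100%, and the strong-signal cohort reaches
macro-F1 above 0.9. Those are checks that the machinery is exact, not claims
about real clinical text, where recall is bounded by how often the note's
phrasing matches a description under the chosen embedder. Conversely,
permuting cohort labels collapses cross-validated F1 to chance, confirming
the evaluation protocol leaks nothing.

## Numerical and degenerate-input choices

Zero-variance EHR features get a unit divisor (zero after centering);
all-missing numeric features impute 0. Empty strings are input errors for
the embedder (the error names the offending index); an n-gram reduced to
emptiness by nesting removal counts as "similarity dropped" (inner
dismissed). Ties are always broken deterministically (ascending description
id in retrieval, shorter-then-leftmost span in pinpointing, lexicographic
expansion text in disambiguation). The libsvm optimizer behind the SVM is
deterministic for fixed input, and fold assignment is the only seeded
randomness in evaluation.

## Known limitations

The identity translation hook only chunks text at sentence boundaries and
shells out; no translation quality is claimed. The linker does not emit
negation modifiers (it links to pre-coordinated negated concepts where the
terminology has them) and does not support disjoint-span or post-coordinated
targets. The hashing provider is a lexical device: production use should
register a neural semantic-similarity provider. Whether candidate
identification and selection share one embedding space is an open question
in the method's description; this implementation uses a single provider per
pipeline run, which keeps the threshold semantics consistent across stages.
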