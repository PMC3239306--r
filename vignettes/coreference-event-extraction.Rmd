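---
title: "Coreference-aware event-argument extraction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coreference-aware event-argument extraction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Biomedical event extraction identifies *event triggers* (tokens such as
"induction" or "binding", frequently nominal), assigns each an *event type*,
and links each event to its *arguments* with the roles **Theme** and
**Cause**. Most extractors work one sentence at a time, yet a substantial
share of true event-argument (E-A) links cross sentence boundaries: a later
sentence refers to an earlier entity through an anaphoric mention ("The
region") whose full description ("The IRF-2 promoter region") lives in a
previous sentence. `corevent` implements two extractors that exploit
coreference information to recover such links, plus everything needed to
study them end to end without any external corpus: a document model with a
shared token index space, readers/writers, a high-precision pairwise
coreference resolver, a synthetic corpus generator, and a cross-validated
evaluation harness.

Three ideas drive both extractors:

* **Transitivity (T).** If token `j` is a Theme of event `i` and `j`
  corefers with an earlier token `k`, then `k` is a Theme of `i` too. This
  is the only mechanism by which either model proposes cross-sentence
  links: candidate arguments are the current sentence's tokens plus the
  antecedents of its tokens, never arbitrary earlier tokens.
* **Salience in discourse (SiD).** Entities mentioned repeatedly are
  salient, and salient entities tend to be arguments of some event. A
  soft formula rewards assignments in which a clustered (anaphoric) token
  receives at least one role.
* **Feature copy (FC).** An anaphor is lexically thin ("The region"); its
  antecedent's words are informative. Copied features transfer the
  antecedent's word/POS/NE evidence (including its dependency children,
  e.g. "IRF-2") onto the anaphor under a separate feature namespace.

# The two models

## Two-phase pipeline

Phase 1 classifies every token into the event-type inventory plus
`Not-Event` (a 36-class problem for a 35-type inventory). Phase 2
classifies every (trigger, candidate) pair inside a sentence into
Theme/Cause/None, where candidates are the NE-tagged tokens and the other
triggers of the sentence. Both phases are one-vs-rest ridge-penalized
logistic models over sparse indicator features (argmax decoding with ties
broken by label order; the penalty `lambda = 1e-4` is deliberately weak so
that lexically separable training data is fit exactly). When coreference is
available, phase 2 additionally sees the copied antecedent features, and a
deterministic post-processing step applies transitivity: every predicted
argument's earlier cluster mates receive the same role. Without
coreference input the pipeline *cannot* produce a cross-sentence link — a
structural zero, not an empirical one.

## Joint Markov Logic model

The joint model declares three hidden predicates — `event(i)`,
`eventType(i,t)`, `role(i,j,r)` — and grounds, per sentence, a weighted
clause network:

* **Local formulae** connect observed token atoms (word, POS, stem, NE,
  chunk, trigger-dictionary membership, character classes, bigrams,
  trigrams, incoming dependency label) and pair atoms (labeled and
  unlabeled dependency path, least common ancestor) to each hidden
  predicate, with one learned weight per (template, feature value[, type or
  role]) combination.
* **Four hard consistency formulae**: an event has a type; a type implies
  an event; a role implies an event; an event has at least one Theme. The
  existential consequents are grounded as disjunctions over the candidate
  domain; over an empty domain the disjunction is false, so a token with no
  candidate arguments cannot be an event. (We ground the Theme-existence
  clause even in that degenerate case — the logically correct reading —
  so every MAP decode satisfies all four implications everywhere.)
* **Coreference formulae**, switchable per preset (`baseline`, `fc`,
  `fc_sid`, `fc_t`, `full`): FC as per-copied-feature soft unit factors on
  the anaphor's role atoms (weights shared across roles and events); SiD as
  one soft clause per clustered in-sentence token and role, satisfied when
  any event takes it as an argument; T as soft clauses
  `role(i,j,r) ∧ corefer(j,k) ⇒ role(i,k,r)` over symmetric-closure
  corefer atoms.

Cross-sentence role atoms are grounded only when T is enabled: the
antecedent extension of the candidate set exists to serve transitivity, so
presets without T are structurally intra-sentential. By default the role
atom domain is "typed" (event side: trigger-lexicon tokens; argument side:
NE-tagged or lexicon tokens plus antecedents), mirroring the
event-protein / event-event pair families of the pipeline and keeping
ground networks compact; `arg_domain = "all"` lifts the restriction.

**Inference.** MAP decoding solves the standard 0-1 encoding (one binary
per hidden atom, a satisfaction indicator per soft clause, linear
implication rows) exactly, with a depth-first branch-and-bound solver:
hard-clause unit propagation, decomposition into connected components of
the factor graph, an admissible bound (undecided atoms at `max(score, 0)`,
unfalsified soft clauses at `max(weight, 0)`), and ties broken toward fewer
true atoms then lexicographic atom order. A brute-force enumerator with the
same tie-break serves as an independent oracle; the suite cross-checks the
two on random networks of up to 16 atoms.

**Learning.** Weights are learned by averaged passive-aggressive updates:
per instance, a loss-augmented MAP decode (weighted Hamming loss, role
atoms counted double because the role predicate is the extraction target),
then a margin-scaled step toward the gold feature counts, clipped at
`aggressiveness = 1`. Instance order is a seeded permutation per epoch;
three epochs are the default. Averaged passive-aggressive learning is this
package's choice among the standard online max-margin learners for
structured prediction: it is deterministic given a seed, has a single
interpretable hyperparameter, and needs only the MAP decoder already
required at test time.

## Pairwise coreference resolver

Mentions are NP-chunk heads; all ordered mention pairs within a sentence
window are classified corefer/not by a linear-kernel SVM over basic pair
features only (word/stem match, POS and NE tag pairs, binned sentence
distance, substring and acronym shape). Class imbalance is absorbed by a
positive-class cost multiplier (default: the negative/positive ratio), and
the operating threshold is chosen precision-first on a held-out document
split: the most permissive threshold whose development precision still
reaches 0.9. Downstream extractors are deliberately fed high-precision,
low-recall chains: noisy chains actively mislead the coreference formulae,
whereas missed chains merely forgo gains.

# The synthetic corpus

`synthetic_config()` defines the study conditions; `simulate_corpus()` is
deterministic given its seed. Documents have 3–5 sentences of 7–10 tokens.
Each sentence carries one event (a second with probability 0.3) whose
trigger is drawn from a type-specific lexicon (from a shared ambiguous pool
with probability `noise_rate = 0.05`, making the corpus separable at 0);
every event has a Theme and, with probability 0.35, a Cause; arguments are
entity NPs attached directly to their trigger with informative dependency
labels. With probability 0.35 a non-initial sentence contains a
cross-link situation: 80% are realized through a chain — the event's Theme
is an anaphoric re-mention of an earlier entity, attached with a
deliberately uninformative label and accompanied by a same-syntax
non-argument distractor, and the gold roles are closed under transitivity
so every earlier mention of the entity is also a gold argument — and 20%
are zero-anaphora: a direct gold link to an earlier mention with no
bridging chain, which neither model can reach (their recall ceiling is the
chained fraction). Independently, with probability 0.2 a sentence re-mentions
an earlier entity without making it an argument, attached exactly like an
anaphoric argument, so clustered-ness is informative but not conclusive.

These rates were chosen once, to resemble the mixture of an
event-annotated biomedical corpus with cross-sentence coreference:
coreference is predominantly event-related and roughly a third of
non-initial sentences involve cross-sentence structure. They were not
tuned to any test outcome.
What passing tests on this corpus show is that the machinery — candidate
restriction, grounding, exact inference, learning, transitivity,
precision-first resolution — behaves as designed under controlled
conditions. They do not show that the models reach any particular accuracy
on real biomedical text: real corpora have richer syntax, unseen
vocabulary, imperfect parses and far messier discourse structure, and the
generator imitates none of a real corpus's vocabulary or its 35-type
ontology.

One consequence of a *clean* generative world is worth stating plainly:
the Feature-Copy formula's copied POS/NE atoms are near-constant across
antecedents, so FC can emulate a per-atom "is clustered" indicator that
largely subsumes the Salience-in-Discourse signal; the measured W-ANT
margin between the `full` and `fc_t` presets is therefore small and
seed-sensitive here, whereas transitivity's effect (cross-link recall
versus a structural zero) is categorical. On real text — where antecedent
features are heterogeneous, sparse and frequently unseen — the two
formulae have more room to complement each other; in this emulation their
redundancy is a property of the conditions, not of the implementation.

# Numerical and degenerate-input choices

* Anchor tokens: the span token whose head exits the span; leftmost on
  (ill-parsed) ties. Single-token spans are their own anchor.
* Dependency paths are intra-sentence only; cross-sentence pairs carry
  token-level features only.
* Character n-grams use no boundary markers.
* The trigger dictionary is built from gold trigger stems of the training
  split — no external lexical resources anywhere.
* `coref_closure` is the connected-components closure of the link graph;
  the `corefer` atoms supplied to models are its symmetric closure, with an
  unlimited sentence window by default.
* MAP tie-breaks (fewer true atoms, then lexicographic) make decoding
  deterministic; the learner's only randomness is the seeded instance
  order.
* Degenerate cases: empty documents and empty annotation layers flow
  through every stage; single-class resolver data and gold assignments
  violating hard constraints abort with informative errors; infeasible
  hard-constraint systems name a violated component.

# Problem sizes used by the checks

The bundled checks run, on one CPU, with 200-document corpora for the
structural and constraint-satisfaction properties, a 200/50 train/test
split for parameter recovery, 100 random networks (≤ 16 atoms) for the
inference oracle, and 60/25 documents for the resolver operating point —
sizes at which every property is measurable in minutes while the learned
weights are stable enough to interpret.

# Known limitations

* Spans are given (or generated); phrase-boundary prediction and
  discontinuous triggers are out of scope.
* The pipeline's phase 2 pairs triggers only with NE-tagged tokens and
  other triggers; non-trigger nominals without NE tags are never candidate
  arguments.
* Dependency-path features carry labels and directions only, not
  intermediate POS tags.
* Marginal (probabilistic) inference, document-level joint grounding and
  joint coreference+event inference are not implemented; instances are
  per-sentence by design.
* The resolver's pair-feature set and the learner's hyperparameters are
  this package's own defaults, chosen for the basic-features,
  precision-first setting described above; other choices in the same
  family would be defensible.
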