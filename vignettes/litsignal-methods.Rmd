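---
title: "Rule-based extraction of signaling events: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based extraction of signaling events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litsignal)
```

## The problem and the model

Most mechanistic knowledge about cell signaling — which kinase
phosphorylates which substrate, what assembles into a complex, what is
degraded when — sits in free text, far beyond the throughput of manual
curation. `litsignal` implements a cascade of interpretable rule-based
extractors that turns biomedical sentences into grounded interaction
records. The cascade proceeds from low- to high-complexity representations:

1. **Preprocessing** — sentence and word segmentation with biomedical
   conventions (intra-word dashes and slashes are separators, so
   "GAP-mediated" exposes a catalysis and "Dvl2/aPKC" exposes complex
   members), and ingestion of dependency parses from CoNLL-U or a pluggable
   parser provider.
2. **Entity extraction** — dictionary NER over knowledge-base names and
   synonyms (UniProt/InterPro/ChEBI/HMDB/GO namespaces), pattern rules for
   reaction sites ("Ser37", "S83") and cellular components, grounding to KB
   identifiers, and attachment of states: wild type, point mutants
   ("H2AX-K134A"), and post-translational modifications ("phospho-p38").
3. **Event extraction** — a two-step bottom-up strategy. Step one extracts
   *simple events*: the nine PTM addition reactions (phosphorylation,
   ubiquitination, hydroxylation, sumoylation, glycosylation, acetylation,
   farnesylation, ribosylation, methylation), their de-/removal mirrors,
   binding (binary; n-ary assemblies are binarized), hydrolysis
   (cleavage/degradation) and translocation (theme/source/destination).
   Step two wraps causes into *nested events*: regulations (controller over
   an event) and activations (controller over an entity's implied
   activity), both signed.
4. **Polarity** — the stated sign of a nested trigger ("enhances" = +) is
   corrected by scanning the dependency path connecting the trigger to its
   arguments for reversal words ("decreased", "loss", "knockdown"),
   including adjectival modifiers hanging off the path; the final sign is
   base sign × (−1)^cues.
5. **Coreference** — deterministic sieves in precision order (exact string,
   mutant alias, event label, type-compatible nearest antecedent) resolve
   entity and event anaphors ("this protein", "this binding"), after which
   event extraction is re-run on the affected sentences.
6. **Assembly** — events are normalized to directed edges
   (`controls_state_change` with a reaction subtype,
   `controls_activity`, symmetric `in_complex_with`), evidence is counted
   at *paper* granularity, a redundancy filter keeps edges seen in ≥ k
   papers (default 2), and the result merges with curated prior networks
   in SIF format.

## The grammar

The central design idea is a small number of *parameterized rule
templates*: one template captures a syntactic variation (say, the
declarative "CAUSE VERB THEME"), and the verb is a parameter instantiated
per event type from a trigger lexicon, so "phosphorylate" and
"ubiquitinate" share machinery. Ten recurring variations are encoded:
declarative, passive, prepositional/object/subject nominalization,
subject/object relative clauses, subject/object apposition, and
paraphrastic causatives ("X causes the degradation of Y"). Combinations
(a passive inside a relative clause, "Pde2, which has been found to
hydrolyze Ras, activates MEK") fall out of path composition rather than
extra templates.

Templates come in two dialects. *Syntax* patterns are per-role paths over
the dependency tree — direction, label disjunction, optional hops, and
lexical constraints on intermediate nodes (the full DSL is documented in
`?rule_template`). *Surface* patterns are linear token windows used for
entity recognition, state attachment, and parse-free fallback event rules
(fallbacks run only when a sentence has no parse, so they never duplicate
syntax matches). The shipped inventory is exactly 154 named templates —
95 syntax, 59 surface; 32 on the entity side and 122 on the event side —
and `grammar_inventory()` is asserted against those counts in the test
suite. The grammar also ships serialized as YAML
(`inst/extdata/grammar/grammar.yaml`); `load_grammar()`/`write_grammar()`
round-trip it.

```{r}
grammar_inventory()
```

Two disambiguation devices deserve mention because they were forced by
fixture failures rather than invented a priori:

* object-relative templates `forbid` an active `nsubj` on the relativized
  verb, otherwise "X, which phosphorylates Y" (a subject relative) also
  fires the object-relative pattern with the roles swapped;
* bare object-nominalization ("EphrinB1 phosphorylation") forbids an
  `nmod:of` dependent, which is the signature of the *subject*
  nominalization ("Smurf1 ubiquitination **of RhoA**").

A role whose path can end on either an entity or an event ("either" kind)
prefers the event reading: in "H2AX methylation was diminished …" the
controlled argument is the methylation event, not the H2AX mention that an
optional compound hop could also reach. This operationalizes the
regulation/activation split: controlled event → regulation, controlled
entity → activation.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| KB namespace priority | uniprot > interpro > chebi > hmdb > go > uaz | proteins before families, curated chemistry before metabolome dumps; ties in the sources are otherwise unordered |
| binding binarization | consecutive-pair chain (n−1 events) | minimal decomposition consistent with binary binding; `all_pairs` available |
| evidence counting | distinct papers, not mentions | redundancy across papers, not repetition within one, predicts correctness; `count = "mentions"` available |
| redundancy threshold k | 2 | the "seen at least twice" high-confidence setting |
| coref window | anaphor's sentence + 2 preceding | cross-sentence anaphora are the motivating cases; unbounded search hurts precision |
| negation lexicon | not, no, n't, never, cannot, without, unable, fail(s/ed), neither, nor | parity rule on cues governing the trigger, so "not unable to bind" is not negated |
| polarity lexicon | decrease/reduce/loss/knockdown/silencing/… | reversal words only; "increase"-class words never flip |

Sentence segmentation uses terminal punctuation plus a configurable
abbreviation blocklist ("Fig.", "et al.", …) — no published algorithm
exists to follow, so the splitter is deliberately simple and the
CoNLL-U path bypasses it entirely.

## The synthetic gold corpus

`generate_fixture_corpus()` emits, for every requested variation × event
type, a sentence *together with its dependency tree and gold annotations*,
plus special cases: coordination ("Smurf1 and Smurf2 degrade and
ubiquitinate RhoA" → 2 simple events under 2×2 regulations), polarity,
negation, activation, three binding constructions, translocation with
source/destination, a cross-sentence coreference pair, and the
relative-plus-passive combination. Entity pairs are sampled from a fixed
protein inventory under the given seed; output is byte-identical across
runs with the same seed.

Carrying gold parses is a deliberate decoupling: it isolates the rule
engine's correctness from parser quality, which in production accounts
for a substantial share of misses and precision errors. Consequently a
green corpus run establishes that the *templates* cover the stated
constructions on *correct* trees — it says nothing about robustness to
parser noise, unseen trigger vocabulary, or tokenization damage in real
articles, and the hand-built trees follow one convention (UD-style labels,
multi-token names headed by their last token) that a live parser may not
share. The per-label trigger lexicons are seeded from the event names and
standard biochemical verbs and are config-extensible; they are not an
exhaustive vocabulary.

A small static fixture set (`inst/extdata/fixtures/`) carries the ten
variation sentences verbatim with hand-built trees, the polarity sentence,
and three coreference documents; the coreference passages are trimmed to
the clause carrying the anaphoric construction. The scorer's approximate
mode matches trigger spans by overlap and nested arguments by recursive
equivalence; for regulations/activations it matches on label and
arguments only (two extraction routes can justify different trigger
tokens for the same regulation); strict mode requires exact spans
throughout, so strict F1 ≤ approximate F1 by construction.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open at document level (standoff
  convention); token indices are 1-based, matching CoNLL-U IDs.
* Duplicate simple-event matches merge on (label, trigger token, themes),
  pooling optional site/source/destination and union-ing causes;
  regulations deduplicate on (sign, controller, controlled).
* Empty text segments to an empty span list; an empty KB yields an empty
  index; a single-participant binding is skipped with a warning;
  `filter_redundancy(k < 1)` is a parameter error; precision over zero
  predictions is reported as `NA` (undefined), with F1 = 0 only when both
  precision and recall are defined and zero.
* Nesting is acyclic by construction: a regulation is rejected if its
  controller appears in the controlled event's argument closure.
* Coreference re-extraction iterates to a fixpoint (≤ 3 rounds needed in
  practice; the loop is bounded).

## Known limitations

* Dictionary NER cannot disambiguate names shared across namespaces — the
  synthetic KB deliberately avoids the gene symbol CAMP for the LL-37
  peptide because it collides with the chemical cAMP; real KBs contain
  thousands of such collisions and would need context models.
* No statistical tagger is included (the pluggable provider contract is
  the extension point); no fuzzy matching, no species disambiguation, no
  hedging detection, no gene-expression events — all stated non-goals.
* Polarity flips the event whose trigger–argument path carries the cue;
  reversal verbs buried inside a controlled clause flip that inner event's
  wrapper, not the outermost one. The alternative (outermost-only) reading
  would differ for doubly nested contrasts, which the fixtures do not
  exercise.
* Evidence aggregation keys on grounding ids; two mentions grounded to
  different ids for the same protein (synonym gaps) produce separate
  edges.

## Reproducing the acceptance report

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The report recomputes, from the installed package: the grammar inventory
totals (154 / 122 / 32; 95 syntax, 59 surface), approximate-mode F1,
precision and recall on the generated corpus and the verbatim fixtures
(1.0 — the grammar and corpus are co-designed, so anything less is a
bug), the polarity flip indicator, the coordination cross-product counts
(2 simple events, 4 regulations), the number of coreference-licensed
additional events (3), and redundancy-filter / prior-merge counts on a
three-paper synthetic corpus. No published headline number is restated:
those depend on external corpora and expert judgment and are out of desk
scale by design.
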