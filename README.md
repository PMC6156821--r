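# litsignal

Rule-based machine reading for molecular signaling: `litsignal` reads
biomedical text (or gold CoNLL-U parses) and extracts grounded biochemical
events — post-translational modifications, binding, hydrolysis,
translocation, and the signed regulations/activations nested over them —
then assembles the events into an evidence-counted interaction network
that can be filtered for redundancy and merged with a curated prior
network in SIF format.

It is written for computational biologists who want literature-derived
pathway fragments as a *prior* for downstream network analyses, and for
NLP researchers who want a compact, fully interpretable event-extraction
cascade whose every decision is a named rule.

## The model in brief

Extraction is a cascade of parameterized rule templates in two dialects:
dependency-tree patterns (per-role labeled paths from a lexicon-matched
trigger token) and linear surface patterns. One template encodes one
syntactic variation — declarative, passive, three nominalizations,
subject/object relatives, appositions, paraphrastic causatives — and is
instantiated per event type from a trigger lexicon, so ten variations
cover dozens of event types. The shipped grammar is exactly **154
templates** (95 syntax + 59 surface; 32 entity-side + 122 event-side).

Nested events are extracted bottom-up: simple events first
(phosphorylation(theme), binding(A,B), …), then controllers
(`positive_regulation(controller, controlled)`); a controlled *event*
makes a regulation, a controlled *entity* an activation. The final sign
is `base sign × (−1)^(reversal cues)` along the trigger–argument
dependency path ("**decreased** PTPN13 expression enhances EphrinB1
phosphorylation" is a *negative* regulation). Deterministic coreference
sieves (exact string → mutant alias → event label → type-compatible
nearest antecedent) resolve "this protein" / "this binding" and re-run
extraction. Assembly maps events to
`controls_state_change(subtype, sign)`, `controls_activity` and
`in_complex_with` edges, counts evidence per *paper*, and keeps edges
seen in ≥ k papers (default 2) as a high-confidence subset.

## Worked example

```r
library(litsignal)

conllu <- system.file("extdata", "fixtures", "verbatim.conllu",
                      package = "litsignal")
docs <- read_conllu(conllu)                    # gold-parsed documents
names(docs) <- sapply(docs, `[[`, "doc_id")

rules <- compile_grammar(default_grammar(), default_lexicons())
ex <- extract_document(docs[["t2-declarative"]], rules = rules)
# sentence: "Smurf1 and Smurf2 degrade and ubiquitinate RhoA ."
```

The coordinated triggers and causes expand to their full cross-product —
two simple events, each under two positive regulations:

```
E1  hydrolysis           trigger=degrade       theme=T3
E2  ubiquitination       trigger=ubiquitinate  theme=T3
E3  positive_regulation  trigger=degrade       controller=T1  controlled=E1
E4  positive_regulation  trigger=degrade       controller=T2  controlled=E1
E5  positive_regulation  trigger=ubiquitinate  controller=T1  controlled=E2
E6  positive_regulation  trigger=ubiquitinate  controller=T2  controlled=E2
```

(T1 = Smurf1, T2 = Smurf2, T3 = RhoA.) Normalizing yields directed,
grounded edges — controller → theme, typed by the controlled reaction:

```r
normalize_interactions(ex)[, c("source", "relation", "subtype", "sign", "target")]
#>           source              relation        subtype sign         target
#> 1 uniprot:Q9HCE7 controls_state_change     hydrolysis    1 uniprot:P61586
#> 2 uniprot:Q9HAU4 controls_state_change     hydrolysis    1 uniprot:P61586
#> 3 uniprot:Q9HCE7 controls_state_change ubiquitination    1 uniprot:P61586
#> 4 uniprot:Q9HAU4 controls_state_change ubiquitination    1 uniprot:P61586
```

Smurf1 (Q9HCE7) and Smurf2 (Q9HAU4) each ubiquitinate and degrade RhoA
(P61586), with sign +1 and one supporting paper each
(`aggregate_evidence()` counts distinct documents; `filter_redundancy(k)`
then keeps the ≥ k-paper subset, and `merge_prior()` unions the result
with a curated SIF network, reporting the overlap).

Plain text works too: `read_text()` segments and tokenizes, and
`annotate()` fills parses through any parser provider you register
(a function from token vectors to POS/lemma/head/label).

## Synthetic gold corpus and scoring

```r
corpus <- generate_fixture_corpus(seed = 7)     # sentences + trees + gold
rep <- score_events(extract_document(corpus[[1]]$doc, rules = rules),
                    corpus[[1]]$gold)
rep$f1                                          # 1 on every generated case
```

The generator emits every syntactic variation × event type with gold
dependency trees (no live parser needed), plus coordination, polarity,
negation, binding, translocation and coreference cases; the scorer
supports the approximate (span-overlap, recursive-argument) and strict
modes.

## Command line

```sh
Rscript -e 'litsignal::litsignal_cli()' extract  --conllu doc.conllu --out events.json
Rscript -e 'litsignal::litsignal_cli()' fixtures --seed 7 --out corpus/
Rscript -e 'litsignal::litsignal_cli()' score    --pred pred.json --gold gold.json
Rscript -e 'litsignal::litsignal_cli()' merge    --prior prior.sif --extracted ex.sif --out merged.sif
```

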