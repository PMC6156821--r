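extract_all <- function(doc) {
  extract_document(doc, kb = test_kb(), rules = test_rules(),
                   lexicons = test_lexicons())
}

test_that("simple events cover PTMs, hydrolysis, binding with held causes", {
  docs <- verbatim_docs()
  ex <- extract_all(docs[["t2-passive"]])
  labs <- sort(vapply(ex$events, `[[`, "", "label"))
  expect_identical(sum(labs == "ubiquitination"), 1L)
  expect_identical(sum(labs == "hydrolysis"), 1L)
  expect_identical(sum(labs == "positive_regulation"), 4L)
  ex <- extract_all(docs[["t2-subject-apposition"]])
  bind <- Filter(function(e) e$label == "binding", ex$events)
  expect_length(bind, 1)
  th <- vapply(bind[[1]]$args$theme, function(id) ex$mentions[[id]]$text, "")
  expect_setequal(th, c("A20", "ABIN"))
  # mentions but no triggers -> no events
  s <- ls_sentence(tokenize("MEK1 and ERK and RhoA"), text = "x")
  d <- annotate(ls_document("d", list(s)), function(tk) list(
    pos = c("PROPN", "CCONJ", "PROPN", "CCONJ", "PROPN"),
    lemma = tolower(tk), head = c(0, 3, 1, 5, 3),
    label = c("root", "cc", "conj", "cc", "conj")))
  expect_length(extract_all(d)$events, 0)
})

test_that("nested events distinguish regulations from activations", {
  docs <- verbatim_docs()
  # paraphrastic causative: controller over a hydrolysis event
  ex <- extract_all(docs[["t2-paraphrastic-causative"]])
  reg <- Filter(function(e) e$label == "positive_regulation", ex$events)
  expect_length(reg, 1)
  expect_identical(ex$mentions[[reg[[1]]$args$controller]]$text, "Smurf1")
  inner <- ex$events[[reg[[1]]$args$controlled]]
  expect_identical(inner$label, "hydrolysis")
  expect_identical(ex$mentions[[inner$args$theme[[1]]]]$text, "RhoA")
  # control verb over an entity becomes an activation
  ex <- extract_all(docs[["t2-combination"]])
  act <- Filter(function(e) e$label == "positive_activation", ex$events)
  expect_length(act, 1)
  expect_identical(ex$mentions[[act[[1]]$args$controlled]]$text, "MEK")
  # nesting is acyclic: no event reachable from its own arguments
  for (ex in test_corpus_preds()) {
    for (id in names(ex$events))
      expect_false(id %in% litsignal:::event_closure(id, ex$events))
  }
})

test_that("coordination expansion equals the cross-product oracle", {
  docs <- verbatim_docs()
  ex <- extract_all(docs[["t2-declarative"]])
  simple <- Filter(function(e) e$label %in% c("hydrolysis", "ubiquitination"),
                   ex$events)
  regs <- Filter(function(e) e$label == "positive_regulation", ex$events)
  # oracle: |triggers| x |causes| x |themes| = 2 x 2 x 1
  expect_length(simple, 2)
  expect_length(regs, 2 * 2 * 1)
  # three coordinated themes, one trigger -> three matches
  s <- litsignal:::sent_build(
    c("MEK1", "phosphorylates", "ERK", ",", "RhoA", "and", "p53", "."),
    c("PROPN", "VERB", "PROPN", "PUNCT", "PROPN", "CCONJ", "PROPN", "PUNCT"),
    c(2, 0, 2, 3, 3, 7, 3, 2),
    c("nsubj", "root", "obj", "punct", "conj", "cc", "conj", "punct"))
  d <- ls_document("d", list(s))
  ex <- extract_all(d)
  ph <- Filter(function(e) e$label == "phosphorylation", ex$events)
  expect_length(ph, 3)
  # no conj edges -> identity
  m <- list(rule = "x", category = "simple_event",
            event_label = "phosphorylation", trigger_tok = 2L,
            trigger = c(2L, 2L),
            bindings = list(theme = list(kind = "mention", ref = 2L)))
  s0 <- toy_sentence()
  out <- expand_coordinations(m, s0, toy_mentions(s0),
                              lexicons = test_lexicons())
  expect_length(out, 1)
  expect_identical(out[[1]]$trigger_tok, m$trigger_tok)
})

test_that("binarize_binding produces binary chains", {
  expect_identical(binarize_binding(c("A", "B")), list(c("A", "B")))
  # oracle: n-1 chain over text order
  expect_identical(binarize_binding(c("A", "B", "C")),
                   list(c("A", "B"), c("B", "C")))
  # all-pairs mode yields C(3,2) = 3
  expect_length(binarize_binding(c("A", "B", "C"), mode = "all_pairs"), 3)
  expect_warning(out <- binarize_binding("A"), "single participant")
  expect_length(out, 0)
})

test_that("negation detection uses cue parity on the governing path", {
  docs <- verbatim_docs()
  ex <- extract_all(docs[["coref-ll37"]])
  reg <- Filter(function(e) e$label == "negative_regulation", ex$events)
  expect_length(reg, 1)
  expect_true(reg[[1]]$negated)
  # plain declarative is not negated
  ex <- extract_all(docs[["t2-paraphrastic-causative"]])
  expect_true(all(!vapply(ex$events, `[[`, TRUE, "negated")))
  # double negation cancels: "not unable to bind" (oracle: cue-count parity)
  s <- litsignal:::sent_build(
    c("MEK1", "is", "not", "unable", "to", "bind", "ERK", "."),
    c("PROPN", "AUX", "PART", "ADJ", "PART", "VERB", "PROPN", "PUNCT"),
    c(4, 4, 4, 0, 6, 4, 6, 4),
    c("nsubj", "cop", "advmod", "root", "mark", "xcomp", "obj", "punct"))
  ev <- list(trigger_start = 6L, sent = 1L)
  expect_false(detect_negation(ev, s, test_lexicons()$negation))
  # single cue negates
  s1 <- litsignal:::sent_build(
    c("MEK1", "does", "not", "bind", "ERK", "."),
    c("PROPN", "AUX", "PART", "VERB", "PROPN", "PUNCT"),
    c(4, 4, 4, 0, 4, 4),
    c("nsubj", "aux", "advmod", "root", "obj", "punct"))
  expect_true(detect_negation(list(trigger_start = 4L, sent = 1L), s1,
                              test_lexicons()$negation))
})

test_that("every extracted trigger belongs to the lexicon of its label", {
  lex <- test_lexicons()$triggers
  reg_forms <- c(lex$positive_regulation$form, lex$negative_regulation$form)
  for (ex in test_corpus_preds()) {
    for (e in ex$events) {
      if (e$rule == "cause-argument") next  # trigger comes from the inner event
      forms <- if (e$category %in% litsignal:::REGULATION_CATEGORIES)
        reg_forms   # polarity flips may change the label, not the trigger
      else lex[[e$label]]$form
      expect_true(tolower(e$trigger_text) %in% forms,
                  info = paste(e$label, e$trigger_text))
    }
  }
})
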