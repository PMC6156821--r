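coref_extract <- function(id, resolve = TRUE) {
  extract_document(verbatim_docs()[[id]], kb = test_kb(), rules = test_rules(),
                   lexicons = test_lexicons(), resolve_coref = resolve)
}

test_that("find_anaphors detects entity, mutant and event anaphors", {
  docs <- verbatim_docs()
  ex <- coref_extract("coref-hp1gamma", resolve = FALSE)
  an <- find_anaphors(docs[["coref-hp1gamma"]], ex)
  expect_length(an, 1)
  expect_identical(an[[1]]$kind, "entity")
  expect_identical(an[[1]]$type, "gene_or_gene_product")
  ex <- coref_extract("coref-ll37", resolve = FALSE)
  an <- find_anaphors(docs[["coref-ll37"]], ex)
  expect_identical(an[[1]]$kind, "event")
  expect_identical(an[[1]]$label, "binding")
  # no demonstratives/definites -> no candidates
  ex <- coref_extract("t2-declarative", resolve = FALSE)
  expect_length(find_anaphors(docs[["t2-declarative"]], ex), 0)
})

test_that("sieves resolve in precision order; unresolved anaphors are dropped", {
  docs <- verbatim_docs()
  ex <- coref_extract("coref-k134a", resolve = FALSE)
  an <- find_anaphors(docs[["coref-k134a"]], ex)
  links <- apply_sieves(docs[["coref-k134a"]], ex, an)
  expect_length(links, 1)
  expect_identical(links[[1]]$sieve, "mutant_alias")
  expect_identical(ex$mentions[[links[[1]]$antecedent_id]]$text, "H2AX")
  ex <- coref_extract("coref-ll37", resolve = FALSE)
  an <- find_anaphors(docs[["coref-ll37"]], ex)
  links <- apply_sieves(docs[["coref-ll37"]], ex, an)
  expect_identical(links[[1]]$sieve, "event_label")
  expect_identical(ex$events[[links[[1]]$antecedent_id]]$label, "binding")
  # an anaphor with no compatible antecedent stays unresolved
  s <- litsignal:::sent_build(
    c("This", "protein", "is", "important", "."),
    c("DET", "NOUN", "AUX", "ADJ", "PUNCT"),
    c(2, 4, 4, 0, 4), c("det", "nsubj", "cop", "root", "punct"))
  d <- ls_document("lonely", list(s))
  ex0 <- extract_document(d, kb = test_kb(), rules = test_rules(),
                          lexicons = test_lexicons(), resolve_coref = FALSE)
  an0 <- find_anaphors(d, ex0)
  expect_length(an0, 1)
  expect_length(apply_sieves(d, ex0, an0), 0)
})

test_that("resolution licenses the additional cross-sentence events", {
  # phosphorylation of "this protein" at S83 -> phosphorylation(HP1-gamma, S83)
  ex <- coref_extract("coref-hp1gamma")
  new <- Filter(function(e) isTRUE(e$coref), ex$events)
  expect_length(new, 1)
  ev <- new[[1]]
  expect_identical(ev$label, "phosphorylation")
  theme <- ex$mentions[[ev$args$theme[[1]]]]
  expect_identical(theme$groundings[[1]]$identifier, "Q13185")
  expect_identical(ex$mentions[[ev$args$site]]$text, "S83")
  # the K134A mutant -> negative regulation of methylation by the mutant
  ex <- coref_extract("coref-k134a")
  reg <- Filter(function(e) e$label == "negative_regulation", ex$events)
  expect_length(reg, 1)
  ctrl <- ex$mentions[[reg[[1]]$args$controller]]
  expect_identical(ctrl$groundings[[1]]$identifier, "P16104")
  expect_identical(ex$events[[reg[[1]]$args$controlled]]$label, "methylation")
  # unresolved anaphor -> no event emitted
  s <- litsignal:::sent_build(
    c("MEK1", "phosphorylates", "this", "protein", "."),
    c("PROPN", "VERB", "DET", "NOUN", "PUNCT"),
    c(2, 0, 4, 2, 2), c("nsubj", "root", "det", "obj", "punct"))
  ex0 <- extract_document(ls_document("d", list(s)), kb = test_kb(),
                          rules = test_rules(), lexicons = test_lexicons())
  expect_length(Filter(function(e) e$label == "phosphorylation", ex0$events), 0)
})

test_that("resolution is deterministic and reaches a fixpoint", {
  ex1 <- coref_extract("coref-hp1gamma")
  ex2 <- coref_extract("coref-hp1gamma")
  expect_identical(lapply(ex1$events, litsignal:::event_key),
                   lapply(ex2$events, litsignal:::event_key))
  # re-running resolution on the resolved document adds no further events
  doc <- verbatim_docs()[["coref-hp1gamma"]]
  an <- find_anaphors(doc, ex1)
  links <- apply_sieves(doc, ex1, an)
  ex3 <- resolve_and_reextract(doc, ex1, links, rules = test_rules(),
                               lexicons = test_lexicons())
  expect_identical(sort(vapply(ex3$events, litsignal:::event_key, "")),
                   sort(vapply(ex1$events, litsignal:::event_key, "")))
})

test_that("disabling a later sieve never changes earlier links", {
  docs <- verbatim_docs()
  full <- c("exact_match", "mutant_alias", "event_label", "generic_type")
  for (id in c("coref-hp1gamma", "coref-k134a", "coref-ll37")) {
    ex <- coref_extract(id, resolve = FALSE)
    an <- find_anaphors(docs[[id]], ex)
    all_links <- apply_sieves(docs[[id]], ex, an, sieves = full)
    for (cut in seq_along(full)) {
      sub <- full[seq_len(cut)]
      sub_links <- apply_sieves(docs[[id]], ex, an, sieves = sub)
      kept <- Filter(function(l) l$sieve %in% sub, all_links)
      expect_identical(
        lapply(sub_links, function(l) c(l$sieve, l$antecedent_id)),
        lapply(kept, function(l) c(l$sieve, l$antecedent_id)))
    }
  }
})
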