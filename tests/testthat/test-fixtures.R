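test_that("the generator is deterministic and validates its config", {
  a <- generate_fixture_corpus(variations = "declarative",
                               events = c("phosphorylation", "methylation"),
                               include = character(0), seed = 11)
  b <- generate_fixture_corpus(variations = "declarative",
                               events = c("phosphorylation", "methylation"),
                               include = character(0), seed = 11)
  expect_identical(unlist(lapply(a, function(x) write_conllu(x$doc))),
                   unlist(lapply(b, function(x) write_conllu(x$doc))))
  # different seed, different entity sampling (same structure)
  c2 <- generate_fixture_corpus(variations = "declarative",
                                events = "phosphorylation",
                                include = character(0), seed = 12)
  expect_identical(names(a)[1], "syn-declarative-phosphorylation")
  expect_error(generate_fixture_corpus(variations = "exclamative"),
               "unknown variation")
  # every document carries a valid tree and gold arguments inside bounds
  for (x in a) {
    for (s in x$doc$sentences) expect_true(validate_sentence(s))
    for (e in x$gold$events)
      for (refs in e$args) for (r in refs)
        if (r$kind == "entity")
          expect_true(all(r$span >= 1 &
            r$span <= nrow(x$doc$sentences[[r$sent]]$tokens)))
  }
})

test_that("the scorer handles perfect, empty and partial predictions", {
  corpus <- test_corpus()
  golds <- lapply(corpus, `[[`, "gold")
  # score(gold, gold) is perfect in both modes
  for (mode in c("approximate", "strict")) {
    rep <- score_events(golds[[1]], golds[[1]], mode = mode)
    expect_identical(rep$precision, 1)
    expect_identical(rep$recall, 1)
    expect_identical(rep$f1, 1)
  }
  # empty predictions vs nonempty gold: P undefined, R = 0
  empty <- list(doc_id = golds[[1]]$doc_id, events = list())
  rep <- score_events(empty, golds[[1]])
  expect_true(is.na(rep$precision))
  expect_identical(rep$recall, 0)
  # 3 gold, 2 correct + 1 spurious -> P = R = 2/3 (oracle: by hand)
  g3 <- list(doc_id = "d", events = golds[["syn-coordination"]]$events[1:3])
  spurious <- g3$events[[1]]
  spurious$label <- "acetylation"
  p3 <- list(doc_id = "d", events = c(g3$events[1:2], list(spurious)))
  rep <- score_events(p3, g3)
  expect_equal(rep$precision, 2 / 3)
  expect_equal(rep$recall, 2 / 3)
  # doc-id mismatch is an error
  expect_error(score_events(list(doc_id = "x", events = list()), g3),
               "mismatch")
})

test_that("strict-mode F1 never exceeds approximate-mode F1", {
  preds <- test_corpus_preds()
  golds <- lapply(test_corpus(), `[[`, "gold")
  # perturb some predictions by shifting trigger spans where possible
  f1s <- score_events(preds, golds, "strict")$f1
  f1a <- score_events(preds, golds, "approximate")$f1
  expect_lte(f1s, f1a)
  # and on a hand-perturbed case: widened trigger still overlaps
  g <- golds[["syn-declarative-phosphorylation"]]
  p <- g
  p$events[[1]]$trigger <- p$events[[1]]$trigger + c(0L, 1L)
  expect_identical(score_events(p, g, "approximate")$f1, 1)
  expect_lt(score_events(p, g, "strict")$f1, 1)
})

test_that("per-label breakdown accounts for every decision", {
  preds <- test_corpus_preds()[1:20]
  golds <- lapply(test_corpus(), `[[`, "gold")[1:20]
  rep <- score_events(preds, golds)
  expect_identical(sum(rep$per_label$tp), rep$tp)
  expect_identical(sum(rep$per_label$fp), rep$fp)
  expect_identical(sum(rep$per_label$fn), rep$fn)
})

test_that("written corpora round trip through CoNLL-U and JSON", {
  corpus <- generate_fixture_corpus(variations = "passive",
                                    events = "ubiquitination",
                                    include = "negation", seed = 3)
  dir <- withr::local_tempdir()
  write_fixture_corpus(corpus, dir)
  docs <- read_conllu(file.path(dir, "corpus.conllu"))
  expect_length(docs, length(corpus))
  golds <- read_gold_json(file.path(dir, "gold.json"))
  expect_identical(vapply(golds, `[[`, "", "doc_id"), names(corpus))
  # extraction on the re-read documents still matches gold
  preds <- lapply(docs, extract_document, kb = test_kb(),
                  rules = test_rules(), lexicons = test_lexicons())
  names(preds) <- vapply(docs, `[[`, "", "doc_id")
  names(golds) <- vapply(golds, `[[`, "", "doc_id")
  expect_identical(score_events(preds, golds)$f1, 1)
})
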