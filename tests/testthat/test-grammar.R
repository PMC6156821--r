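test_that("compile_template instantiates rules and fails fast on bad input", {
  lex <- test_lexicons()
  decl <- Filter(function(t) t$name == "se-declarative", default_grammar())[[1]]
  rule <- compile_template(decl, lex$triggers, "phosphorylation")
  expect_s3_class(rule, "ls_rule")
  m <- match_dependency_pattern(rule, toy_sentence(), toy_mentions())
  expect_length(m, 1)
  expect_identical(m[[1]]$trigger_tok, 2L)
  expect_identical(m[[1]]$bindings$theme$kind, "mention")
  # empty lexicon -> compile error
  expect_error(compile_template(decl, list(), "phosphorylation"), "empty")
  # unknown dependency label -> compile error (at load, not at match)
  bad <- rule_template("bad", "simple_event", "syntax", trigger_pos = "verb",
                       roles = list(theme = list(path = ">frobnicate",
                                                 required = TRUE)))
  expect_error(compile_template(bad, lex$triggers, "phosphorylation"),
               "unknown dependency label")
})

test_that("grammar inventory reproduces the shipped template counts", {
  inv <- grammar_inventory()
  row <- function(cat) inv[inv$category == cat, ]
  expect_identical(unlist(row("entity")[, 2:4], use.names = FALSE), c(0L, 15L, 15L))
  expect_identical(unlist(row("hydrolysis")[, 2:4], use.names = FALSE), c(8L, 2L, 10L))
  expect_identical(unlist(row("binding")[, 2:4], use.names = FALSE), c(30L, 7L, 37L))
  expect_identical(row("total")$total, 154L)
  expect_identical(row("total_events")$total, 122L)
  # every template name is unique and every declared role is in the pattern
  g <- default_grammar()
  expect_identical(anyDuplicated(vapply(g, `[[`, "", "name")), 0L)
})

test_that("dependency matcher equals the recursive path-enumeration oracle", {
  rules <- Filter(function(r) r$dialect == "syntax", test_rules())
  corpus <- test_corpus()
  checked <- 0L
  for (nm in names(corpus)[seq(1, length(corpus), by = 11)]) {
    for (s in corpus[[nm]]$doc$sentences) {
      if (nrow(s$tokens) > 25) next
      for (r in rules[seq(1, length(rules), by = 7)]) {
        trig <- which(litsignal:::token_matches_lex(
          s$tokens, seq_len(nrow(s$tokens)), r$trigger_forms))
        for (t in trig) for (role in r$roles) {
          got <- sort(litsignal:::walk_path(s, t, role$steps))
          want <- oracle_walk(s, t, role$steps)
          expect_identical(got, want)
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 20)
})

test_that("rule matching is a pure, order-independent function", {
  s <- verbatim_docs()[["t2-declarative"]]$sentences[[1]]
  ms <- toy_mentions(s)
  rules <- Filter(function(r) r$dialect == "syntax" &&
                    r$category %in% litsignal:::SIMPLE_CATEGORIES, test_rules())
  run <- function(rr) {
    out <- unlist(lapply(rr, match_dependency_pattern, sentence = s,
                         mentions = ms), recursive = FALSE)
    out[order(vapply(out, function(m) paste(m$rule, m$event_label,
                                            m$trigger_tok), ""))]
  }
  expect_identical(run(rules), run(rev(rules)))
})

test_that("surface patterns match modifications, mutants and empty input", {
  lex <- test_lexicons()
  rules <- test_rules()
  byname <- function(nm) Filter(function(r) r$name == nm, rules)[[1]]
  s <- ls_sentence(tokenize("phospho - p38 binds the K134A mutant"), text = "x")
  ms <- toy_mentions(s)
  mod <- match_surface_pattern(byname("mod-ptm-prefix-dash"), s, ms)
  expect_length(mod, 1)
  expect_identical(mod[[1]]$bindings$target$kind, "mention")
  mut <- match_surface_pattern(byname("mut-code-anaphoric"), s, ms)
  expect_length(mut, 1)
  expect_identical(s$tokens$text[mut[[1]]$bindings$code$ref], "K134A")
  # a sentence without tokens matches nothing
  empty <- ls_sentence(tokenize(" . "), text = " . ")
  expect_length(match_surface_pattern(byname("mut-code-anaphoric"),
                                      empty, list()), 0)
})

test_that("grammar YAML round trip preserves the inventory", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_grammar(default_grammar(), path)
  g2 <- load_grammar(path)
  expect_identical(grammar_inventory(g2), grammar_inventory())
  expect_identical(vapply(g2, `[[`, "", "name"),
                   vapply(default_grammar(), `[[`, "", "name"))
  # a reloaded grammar compiles to the same number of rules
  expect_length(compile_grammar(g2, test_lexicons()), length(test_rules()))
  # the YAML artifact shipped with the package matches the built-in grammar
  shipped <- load_grammar(system.file("extdata", "grammar", "grammar.yaml",
                                      package = "litsignal"))
  expect_identical(vapply(shipped, `[[`, "", "name"),
                   vapply(default_grammar(), `[[`, "", "name"))
  expect_identical(grammar_inventory(shipped), grammar_inventory())
})
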