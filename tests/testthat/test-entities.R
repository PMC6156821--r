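test_that("load_kb builds an index with exact and case-insensitive lookup", {
  kb <- load_kb(c(
    "uniprot\tQ02750\tMAP2K1\tMEK1|MAP kinase kinase 1\tgene_or_gene_product"))
  hit <- kb_lookup(kb, "MEK1")
  expect_length(hit, 1)
  expect_identical(hit[[1]]$identifier, "Q02750")
  expect_length(kb_lookup(kb, "mek1"), 1)        # case-insensitive
  expect_length(kb_lookup(kb, "mek1", exact = TRUE), 0)
  expect_length(load_kb(character(0))$entries, 0)
  # a synonym shared by two entries returns both (oracle: linear scan)
  kb2 <- load_kb(c(
    "uniprot\tQ16539\tMAPK14\tp38\tgene_or_gene_product",
    "interpro\tIPR003527\tMAPK family\tp38\tfamily"))
  both <- kb_lookup(kb2, "p38")
  expect_length(both, 2)
  scan <- Filter(function(e) "p38" %in% c(e$canonical, e$synonyms), kb2$entries)
  expect_identical(length(both), length(scan))
  # conflicting entity types for one identifier are a load error
  expect_error(load_kb(c(
    "uniprot\tQ1\tX\t\tgene_or_gene_product",
    "uniprot\tQ1\tX\t\tfamily")), "conflicting")
})

test_that("match_entities equals the brute-force n-gram oracle", {
  kb <- test_kb()
  texts <- c("MEK1 phosphorylates ERK",
             "wild type EHR was measured",
             "HP1 - gamma binds histone H2AX in the nucleus",
             "cyclic AMP and cAMP and MAP kinase kinase 1",
             "no entities here at all")
  for (txt in texts) {
    s <- ls_sentence(tokenize(txt), text = txt)
    got <- match_entities(s, kb)
    want <- oracle_ngram_entities(s, kb)
    expect_identical(length(got), length(want), info = txt)
    for (i in seq_along(got)) {
      expect_identical(got[[i]]$tok_start, unname(want[[i]]["start"]), info = txt)
      expect_identical(got[[i]]$tok_end, unname(want[[i]]["end"]), info = txt)
    }
  }
  # mentions never overlap
  s <- ls_sentence(tokenize("MAP kinase kinase 1 binds MAP kinase kinase 1"),
                   text = "x")
  ms <- match_entities(s, kb)
  toks <- unlist(lapply(ms, function(m) m$tok_start:m$tok_end))
  expect_identical(anyDuplicated(toks), 0L)
})

test_that("site tokens are pattern-matched even when absent from the KB", {
  s <- ls_sentence(tokenize("phosphorylation at Ser37 and S83 but not K134A"),
                   text = "x")
  ms <- match_entities(s, test_kb())
  sites <- Filter(function(m) m$type == "site", ms)
  expect_identical(vapply(sites, `[[`, "", "text"), c("Ser37", "S83"))
})

test_that("ground orders namespaces by priority and is idempotent", {
  kb <- test_kb()
  s <- ls_sentence(tokenize("MEK1 and cAMP"), text = "x")
  ms <- lapply(match_entities(s, kb), ground)
  expect_identical(grounding_id(ms[[1]]), "uniprot:Q02750")
  # cAMP is in both ChEBI and HMDB; ChEBI comes first (oracle: priority sort)
  camp <- ms[[2]]
  ns <- vapply(camp$groundings, `[[`, "", "namespace")
  expect_identical(ns[1], "chebi")
  expect_true("hmdb" %in% ns)
  expect_identical(ground(camp), camp)   # idempotent
  # pattern-only mentions get a deterministic local id
  s2 <- ls_sentence(tokenize("Ser37"), text = "Ser37")
  m2 <- ground(match_entities(s2, kb)[[1]])
  expect_identical(m2$groundings[[1]]$namespace, "uaz")
  expect_identical(grounding_id(m2), grounding_id(ground(m2)))
})

test_that("grounding is stable under synonym order permutation", {
  rows <- function(syn) c(
    sprintf("uniprot\tQ02750\tMAP2K1\t%s\tgene_or_gene_product", syn),
    "chebi\tCHEBI:17489\tcAMP\tcyclic AMP\tsimple_chemical")
  kb1 <- load_kb(rows("MEK1|MEK"))
  kb2 <- load_kb(rows("MEK|MEK1"))
  s <- ls_sentence(tokenize("MEK1"), text = "MEK1")
  g1 <- ground(match_entities(s, kb1)[[1]])
  g2 <- ground(match_entities(s, kb2)[[1]])
  expect_identical(g1$groundings, g2$groundings)
})

test_that("attach_states detects wild-type, mutant and PTM states", {
  kb <- test_kb()
  attach1 <- function(txt) {
    s <- ls_sentence(tokenize(txt), text = txt)
    attach_states(s, match_entities(s, kb))
  }
  ms <- attach1("wild type EHR")
  ehr <- Filter(function(m) m$text == "EHR", ms)[[1]]
  expect_identical(ehr$mods[[1]]$kind, "WildType")
  ms <- attach1("recombinant H2AX - K134A")
  h2 <- Filter(function(m) grepl("H2AX", m$text), ms)[[1]]
  expect_identical(h2$mods[[1]]$kind, "Mutant")
  expect_identical(h2$mods[[1]]$subtype, "K134A")
  ms <- attach1("phospho - p38 and phosphorylated ERK")
  mods <- lapply(ms, `[[`, "mods")
  expect_true(all(vapply(mods, function(m) m[[1]]$kind == "PTM", TRUE)))
  expect_identical(mods[[1]][[1]]$subtype, "phosphorylation")
  # bare mention carries no modifications
  ms <- attach1("ERK binds MEK1")
  expect_true(all(vapply(ms, function(m) length(m$mods) == 0, TRUE)))
})
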