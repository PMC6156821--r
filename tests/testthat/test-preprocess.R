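test_that("segment_sentences splits on terminal punctuation, not abbreviations", {
  expect_identical(nrow(segment_sentences("")), 0L)
  spans <- segment_sentences(
    "RhoA is ubiquitinated. Smurf1 causes the degradation of RhoA.")
  expect_identical(nrow(spans), 2L)
  one <- segment_sentences(paste(
    "We measured transcription activation in the presence of cAMP,",
    "which is hydrolyzed by CRP."))
  expect_identical(nrow(one), 1L)
  # abbreviations with trailing periods do not split
  ab <- segment_sentences("See Fig. 2 for details. ERK et al. were studied.")
  expect_identical(nrow(ab), 2L)
  # spans are disjoint, ordered, and cover all non-whitespace characters
  txt <- "MEK1 phosphorylates ERK. KRAS activates p53! Is RhoA degraded?"
  sp <- segment_sentences(txt)
  expect_true(all(diff(sp$start) > 0))
  expect_true(all(sp$end[-nrow(sp)] <= sp$start[-1]))
  covered <- unlist(Map(seq, sp$start + 1L, sp$end))
  chars <- strsplit(txt, "")[[1]]
  ws <- grepl("\\s", chars)
  expect_true(all(which(!ws) %in% covered))
})

test_that("tokenize splits intra-word dashes and slashes, keeping offsets", {
  tk <- tokenize("GAP-mediated")
  expect_identical(tk$text, c("GAP", "-", "mediated"))
  expect_identical(tokenize("RhoA")$text, "RhoA")
  tk <- tokenize("H2AX-K134A binds DNA")
  expect_identical(tk$text[1:3], c("H2AX", "-", "K134A"))
  # oracle: offsets reconstruct the input exactly
  s <- "Dvl2/aPKC interaction increased (p = 3.5)"
  tk <- tokenize(s, sentence_offset = 100L)
  expect_identical(tk$text[1:3], c("Dvl2", "/", "aPKC"))
  for (i in seq_len(nrow(tk)))
    expect_identical(substr(s, tk$start[i] - 100L + 1L, tk$end[i] - 100L),
                     tk$text[i])
  expect_true("3.5" %in% tk$text)   # decimals stay whole
})

test_that("segment+tokenize are deterministic pure functions", {
  txt <- "MEK1 phosphorylates ERK. RhoA is degraded by Smurf1."
  expect_identical(segment_sentences(txt), segment_sentences(txt))
  expect_identical(tokenize(txt), tokenize(txt))
})

test_that("read_conllu parses documents and validates structure", {
  docs <- verbatim_docs()
  # oracle: independent count of `# newdoc` lines in the raw file
  raw <- readLines(system.file("extdata", "fixtures", "verbatim.conllu",
                               package = "litsignal"))
  expect_length(docs, sum(grepl("^# newdoc id =", raw)))
  nsent <- sum(vapply(docs, function(d) length(d$sentences), 0L))
  blocks <- sum(grepl("^1\t", raw))
  expect_identical(nsent, blocks)
  # minimal tree: single token with HEAD=0 gives one ROOT edge
  d <- read_conllu(c("1\tERK\terk\tPROPN\t_\t_\t0\troot\t_\t_", ""))
  expect_identical(nrow(d$sentences[[1]]$deps), 1L)
  expect_identical(d$sentences[[1]]$deps$head, 0L)
  # HEAD pointing at a nonexistent ID is a structural error
  expect_error(read_conllu(c("1\tERK\terk\tPROPN\t_\t_\t5\tdep\t_\t_", "")),
               "nonexistent")
  # malformed line names the line number
  expect_error(read_conllu(c("1\tERK\terk", "")), "line 1")
  # cyclic heads are rejected
  expect_error(read_conllu(c(
    "1\tA\ta\tPROPN\t_\t_\t2\tdep\t_\t_",
    "2\tB\tb\tPROPN\t_\t_\t1\tdep\t_\t_", "")), "ROOT|cycle")
})

test_that("CoNLL-U round trip preserves tokens, heads and labels", {
  docs <- verbatim_docs()
  lines <- write_conllu(docs)
  docs2 <- read_conllu(lines)
  expect_length(docs2, length(docs))
  for (i in seq_along(docs)) {
    for (j in seq_along(docs[[i]]$sentences)) {
      a <- docs[[i]]$sentences[[j]]
      b <- docs2[[i]]$sentences[[j]]
      expect_identical(a$tokens$text, b$tokens$text)
      expect_identical(a$tokens$start, b$tokens$start)
      expect_identical(a$deps, b$deps)
    }
  }
})

test_that("annotate fills annotations via the provider contract", {
  # stub provider returning a hand-built tree; pass-through fidelity
  words <- c("Smurf1", "causes", "the", "degradation", "of", "RhoA")
  doc <- ls_document("d1", list(ls_sentence(
    tokenize(paste(words, collapse = " ")),
    text = paste(words, collapse = " "))))
  stub <- function(tokens) list(
    pos = c("PROPN", "VERB", "DET", "NOUN", "ADP", "PROPN"),
    lemma = tolower(tokens),
    head = c(2, 0, 4, 2, 6, 4),
    label = c("nsubj", "root", "det", "obj", "case", "nmod:of"))
  out <- annotate(doc, stub)
  d <- out$sentences[[1]]$deps
  expect_identical(d$label[d$dep == 1], "nsubj")
  expect_identical(d$head[d$dep == 1], 2L)
  # idempotence: an already-annotated document is unchanged
  out2 <- annotate(out, function(...) stop("must not be called"))
  expect_identical(out, out2)
  # provider failure is contextualized with doc id and sentence index
  doc2 <- ls_document("doc-x", list(ls_sentence(tokenize("ERK binds MEK1"),
                                                text = "ERK binds MEK1")))
  expect_error(annotate(doc2, function(...) stop("boom")),
               "doc-x.*sentence 1")
})
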