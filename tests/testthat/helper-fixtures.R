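# Shared fixtures and independent oracles for the test suite. Expensive
# artifacts (compiled grammar, extracted corpus) are computed once per run.

.cache <- new.env(parent = emptyenv())

test_lexicons <- function() {
  if (is.null(.cache$lex)) .cache$lex <- default_lexicons()
  .cache$lex
}
test_rules <- function() {
  if (is.null(.cache$rules))
    .cache$rules <- compile_grammar(default_grammar(), test_lexicons())
  .cache$rules
}
test_kb <- function() {
  if (is.null(.cache$kb)) .cache$kb <- default_kb()
  .cache$kb
}

# generated corpus + predictions, computed once (used by several tests)
test_corpus <- function() {
  if (is.null(.cache$corpus)) .cache$corpus <- generate_fixture_corpus(seed = 7)
  .cache$corpus
}
test_corpus_preds <- function() {
  if (is.null(.cache$preds)) {
    .cache$preds <- lapply(test_corpus(), function(x)
      extract_document(x$doc, kb = test_kb(), rules = test_rules(),
                       lexicons = test_lexicons()))
  }
  .cache$preds
}

verbatim_docs <- function() {
  docs <- read_conllu(system.file("extdata", "fixtures", "verbatim.conllu",
                                  package = "litsignal"))
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  docs
}
verbatim_gold <- function() {
  g <- read_gold_json(system.file("extdata", "fixtures", "verbatim_gold.json",
                                  package = "litsignal"))
  names(g) <- vapply(g, `[[`, "", "doc_id")
  g
}

# a tiny annotated sentence: "MEK1 phosphorylates ERK ."
toy_sentence <- function() {
  litsignal:::sent_build(
    c("MEK1", "phosphorylates", "ERK", "."),
    c("PROPN", "VERB", "PROPN", "PUNCT"),
    c(2, 0, 2, 2), c("nsubj", "root", "obj", "punct"))
}

toy_mentions <- function(sentence = toy_sentence()) {
  ms <- match_entities(sentence, test_kb())
  ms <- lapply(ms, ground)
  for (i in seq_along(ms)) ms[[i]]$id <- sprintf("T%d", i)
  ms
}

# --- independent oracles ----------------------------------------------------

# brute-force n-gram entity scan: every token span checked against the KB,
# then greedy longest-leftmost non-overlap selection
oracle_ngram_entities <- function(sentence, kb) {
  tk <- sentence$tokens
  n <- nrow(tk)
  hits <- list()
  for (i in seq_len(n)) for (j in i:min(n, i + kb$max_ngram - 1L)) {
    key <- tolower(paste(tk$text[i:j], collapse = " "))
    if (!is.null(kb$lookup[[key]]))
      hits[[length(hits) + 1L]] <- c(start = i, end = j)
  }
  if (length(hits) == 0) return(hits)
  hits <- hits[order(vapply(hits, `[[`, 0L, "start"),
                     -vapply(hits, function(h) h["end"] - h["start"], 0L))]
  taken <- rep(FALSE, n)
  out <- list()
  for (h in hits) {
    if (any(taken[h["start"]:h["end"]])) next
    taken[h["start"]:h["end"]] <- TRUE
    out[[length(out) + 1L]] <- h
  }
  out
}

# recursive DFS path evaluation, independent of the frontier-based walker
oracle_walk_inner <- function(sentence, tok, steps) {
  if (length(steps) == 0) return(tok)
  st <- steps[[1]]
  rest <- steps[-1]
  out <- integer(0)
  if (st$optional) out <- c(out, oracle_walk_inner(sentence, tok, rest))
  d <- sentence$deps
  for (r in seq_len(nrow(d))) {
    lab <- litsignal:::normalize_dep_label(d$label[r])
    if (!(lab %in% st$labels)) next
    nxt <- if (st$dir == "down" && d$head[r] == tok) d$dep[r]
           else if (st$dir == "up" && d$dep[r] == tok && d$head[r] != 0) d$head[r]
           else NA_integer_
    if (is.na(nxt)) next
    if (!is.null(st$lex)) {
      t2 <- tolower(sentence$tokens$text[nxt])
      l2 <- tolower(sentence$tokens$lemma[nxt])
      if (!(t2 %in% st$lex || (!is.na(l2) && l2 %in% st$lex))) next
    }
    out <- c(out, oracle_walk_inner(sentence, nxt, rest))
  }
  unique(out)
}
oracle_walk <- function(sentence, tok, steps) {
  sort(unique(setdiff(oracle_walk_inner(sentence, tok, steps), tok)))
}

# brute-force redundancy filter
oracle_filter <- function(records, k) {
  records[vapply(seq_len(nrow(records)),
                 function(i) records$evidence_count[i] >= k, TRUE), ,
          drop = FALSE]
}

# build a small aggregated record table quickly
make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(source = r[[1]], relation = r[[2]], subtype = NA_character_,
               sign = 1L, target = r[[3]], doc_id = r[[4]], sent = 1L,
               trigger = "t", negated = isTRUE(r[[5]]),
               stringsAsFactors = FALSE)))
}
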