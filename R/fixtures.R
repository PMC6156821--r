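# Synthetic gold corpus generator and event scorer. Each skeleton emits a
# sentence together with its dependency tree (so no live parser is needed)
# and gold annotations by construction. The generator covers the ten
# recurring syntactic variations, coordination, polarity, negation,
# binding, translocation, coreference and a combination case.

FIXTURE_PROTEINS <- c("MEK1", "ERK", "RhoA", "Smurf1", "Smurf2", "KRAS",
                      "p53", "PTPN13", "EphrinB1", "Dvl2", "aPKC", "A20",
                      "ABIN", "Cdc42", "PTEN", "GATA3", "BRCA1", "EGFR")

CORE_VARIATIONS <- c("declarative", "passive", "prep_nominalization",
                     "object_nominalization", "subject_nominalization",
                     "subject_relative", "object_relative",
                     "subject_apposition", "object_apposition",
                     "paraphrastic_causative")

# build an annotated sentence from parallel vectors
sent_build <- function(words, pos, heads, labels, offset = 0L) {
  starts <- integer(length(words))
  p <- offset
  for (i in seq_along(words)) {
    starts[i] <- p
    p <- p + nchar(words[i]) + 1L
  }
  tokens <- data.frame(index = seq_along(words), text = words,
                       start = starts, end = starts + nchar(words),
                       pos = pos, lemma = tolower(words),
                       stringsAsFactors = FALSE)
  deps <- data.frame(head = as.integer(heads), dep = seq_along(words),
                     label = labels, stringsAsFactors = FALSE)
  ls_sentence(tokens, deps, paste(words, collapse = " "), offset)
}

gold_entity <- function(sent, s, e = s) list(kind = "entity", sent = sent,
                                             span = c(s, e))
gold_event_ref <- function(idx) list(kind = "event", idx = idx)

# forms of an event label used by the generator
label_forms <- function(label, lexicons) {
  d <- lexicons$triggers[[label]]
  vlem <- d$lemma[d$pos == "verb"][1]
  list(vb = vlem, vb3 = inflect_verb(vlem)[2], vpp = inflect_verb(vlem)[3],
       nn = d$lemma[d$pos == "noun"][1])
}

# each skeleton returns list(sentence, mentions, events); token indices of
# gold spans refer to the single generated sentence (sent = 1)
skeleton_case <- function(variation, label, A, B, lexicons) {
  f <- label_forms(label, lexicons)
  simple <- function(trig, theme_tok, extra = list())
    c(list(sent = 1L, label = label, trigger = c(trig, trig),
           negated = FALSE,
           args = c(list(theme = list(gold_entity(1L, theme_tok))), extra)))
  reg <- function(trig, ctrl_tok, sign = 1L)
    list(sent = 1L,
         label = if (sign > 0) "positive_regulation" else "negative_regulation",
         trigger = c(trig, trig), negated = FALSE,
         args = list(controller = list(gold_entity(1L, ctrl_tok)),
                     controlled = list(gold_event_ref(1L))))
  switch(variation,
    declarative = {
      s <- sent_build(c(A, f$vb3, B, "."), c("PROPN", "VERB", "PROPN", "PUNCT"),
                      c(2, 0, 2, 2), c("nsubj", "root", "obj", "punct"))
      list(sentence = s, events = list(simple(2L, 3L), reg(2L, 1L)))
    },
    passive = {
      s <- sent_build(c(B, "is", f$vpp, "by", A, "."),
                      c("PROPN", "AUX", "VERB", "ADP", "PROPN", "PUNCT"),
                      c(3, 3, 0, 5, 3, 3),
                      c("nsubj:pass", "aux:pass", "root", "case", "obl:by", "punct"))
      list(sentence = s, events = list(simple(3L, 1L), reg(3L, 5L)))
    },
    prep_nominalization = {
      s <- sent_build(c("The", f$nn, "of", B, "by", A, "increased", "."),
                      c("DET", "NOUN", "ADP", "PROPN", "ADP", "PROPN", "VERB", "PUNCT"),
                      c(2, 7, 4, 2, 6, 2, 0, 7),
                      c("det", "nsubj", "case", "nmod:of", "case", "nmod:by",
                        "root", "punct"))
      list(sentence = s, events = list(simple(2L, 4L), reg(2L, 6L)))
    },
    object_nominalization = {
      s <- sent_build(c(B, f$nn, "by", A, "increased", "."),
                      c("PROPN", "NOUN", "ADP", "PROPN", "VERB", "PUNCT"),
                      c(2, 5, 4, 2, 0, 5),
                      c("compound", "nsubj", "case", "nmod:by", "root", "punct"))
      list(sentence = s, events = list(simple(2L, 1L), reg(2L, 4L)))
    },
    subject_nominalization = {
      s <- sent_build(c(A, f$nn, "of", B, "increased", "."),
                      c("PROPN", "NOUN", "ADP", "PROPN", "VERB", "PUNCT"),
                      c(2, 5, 4, 2, 0, 5),
                      c("compound", "nsubj", "case", "nmod:of", "root", "punct"))
      list(sentence = s, events = list(simple(2L, 4L), reg(2L, 1L)))
    },
    subject_relative = {
      s <- sent_build(c(A, ",", "which", f$vb3, B, ",", "was", "studied", "."),
                      c("PROPN", "PUNCT", "PRON", "VERB", "PROPN", "PUNCT",
                        "AUX", "VERB", "PUNCT"),
                      c(8, 1, 4, 1, 4, 1, 8, 0, 8),
                      c("nsubj:pass", "punct", "nsubj", "acl:relcl", "obj",
                        "punct", "aux:pass", "root", "punct"))
      list(sentence = s, events = list(simple(4L, 5L), reg(4L, 1L)))
    },
    object_relative = {
      s <- sent_build(c("We", "studied", B, ",", "which", "is", f$vpp, "by",
                        A, "."),
                      c("PRON", "VERB", "PROPN", "PUNCT", "PRON", "AUX",
                        "VERB", "ADP", "PROPN", "PUNCT"),
                      c(2, 0, 2, 3, 7, 7, 3, 9, 7, 2),
                      c("nsubj", "root", "obj", "punct", "nsubj:pass",
                        "aux:pass", "acl:relcl", "case", "obl:by", "punct"))
      list(sentence = s, events = list(simple(7L, 3L), reg(7L, 9L)))
    },
    subject_apposition = {
      s <- sent_build(c("a", "novel", "protein", ",", A, ",", f$vb3, B, "."),
                      c("DET", "ADJ", "NOUN", "PUNCT", "PROPN", "PUNCT",
                        "VERB", "PROPN", "PUNCT"),
                      c(3, 3, 7, 3, 3, 3, 0, 7, 7),
                      c("det", "amod", "nsubj", "punct", "appos", "punct",
                        "root", "obj", "punct"))
      list(sentence = s, events = list(simple(7L, 8L), reg(7L, 5L)))
    },
    object_apposition = {
      s <- sent_build(c(A, f$vb3, "a", "novel", "protein", ",", B, "."),
                      c("PROPN", "VERB", "DET", "ADJ", "NOUN", "PUNCT",
                        "PROPN", "PUNCT"),
                      c(2, 0, 5, 5, 2, 5, 5, 2),
                      c("nsubj", "root", "det", "amod", "obj", "punct",
                        "appos", "punct"))
      list(sentence = s, events = list(simple(2L, 7L), reg(2L, 1L)))
    },
    paraphrastic_causative = {
      s <- sent_build(c(A, "causes", "the", f$nn, "of", B, "."),
                      c("PROPN", "VERB", "DET", "NOUN", "ADP", "PROPN", "PUNCT"),
                      c(2, 0, 4, 2, 6, 4, 2),
                      c("nsubj", "root", "det", "obj", "case", "nmod:of", "punct"))
      list(sentence = s, events = list(simple(4L, 6L), reg(4L, 1L)))
    },
    stop("unknown variation name: ", variation)
  )
}

special_cases <- function(lexicons) {
  out <- list()
  # coordination: cross-product of conjoined triggers and causes
  s <- sent_build(c("Smurf1", "and", "Smurf2", "degrade", "and",
                    "ubiquitinate", "RhoA", "."),
                  c("PROPN", "CCONJ", "PROPN", "VERB", "CCONJ", "VERB",
                    "PROPN", "PUNCT"),
                  c(4, 3, 1, 0, 6, 4, 4, 4),
                  c("nsubj", "cc", "conj", "root", "cc", "conj", "obj", "punct"))
  ev <- list(
    list(sent = 1L, label = "hydrolysis", trigger = c(4L, 4L), negated = FALSE,
         args = list(theme = list(gold_entity(1L, 7L)))),
    list(sent = 1L, label = "ubiquitination", trigger = c(6L, 6L), negated = FALSE,
         args = list(theme = list(gold_entity(1L, 7L)))))
  regs <- list()
  for (ei in 1:2) for (ct in c(1L, 3L))
    regs[[length(regs) + 1L]] <- list(
      sent = 1L, label = "positive_regulation", trigger = ev[[ei]]$trigger,
      negated = FALSE,
      args = list(controller = list(gold_entity(1L, ct)),
                  controlled = list(gold_event_ref(ei))))
  out$coordination <- list(sentences = list(s), events = c(ev, regs))

  # polarity: reversal adjective on the controller path flips the sign
  s <- sent_build(c("Decreased", "PTPN13", "expression", "enhances",
                    "EphrinB1", "phosphorylation", "."),
                  c("ADJ", "PROPN", "NOUN", "VERB", "PROPN", "NOUN", "PUNCT"),
                  c(3, 3, 4, 0, 6, 4, 4),
                  c("amod", "compound", "nsubj", "root", "compound", "obj",
                    "punct"))
  out$polarity <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "phosphorylation", trigger = c(6L, 6L),
         negated = FALSE, args = list(theme = list(gold_entity(1L, 5L)))),
    list(sent = 1L, label = "negative_regulation", trigger = c(4L, 4L),
         negated = FALSE,
         args = list(controller = list(gold_entity(1L, 2L)),
                     controlled = list(gold_event_ref(1L))))))

  # negation: cue governing the trigger
  s <- sent_build(c("KRAS", "did", "not", "inhibit", "p53", "."),
                  c("PROPN", "AUX", "PART", "VERB", "PROPN", "PUNCT"),
                  c(4, 4, 4, 0, 4, 4),
                  c("nsubj", "aux", "advmod", "root", "obj", "punct"))
  out$negation <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "negative_activation", trigger = c(4L, 4L),
         negated = TRUE,
         args = list(controller = list(gold_entity(1L, 1L)),
                     controlled = list(gold_entity(1L, 5L))))))

  # activation: controlled participant is an entity
  s <- sent_build(c("KRAS", "activates", "p53", "."),
                  c("PROPN", "VERB", "PROPN", "PUNCT"),
                  c(2, 0, 2, 2), c("nsubj", "root", "obj", "punct"))
  out$activation <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "positive_activation", trigger = c(2L, 2L),
         negated = FALSE,
         args = list(controller = list(gold_entity(1L, 1L)),
                     controlled = list(gold_entity(1L, 3L))))))

  # binding, three constructions
  s <- sent_build(c("A20", "binds", "to", "ABIN", "."),
                  c("PROPN", "VERB", "ADP", "PROPN", "PUNCT"),
                  c(2, 0, 4, 2, 2),
                  c("nsubj", "root", "case", "obl:to", "punct"))
  out$binding_declarative <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "binding", trigger = c(2L, 2L), negated = FALSE,
         args = list(theme = list(gold_entity(1L, 1L), gold_entity(1L, 4L))))))
  s <- sent_build(c("The", "interaction", "between", "Dvl2", "and", "aPKC",
                    "increased", "."),
                  c("DET", "NOUN", "ADP", "PROPN", "CCONJ", "PROPN", "VERB",
                    "PUNCT"),
                  c(2, 7, 4, 2, 6, 4, 0, 7),
                  c("det", "nsubj", "case", "nmod:between", "cc", "conj",
                    "root", "punct"))
  out$binding_between <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "binding", trigger = c(2L, 2L), negated = FALSE,
         args = list(theme = list(gold_entity(1L, 4L), gold_entity(1L, 6L))))))
  s <- sent_build(c("Cdc42", "forms", "a", "complex", "with", "PTEN", "."),
                  c("PROPN", "VERB", "DET", "NOUN", "ADP", "PROPN", "PUNCT"),
                  c(2, 0, 4, 2, 6, 4, 2),
                  c("nsubj", "root", "det", "obj", "case", "nmod:with",
                    "punct"))
  out$binding_complex <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "binding", trigger = c(4L, 4L), negated = FALSE,
         args = list(theme = list(gold_entity(1L, 1L), gold_entity(1L, 6L))))))

  # translocation with source and destination roles
  s <- sent_build(c("ERK", "translocates", "to", "the", "nucleus", "."),
                  c("PROPN", "VERB", "ADP", "DET", "NOUN", "PUNCT"),
                  c(2, 0, 5, 5, 2, 2),
                  c("nsubj", "root", "case", "det", "obl:to", "punct"))
  out$translocation_to <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "translocation", trigger = c(2L, 2L),
         negated = FALSE,
         args = list(theme = list(gold_entity(1L, 1L)),
                     destination = list(gold_entity(1L, 5L))))))
  s <- sent_build(c("GATA3", "is", "transported", "from", "the", "cytoplasm",
                    "to", "the", "nucleus", "."),
                  c("PROPN", "AUX", "VERB", "ADP", "DET", "NOUN", "ADP",
                    "DET", "NOUN", "PUNCT"),
                  c(3, 3, 0, 6, 6, 3, 9, 9, 3, 3),
                  c("nsubj:pass", "aux:pass", "root", "case", "det",
                    "obl:from", "case", "det", "obl:to", "punct"))
  out$translocation_from_to <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "translocation", trigger = c(3L, 3L),
         negated = FALSE,
         args = list(theme = list(gold_entity(1L, 1L)),
                     source = list(gold_entity(1L, 6L)),
                     destination = list(gold_entity(1L, 9L))))))

  # coreference: definite NP resolved across a sentence boundary
  s1 <- sent_build(c("We", "studied", "BRCA1", "."),
                   c("PRON", "VERB", "PROPN", "PUNCT"),
                   c(2, 0, 2, 2), c("nsubj", "root", "obj", "punct"))
  s2 <- sent_build(c("EGFR", "phosphorylates", "this", "protein", "."),
                   c("PROPN", "VERB", "DET", "NOUN", "PUNCT"),
                   c(2, 0, 4, 2, 2),
                   c("nsubj", "root", "det", "obj", "punct"),
                   offset = max(s1$tokens$end) + 1L)
  out$coref_entity <- list(sentences = list(s1, s2), events = list(
    list(sent = 2L, label = "phosphorylation", trigger = c(2L, 2L),
         negated = FALSE, args = list(theme = list(gold_entity(2L, 3L, 4L)))),
    list(sent = 2L, label = "positive_regulation", trigger = c(2L, 2L),
         negated = FALSE,
         args = list(controller = list(gold_entity(2L, 1L)),
                     controlled = list(gold_event_ref(1L))))))

  # combination: appositive-free subject relative plus passivization
  s <- sent_build(c("Pde2", ",", "which", "has", "been", "found", "to",
                    "hydrolyze", "Ras", ",", "activates", "MEK", "."),
                  c("PROPN", "PUNCT", "PRON", "AUX", "AUX", "VERB", "PART",
                    "VERB", "PROPN", "PUNCT", "VERB", "PROPN", "PUNCT"),
                  c(11, 1, 6, 6, 6, 1, 8, 6, 8, 1, 0, 11, 11),
                  c("nsubj", "punct", "nsubj:pass", "aux", "aux:pass",
                    "acl:relcl", "mark", "xcomp", "obj", "punct", "root",
                    "obj", "punct"))
  out$combination <- list(sentences = list(s), events = list(
    list(sent = 1L, label = "hydrolysis", trigger = c(8L, 8L),
         negated = FALSE, args = list(theme = list(gold_entity(1L, 9L)))),
    list(sent = 1L, label = "positive_regulation", trigger = c(8L, 8L),
         negated = FALSE,
         args = list(controller = list(gold_entity(1L, 1L)),
                     controlled = list(gold_event_ref(1L)))),
    list(sent = 1L, label = "positive_activation", trigger = c(11L, 11L),
         negated = FALSE,
         args = list(controller = list(gold_entity(1L, 1L)),
                     controlled = list(gold_entity(1L, 12L))))))
  out
}

#' Generate a synthetic gold corpus
#'
#' For each requested syntactic variation and event type, emits a sentence
#' instantiated from a skeleton (surface string and dependency tree
#' generated together) plus gold annotations by construction, and a set of
#' special cases (coordination, polarity, negation, activation, binding,
#' translocation, cross-sentence coreference, a variation combination).
#' Deterministic given the seed.
#'
#' @param variations Names of core variations (see `CORE_VARIATIONS`).
#' @param events Event labels instantiated per variation.
#' @param include Special-case names to include (default all).
#' @param seed Random seed controlling entity sampling.
#' @param lexicons Lexicon bundle.
#' @return List of `list(doc, gold)`; `doc` is an annotated `ls_document`,
#'   `gold` the gold annotation (`doc_id`, `events`).
#' @export
generate_fixture_corpus <- function(variations = CORE_VARIATIONS,
                                    events = SIMPLE_EVENT_LABELS,
                                    include = NULL, seed = 7L,
                                    lexicons = default_lexicons()) {
  bad <- setdiff(variations, CORE_VARIATIONS)
  if (length(bad)) stop("unknown variation name(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  out <- list()
  for (v in variations) {
    for (lb in events) {
      pair <- sample(FIXTURE_PROTEINS, 2L)
      cs <- skeleton_case(v, lb, pair[1], pair[2], lexicons)
      doc_id <- sprintf("syn-%s-%s", v, lb)
      doc <- ls_document(doc_id, list(cs$sentence),
                         cs$sentence$text)
      out[[doc_id]] <- list(doc = doc,
                            gold = list(doc_id = doc_id, events = cs$events))
    }
  }
  sp <- special_cases(lexicons)
  if (is.null(include)) include <- names(sp)
  for (nm in intersect(include, names(sp))) {
    cs <- sp[[nm]]
    doc_id <- sprintf("syn-%s", nm)
    doc <- ls_document(doc_id, cs$sentences,
                       paste(vapply(cs$sentences, function(s) s$text, ""),
                             collapse = " "))
    out[[doc_id]] <- list(doc = doc,
                          gold = list(doc_id = doc_id, events = cs$events))
  }
  out
}

#' Write a generated corpus to disk (CoNLL-U + gold JSON)
#' @param corpus From [generate_fixture_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- unlist(lapply(corpus, function(x) write_conllu(x$doc)))
  writeLines(lines, file.path(dir, "corpus.conllu"), useBytes = TRUE)
  jsonlite::write_json(lapply(unname(corpus), function(x) x$gold),
                       file.path(dir, "gold.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}

#' Read gold annotations from JSON
#'
#' Inverse of the gold serialization in [write_fixture_corpus()]: converts
#' JSON lists back to the in-memory gold shape (integer trigger/argument
#' spans) accepted by [score_events()].
#' @param path JSON file path.
#' @return List of gold annotations.
#' @export
read_gold_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix_ref <- function(r) {
    if (identical(r$kind, "entity"))
      list(kind = "entity", sent = as.integer(r$sent),
           span = as.integer(unlist(r$span)))
    else gold_event_ref(as.integer(r$idx))
  }
  lapply(raw, function(g) list(
    doc_id = g$doc_id,
    events = lapply(g$events, function(e) list(
      sent = as.integer(e$sent), label = e$label,
      trigger = as.integer(unlist(e$trigger)),
      negated = isTRUE(e$negated),
      args = lapply(e$args, function(refs) lapply(refs, fix_ref))))))
}

# --- scoring ----------------------------------------------------------------

# convert an extraction's events into comparable views
extraction_views <- function(extraction) {
  ids <- names(extraction$events)
  lapply(extraction$events, function(e) {
    args <- lapply(e$args, function(refs) lapply(refs, function(ref) {
      if (ref %in% ids) {
        gold_event_ref(match(ref, ids))
      } else {
        m <- extraction$mentions[[ref]]
        gold_entity(m$sent, m$tok_start, m$tok_end)
      }
    }))
    list(sent = e$sent, label = e$label, trigger = c(e$trigger_start,
                                                     e$trigger_end),
         negated = e$negated, args = args)
  })
}

spans_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

REGACT_LABELS <- c("positive_regulation", "negative_regulation",
                   "positive_activation", "negative_activation")

view_equal <- function(p, g, P, G, mode, depth = 0) {
  if (depth > 10) return(FALSE)
  if (!identical(p$label, g$label)) return(FALSE)
  if (!identical(p$negated, g$negated)) return(FALSE)
  trigger_free <- mode == "approximate" && p$label %in% REGACT_LABELS
  if (!trigger_free) {
    if (p$sent != g$sent) return(FALSE)
    ok <- if (mode == "strict") identical(as.integer(p$trigger),
                                          as.integer(g$trigger))
          else spans_overlap(p$trigger, g$trigger)
    if (!ok) return(FALSE)
  }
  roles <- union(names(p$args), names(g$args))
  for (rn in roles) {
    pr <- p$args[[rn]] %||% list()
    gr <- g$args[[rn]] %||% list()
    if (length(pr) != length(gr)) return(FALSE)
    used <- logical(length(gr))
    for (a in pr) {
      found <- FALSE
      for (j in seq_along(gr)) {
        if (used[j]) next
        if (ref_equal(a, gr[[j]], P, G, mode, depth)) {
          used[j] <- TRUE; found <- TRUE; break
        }
      }
      if (!found) return(FALSE)
    }
  }
  TRUE
}

ref_equal <- function(a, b, P, G, mode, depth) {
  if (!identical(a$kind, b$kind)) return(FALSE)
  if (a$kind == "entity") {
    if (a$sent != b$sent) return(FALSE)
    if (mode == "strict") identical(as.integer(a$span), as.integer(b$span))
    else spans_overlap(a$span, b$span)
  } else {
    view_equal(P[[a$idx]], G[[b$idx]], P, G, mode, depth + 1)
  }
}

#' Score predicted events against a gold annotation
#'
#' Approximate mode matches trigger spans by overlap and nested arguments
#' by recursive equivalence; regulations/activations are matched on their
#' label and recursively equivalent arguments. Strict mode requires exact
#' spans throughout.
#'
#' @param predictions One `ls_extraction` or a named list of them.
#' @param gold One gold annotation (`list(doc_id, events)`) or a list.
#' @param mode `"approximate"` (default) or `"strict"`.
#' @return A ScoreReport: list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1` and a `per_label` data frame. Precision is `NA`
#'   (undefined) when there are no predictions.
#' @export
score_events <- function(predictions, gold, mode = c("approximate", "strict")) {
  mode <- match.arg(mode)
  if (inherits(predictions, "ls_extraction") || !is.null(predictions$doc_id))
    predictions <- list(predictions)
  if (!is.null(gold$doc_id)) gold <- list(gold)
  pred_ids <- vapply(predictions, function(x) x$doc_id, "")
  gold_ids <- vapply(gold, function(g) g$doc_id, "")
  if (!setequal(pred_ids, gold_ids))
    stop("document id mismatch between predictions and gold")
  tp <- 0L; fp <- 0L; fn <- 0L
  lab_stats <- list()
  bump <- function(lab, what) {
    cur <- lab_stats[[lab]] %||% c(tp = 0L, fp = 0L, fn = 0L)
    cur[what] <- cur[what] + 1L
    lab_stats[[lab]] <<- cur
  }
  for (di in seq_along(predictions)) {
    P <- if (inherits(predictions[[di]], "ls_extraction"))
      extraction_views(predictions[[di]]) else predictions[[di]]$events
    G <- gold[[match(pred_ids[di], gold_ids)]]$events
    used <- logical(length(G))
    for (p in P) {
      hit <- FALSE
      for (j in seq_along(G)) {
        if (used[j]) next
        if (view_equal(p, G[[j]], P, G, mode)) {
          used[j] <- TRUE; hit <- TRUE; break
        }
      }
      if (hit) { tp <- tp + 1L; bump(p$label, "tp") }
      else { fp <- fp + 1L; bump(p$label, "fp") }
    }
    for (j in which(!used)) { fn <- fn + 1L; bump(G[[j]]$label, "fn") }
  }
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  per_label <- do.call(rbind, lapply(names(lab_stats), function(lb) {
    st <- lab_stats[[lb]]
    data.frame(label = lb, tp = st["tp"], fp = st["fp"], fn = st["fn"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, per_label = per_label)
}
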