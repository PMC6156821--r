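# Document-level extraction pipeline: entities -> simple events -> nested
# events -> polarity -> negation, per sentence, with document-wide ids.

#' Run the full extraction cascade on a document
#'
#' @param document An annotated `ls_document` (from [read_conllu()] or
#'   [read_text()] + [annotate()]).
#' @param kb KB index ([load_kb()]); defaults to the shipped synthetic KB.
#' @param rules Compiled rules ([compile_grammar()]); defaults to the
#'   shipped grammar. Pass precompiled rules when processing a corpus.
#' @param lexicons Lexicon bundle.
#' @param binding_mode Binding binarization mode (see [binarize_binding()]).
#' @param resolve_coref If `TRUE`, run the coreference sieves and
#'   re-extract events with resolved arguments (see [resolve_and_reextract()]).
#' @return An `ls_extraction`: list with `doc_id`, `document`, `mentions`
#'   (named by id) and `events` (named by id).
#' @export
extract_document <- function(document, kb = default_kb(), rules = NULL,
                             lexicons = default_lexicons(),
                             binding_mode = "chain", resolve_coref = TRUE) {
  if (is.null(rules)) rules <- compile_grammar(default_grammar(), lexicons)
  mentions <- list()
  events <- list()
  tcount <- 0L
  ecount <- 0L
  per_sentence_mentions <- list()
  for (si in seq_along(document$sentences)) {
    s <- document$sentences[[si]]
    ms <- match_entities(s, kb, doc_id = document$doc_id, sent = si)
    ms <- lapply(ms, ground)
    ms <- attach_states(s, ms)
    for (i in seq_along(ms)) {
      tcount <- tcount + 1L
      ms[[i]]$id <- sprintf("T%d", tcount)
    }
    per_sentence_mentions[[si]] <- ms
    for (m in ms) mentions[[m$id]] <- m
  }
  for (si in seq_along(document$sentences)) {
    s <- document$sentences[[si]]
    ms <- per_sentence_mentions[[si]]
    simple <- extract_simple_events(s, ms, rules, lexicons,
                                    doc_id = document$doc_id, sent = si,
                                    id_start = ecount + 1L,
                                    binding_mode = binding_mode)
    ecount <- ecount + length(simple)
    nested <- extract_nested_events(s, ms, simple, rules, lexicons,
                                    doc_id = document$doc_id, sent = si,
                                    id_start = ecount + 1L)
    ecount <- ecount + length(nested)
    sentence_events <- c(simple, nested)
    # polarity correction, then negation flags
    for (eid in names(sentence_events)) {
      ev <- sentence_events[[eid]]
      if (ev$category %in% REGULATION_CATEGORIES) {
        cues <- collect_reversal_cues(ev, s, mentions, sentence_events,
                                      lexicons$polarity)
        ev <- correct_polarity(ev, cues)
      }
      ev$negated <- detect_negation(ev, s, lexicons$negation)
      sentence_events[[eid]] <- ev
    }
    events <- c(events, sentence_events)
  }
  extraction <- structure(list(doc_id = document$doc_id, document = document,
                               mentions = mentions, events = events,
                               sentence_mentions = per_sentence_mentions),
                          class = "ls_extraction")
  if (resolve_coref) {
    anaphors <- find_anaphors(document, extraction, lexicons)
    links <- apply_sieves(document, extraction, anaphors)
    extraction <- resolve_and_reextract(document, extraction, links,
                                        rules = rules, lexicons = lexicons,
                                        binding_mode = binding_mode)
  }
  extraction
}

#' Serialize an extraction's events to JSON standoff
#'
#' Nested arguments are referenced by event id; the schema is
#' `{doc_id, events: [{id, label, sign, negated, sent, trigger, args}]}`.
#' @param extraction An `ls_extraction`.
#' @return JSON string.
#' @export
events_to_json <- function(extraction) {
  jsonlite::toJSON(list(
    doc_id = extraction$doc_id,
    events = lapply(unname(extraction$events), function(e)
      list(id = e$id, label = e$label, sign = e$sign, negated = e$negated,
           sent = e$sent, trigger = e$trigger_text, args = e$args,
           coref = e$coref))),
    auto_unbox = TRUE, null = "null")
}
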