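# Sieve-based coreference for entity and event anaphors. Deterministic
# resolution rules are applied in precision order; the first sieve to
# resolve an anaphor wins. Resolved anaphors license re-extraction of
# events whose arguments were pronominal or definite references.

GENERIC_ENTITY_NOUNS <- c(protein = "gene_or_gene_product",
                          kinase = "gene_or_gene_product",
                          phosphatase = "gene_or_gene_product",
                          enzyme = "gene_or_gene_product",
                          receptor = "gene_or_gene_product",
                          ligase = "gene_or_gene_product",
                          factor = "gene_or_gene_product",
                          chemical = "simple_chemical",
                          compound = "simple_chemical",
                          substrate = "gene_or_gene_product")

EVENT_ANAPHOR_NOUNS <- c(binding = "binding", interaction = "binding",
                         association = "binding", complex = "binding",
                         phosphorylation = "phosphorylation",
                         ubiquitination = "ubiquitination",
                         methylation = "methylation",
                         acetylation = "acetylation",
                         degradation = "hydrolysis",
                         translocation = "translocation")

#' Find anaphor candidates in a document
#'
#' Candidates are definite/demonstrative NPs headed by a taxonomy noun
#' ("this protein", "these kinases"), mutant descriptions ("the K134A
#' mutant") and event anaphors ("this interaction", "this binding").
#'
#' @param document An `ls_document`.
#' @param extraction Its `ls_extraction` (mentions block anaphor readings
#'   of tokens already inside a mention).
#' @param lexicons Lexicon bundle (unused by the default noun inventories,
#'   kept for configurability).
#' @return List of anaphor records: `list(sent, tok_start, tok_end, head_tok,
#'   kind, type, label, number, code, text)`.
#' @export
find_anaphors <- function(document, extraction, lexicons = default_lexicons()) {
  out <- list()
  for (si in seq_along(document$sentences)) {
    s <- document$sentences[[si]]
    tk <- s$tokens
    low <- tolower(tk$text)
    n <- nrow(tk)
    in_mention <- rep(FALSE, n)
    for (m in extraction$sentence_mentions[[si]])
      in_mention[m$tok_start:m$tok_end] <- TRUE
    for (i in seq_len(n - 1L)) {
      # "the K134A mutant"
      if (i <= n - 2L && low[i] %in% c("the", "this") &&
          grepl(MUTANT_CODE_PATTERN, tk$text[i + 1L]) &&
          low[i + 2L] == "mutant") {
        out[[length(out) + 1L]] <- list(
          sent = si, tok_start = i, tok_end = i + 2L, head_tok = i + 2L,
          kind = "entity", type = "gene_or_gene_product", label = NA,
          number = "sg", code = tk$text[i + 1L],
          text = paste(tk$text[i:(i + 2L)], collapse = " "))
        next
      }
      if (in_mention[i + 1L]) next
      # the determiner slot must really be a determiner ("that" as a
      # complementizer, tagged SCONJ, is not anaphoric)
      if (!is.na(tk$pos[i]) && !tk$pos[i] %in% c("DET", "PRON")) next
      hd <- low[i + 1L]
      if (low[i] %in% c("this", "that", "the") && hd %in% names(GENERIC_ENTITY_NOUNS)) {
        # not anaphoric when the noun introduces a named entity ("the protein MEK1")
        if (i + 2L <= n && in_mention[i + 2L]) next
        out[[length(out) + 1L]] <- list(
          sent = si, tok_start = i, tok_end = i + 1L, head_tok = i + 1L,
          kind = "entity", type = unname(GENERIC_ENTITY_NOUNS[hd]), label = NA,
          number = "sg", code = NA,
          text = paste(tk$text[i:(i + 1L)], collapse = " "))
      } else if (low[i] %in% c("these", "those", "both") &&
                 sub("s$", "", hd) %in% names(GENERIC_ENTITY_NOUNS)) {
        out[[length(out) + 1L]] <- list(
          sent = si, tok_start = i, tok_end = i + 1L, head_tok = i + 1L,
          kind = "entity", type = unname(GENERIC_ENTITY_NOUNS[sub("s$", "", hd)]),
          label = NA, number = "pl", code = NA,
          text = paste(tk$text[i:(i + 1L)], collapse = " "))
      } else if (low[i] %in% c("this", "that") && hd %in% names(EVENT_ANAPHOR_NOUNS)) {
        out[[length(out) + 1L]] <- list(
          sent = si, tok_start = i, tok_end = i + 1L, head_tok = i + 1L,
          kind = "event", type = NA, label = unname(EVENT_ANAPHOR_NOUNS[hd]),
          number = "sg", code = NA,
          text = paste(tk$text[i:(i + 1L)], collapse = " "))
      }
    }
  }
  out
}

#' Resolve anaphors with a precision-ordered sieve cascade
#'
#' Sieves, from highest to lowest precision: (1) exact string match,
#' (2) mutant-alias match ("the K134A mutant" to "H2AX-K134A"),
#' (3) event-label match to the most recent compatible event, (4)
#' type-compatible nearest antecedent for generic NPs. The first sieve to
#' resolve an anaphor wins; later sieves never alter earlier links.
#'
#' @param document An `ls_document`.
#' @param extraction Its `ls_extraction`.
#' @param anaphors Candidates from [find_anaphors()].
#' @param sieves Sieve roster, in order.
#' @param window Number of preceding sentences searched (plus the
#'   anaphor's own sentence).
#' @return List of CorefLink records: `list(anaphor, antecedent_kind,
#'   antecedent_id, sieve, rank)`.
#' @export
apply_sieves <- function(document, extraction, anaphors,
                         sieves = c("exact_match", "mutant_alias",
                                    "event_label", "generic_type"),
                         window = 2L) {
  links <- list()
  mentions <- extraction$mentions
  events <- extraction$events
  for (an in anaphors) {
    lo <- an$sent - window
    cand_m <- Filter(function(m) {
      m$sent >= lo && (m$sent < an$sent ||
        (m$sent == an$sent && m$tok_end < an$tok_start))
    }, mentions)
    # most recent first
    if (length(cand_m)) {
      ord <- order(vapply(cand_m, function(m) m$sent * 1000L + m$tok_end, 0L),
                   decreasing = TRUE)
      cand_m <- cand_m[ord]
    }
    cand_e <- Filter(function(e) {
      e$sent >= lo && (e$sent < an$sent ||
        (e$sent == an$sent && e$trigger_end < an$tok_start))
    }, events)
    if (length(cand_e)) {
      ord <- order(vapply(cand_e, function(e) e$sent * 1000L + e$trigger_start, 0L),
                   decreasing = TRUE)
      cand_e <- cand_e[ord]
    }
    resolved <- NULL
    for (sv in sieves) {
      if (sv == "exact_match" && an$kind == "entity") {
        bare <- tolower(sub("^(this|that|the|these|those|both) ", "", an$text))
        hit <- Filter(function(m) tolower(m$text) == bare, cand_m)
        if (length(hit))
          resolved <- list(kind = "mention", id = hit[[1]]$id, sieve = sv)
      } else if (sv == "mutant_alias" && an$kind == "entity" && !is.na(an$code)) {
        hit <- Filter(function(m) {
          any(vapply(m$mods, function(md)
            md$kind == "Mutant" && identical(md$subtype, an$code), TRUE)) ||
            grepl(an$code, m$text, fixed = TRUE)
        }, cand_m)
        if (length(hit))
          resolved <- list(kind = "mention", id = hit[[1]]$id, sieve = sv)
      } else if (sv == "event_label" && an$kind == "event") {
        hit <- Filter(function(e) e$label == an$label, cand_e)
        if (length(hit))
          resolved <- list(kind = "event", id = hit[[1]]$id, sieve = sv)
      } else if (sv == "generic_type" && an$kind == "entity" && an$number == "sg") {
        # lowest-precision sieve: only antecedents from earlier sentences,
        # so a clause's own arguments never antecede its generic NPs
        hit <- Filter(function(m) m$type == an$type && m$sent < an$sent, cand_m)
        if (length(hit))
          resolved <- list(kind = "mention", id = hit[[1]]$id, sieve = sv)
      }
      if (!is.null(resolved)) break
    }
    if (is.null(resolved)) next
    links[[length(links) + 1L]] <- list(
      anaphor = an, antecedent_kind = resolved$kind,
      antecedent_id = resolved$id, sieve = resolved$sieve,
      rank = match(resolved$sieve, sieves))
  }
  links
}

#' Substitute resolved antecedents and re-extract events
#'
#' Entity links materialize a virtual mention (carrying the antecedent's
#' type, groundings and states) at the anaphor span; event links map the
#' anaphor head token to the antecedent event id. Event extraction is then
#' re-run on the affected sentences until a fixpoint; events found only
#' through resolution carry `coref = TRUE`.
#'
#' @param document An `ls_document`.
#' @param extraction Its `ls_extraction`.
#' @param links From [apply_sieves()].
#' @param rules,lexicons,binding_mode As in [extract_document()].
#' @return The augmented `ls_extraction`.
#' @export
resolve_and_reextract <- function(document, extraction, links, rules,
                                  lexicons = default_lexicons(),
                                  binding_mode = "chain") {
  if (length(links) == 0) return(extraction)
  tcount <- length(extraction$mentions)
  affected <- integer(0)
  alias_by_sent <- list()
  for (lk in links) {
    an <- lk$anaphor
    si <- an$sent
    affected <- union(affected, si)
    if (lk$antecedent_kind == "mention") {
      ante <- extraction$mentions[[lk$antecedent_id]]
      tcount <- tcount + 1L
      vm <- new_mention(document$doc_id, si, an$tok_start, an$tok_end,
                        document$sentences[[si]]$tokens, ante$type,
                        kb_entries = ante$kb_entries)
      vm$id <- sprintf("T%d", tcount)
      vm$groundings <- ante$groundings
      vm$mods <- ante$mods
      vm$coref_antecedent <- ante$id
      extraction$mentions[[vm$id]] <- vm
      extraction$sentence_mentions[[si]] <-
        c(extraction$sentence_mentions[[si]], list(vm))
    } else {
      key <- as.character(si)
      alias_by_sent[[key]] <- rbind(
        alias_by_sent[[key]],
        data.frame(tok = an$head_tok, id = lk$antecedent_id,
                   stringsAsFactors = FALSE))
    }
  }
  ecount <- length(extraction$events)
  key_to_id <- if (length(extraction$events))
    stats::setNames(names(extraction$events),
                    vapply(extraction$events, event_key, ""))
  else character(0)
  for (iter in 1:3) {
    added <- FALSE
    for (si in affected) {
      s <- document$sentences[[si]]
      ms <- extraction$sentence_mentions[[si]]
      alias <- alias_by_sent[[as.character(si)]]

      simple_prov <- extract_simple_events(s, ms, rules, lexicons,
                                           doc_id = document$doc_id, sent = si,
                                           id_start = ecount + 1L,
                                           binding_mode = binding_mode)
      idmap <- character(0)   # provisional id -> stored id
      for (e in simple_prov) {
        k <- event_key(e)
        if (!is.na(key_to_id[k])) {
          idmap[e$id] <- unname(key_to_id[k])
        } else {
          prov <- e$id
          ecount <- ecount + 1L
          e$id <- sprintf("E%d", ecount)
          e$coref <- TRUE
          e <- finalize_event(e, s, extraction$mentions, extraction$events,
                              lexicons)
          extraction$events[[e$id]] <- e
          key_to_id[k] <- e$id
          idmap[prov] <- e$id
          added <- TRUE
        }
      }
      pool <- Filter(function(e) e$sent == si, extraction$events)
      nested_prov <- extract_nested_events(s, ms, pool, rules, lexicons,
                                           doc_id = document$doc_id, sent = si,
                                           id_start = ecount + 1L,
                                           event_alias = alias)
      for (e in nested_prov) {
        for (rn in names(e$args)) {
          ref <- e$args[[rn]]
          if (length(ref) == 1 && ref %in% names(idmap))
            e$args[[rn]] <- unname(idmap[ref])
        }
        k <- event_key(e)
        if (!is.na(key_to_id[k])) next
        ecount <- ecount + 1L
        e$id <- sprintf("E%d", ecount)
        e$coref <- TRUE
        e <- finalize_event(e, s, extraction$mentions, extraction$events,
                            lexicons)
        extraction$events[[e$id]] <- e
        key_to_id[k] <- e$id
        added <- TRUE
      }
    }
    if (!added) break
  }
  extraction$coref_links <- links
  extraction
}

finalize_event <- function(e, s, mentions, events, lexicons) {
  if (e$category %in% REGULATION_CATEGORIES) {
    cues <- collect_reversal_cues(e, s, mentions, events, lexicons$polarity)
    e <- correct_polarity(e, cues)
  }
  e$negated <- detect_negation(e, s, lexicons$negation)
  e
}

# identity key of an event, independent of its id
event_key <- function(e) {
  paste(e$sent, e$label, e$trigger_start,
        paste(vapply(names(e$args), function(rn)
          paste(rn, paste(sort(unlist(e$args[[rn]])), collapse = ","), sep = "="),
          ""), collapse = ";"))
}
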