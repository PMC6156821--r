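# Two-step bottom-up event extraction: simple biochemical events first
# (PTM additions/removals, binding, hydrolysis, translocation), then nested
# regulations/activations over them. Coordinated triggers and arguments are
# expanded to their cross-product; n-ary binding participant sets are
# binarized; negation is flagged from cues governing the trigger.

SIMPLE_CATEGORIES <- c("simple_event", "binding", "hydrolysis", "translocation")
REGULATION_CATEGORIES <- c("positive_regulation_activation",
                           "negative_regulation_activation")

# all conj-descendants of a token (transitively), head conjunct first
conj_set <- function(sentence, tok) {
  out <- tok
  frontier <- tok
  repeat {
    nxt <- unique(unlist(lapply(frontier, function(u)
      dep_children(sentence$deps, u, "conj"))))
    nxt <- setdiff(nxt, out)
    if (length(nxt) == 0) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# label for a coordinated trigger token, searched across the lexicons of the
# categories compatible with the original match
relabel_trigger <- function(tok, sentence, category, lexicons) {
  labels <- if (category %in% SIMPLE_CATEGORIES) {
    c(SIMPLE_EVENT_LABELS, "binding", "hydrolysis", "translocation")
  } else c("positive_regulation", "negative_regulation")
  pc <- pos_class(sentence$tokens$pos[tok])
  for (lb in labels) {
    forms <- lexicon_forms(lexicons$triggers, lb,
                           if (pc %in% c("verb", "noun")) pc else "any")
    if (tolower(sentence$tokens$text[tok]) %in% forms ||
        (!is.na(sentence$tokens$lemma[tok]) &&
         tolower(sentence$tokens$lemma[tok]) %in% forms))
      return(lb)
  }
  NA_character_
}

category_for_label <- function(label) {
  if (label %in% SIMPLE_EVENT_LABELS) "simple_event"
  else if (label == "positive_regulation") "positive_regulation_activation"
  else if (label == "negative_regulation") "negative_regulation_activation"
  else label
}

#' Expand a pattern match across coordinations
#'
#' Conjoined triggers and conjoined arguments yield the full cross-product
#' of matches ("Smurf1 and Smurf2 degrade and ubiquitinate RhoA" gives
#' 2 triggers x 2 causes). Expanded trigger tokens are re-labeled against
#' the trigger lexicons (a conjunct of "degrade" may be "ubiquitinate",
#' which carries its own event label); conjuncts matching no lexicon are
#' dropped.
#'
#' @param match A pattern match (see [match_dependency_pattern()]).
#' @param sentence The `ls_sentence` it was found in.
#' @param mentions Sentence mentions (for resolving conjoined arguments).
#' @param events Prior events (for event-typed arguments).
#' @param lexicons Lexicon bundle.
#' @return List of matches (the input match always included first).
#' @export
expand_coordinations <- function(match, sentence, mentions, events = list(),
                                 lexicons = default_lexicons()) {
  if (nrow(sentence$deps) == 0) return(list(match))
  trig_toks <- conj_set(sentence, match$trigger_tok)
  trig_opts <- list()
  for (t in trig_toks) {
    lb <- if (t == match$trigger_tok) match$event_label
          else relabel_trigger(t, sentence, match$category, lexicons)
    if (!is.na(lb)) trig_opts[[length(trig_opts) + 1L]] <- list(tok = t, label = lb)
  }
  role_opts <- lapply(match$bindings, function(b) {
    if (b$kind == "mention") {
      head_tok <- mentions[[b$ref]]$tok_end
      toks <- conj_set(sentence, head_tok)
      outs <- list()
      for (tk in toks) {
        r <- resolve_endpoint(tk, "entity", NULL, mentions, events, NULL)
        if (length(r)) outs <- c(outs, r[1])
      }
      key <- vapply(outs, function(x) paste(x$kind, x$ref), "")
      outs[!duplicated(key)]
    } else if (b$kind == "event") {
      ev <- events[[b$ref]]
      # aliased events resolved from other sentences cannot be expanded here
      if (is.null(ev)) return(list(b))
      toks <- conj_set(sentence, ev$trigger_start)
      outs <- list()
      for (tk in toks) {
        r <- resolve_endpoint(tk, "event", NULL, mentions, events, NULL)
        if (length(r)) outs <- c(outs, r[1])
      }
      key <- vapply(outs, function(x) paste(x$kind, x$ref), "")
      outs[!duplicated(key)]
    } else list(b)
  })
  out <- list()
  combos <- expand.grid(c(list(.trig = seq_along(trig_opts)),
                          lapply(role_opts, seq_along)),
                        KEEP.OUT.ATTRS = FALSE)
  for (i in seq_len(nrow(combos))) {
    tr <- trig_opts[[combos$.trig[i]]]
    m <- match
    m$trigger_tok <- tr$tok
    m$trigger <- c(tr$tok, tr$tok)
    m$event_label <- tr$label
    m$category <- category_for_label(tr$label)
    for (rn in names(role_opts))
      m$bindings[[rn]] <- role_opts[[rn]][[combos[i, rn]]]
    refs <- vapply(m$bindings, function(b) paste(b$kind, b$ref), "")
    if (anyDuplicated(refs)) next
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Binarize an n-ary binding participant set
#'
#' Complex-assembly mentions with more than two participants are decomposed
#' into binary binding events. The default is a chain over participants in
#' text order (n-1 events); `mode = "all_pairs"` emits every unordered pair.
#'
#' @param themes Character vector of participant (mention) ids, text order.
#' @param mode `"chain"` (default) or `"all_pairs"`.
#' @return List of length-2 character vectors; empty (with a warning) for a
#'   single participant.
#' @export
binarize_binding <- function(themes, mode = c("chain", "all_pairs")) {
  mode <- match.arg(mode)
  themes <- unique(themes)
  n <- length(themes)
  if (n < 2) {
    warning("binding with a single participant skipped")
    return(list())
  }
  if (n == 2) return(list(themes))
  if (mode == "chain") {
    lapply(seq_len(n - 1L), function(i) themes[c(i, i + 1L)])
  } else {
    out <- list()
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
      out[[length(out) + 1L]] <- themes[c(i, j)]
    out
  }
}

new_event <- function(id, doc_id, sent, label, category, trigger_tok,
                      sentence, args, sign = 1L, rule = NA_character_) {
  structure(list(
    id = id, doc_id = doc_id, sent = as.integer(sent), label = label,
    category = category, sign = as.integer(sign),
    trigger_start = trigger_tok, trigger_end = trigger_tok,
    trigger_text = sentence$tokens$text[trigger_tok],
    args = args, causes = character(0), negated = FALSE,
    rule = rule, coref = FALSE
  ), class = "ls_event")
}

binding_ref_id <- function(b, mentions) {
  if (b$kind == "mention") mentions[[b$ref]]$id else b$ref
}

# which dialect applies to this sentence
active_rules <- function(rules, sentence, categories) {
  dialect <- if (nrow(sentence$deps) > 0) "syntax" else "surface"
  Filter(function(r) r$category %in% categories && r$dialect == dialect, rules)
}

#' Extract simple events from one sentence
#'
#' Step one of the bottom-up strategy: matches all simple-event, binding,
#' hydrolysis and translocation rules (dependency dialect when a parse is
#' available, surface fallback otherwise), expands coordinations, merges
#' duplicate matches, and binarizes binding participant sets. Causes bound
#' by simple-event rules are held on the event (`$causes`) for step two.
#'
#' @param sentence Annotated `ls_sentence`.
#' @param mentions Sentence mentions with ids assigned.
#' @param rules Compiled rules (see [compile_grammar()]).
#' @param lexicons Lexicon bundle.
#' @param doc_id,sent Provenance.
#' @param id_start Integer seed for event ids.
#' @param binding_mode Passed to [binarize_binding()].
#' @return Named list of `ls_event`.
#' @export
extract_simple_events <- function(sentence, mentions, rules,
                                  lexicons = default_lexicons(),
                                  doc_id = "doc", sent = 1L, id_start = 1L,
                                  binding_mode = "chain") {
  srules <- active_rules(rules, sentence, SIMPLE_CATEGORIES)
  matches <- list()
  for (r in srules) {
    ms <- if (r$dialect == "syntax")
      match_dependency_pattern(r, sentence, mentions)
    else match_surface_pattern(r, sentence, mentions)
    for (m in ms)
      matches <- c(matches, expand_coordinations(m, sentence, mentions,
                                                 lexicons = lexicons))
  }
  mention_ids <- vapply(mentions, function(m) m$id, "")

  # group matches into events
  groups <- list()
  for (m in matches) {
    if (!m$category %in% SIMPLE_CATEGORIES) next
    b <- m$bindings
    if (m$category == "binding") {
      if (is.null(b$theme1) || is.null(b$theme2)) next
      th <- c(binding_ref_id(b$theme1, mentions), binding_ref_id(b$theme2, mentions))
      ord <- order(match(th, mention_ids))
      th <- th[ord]
      key <- paste("binding", m$trigger_tok, paste(th, collapse = "+"))
      g <- groups[[key]] %||% list(label = "binding", category = "binding",
                                   trigger_tok = m$trigger_tok, themes = th,
                                   site = NULL, source = NULL,
                                   destination = NULL, causes = character(0),
                                   rule = m$rule)
      if (!is.null(b$cause))
        g$causes <- union(g$causes, binding_ref_id(b$cause, mentions))
      groups[[key]] <- g
    } else {
      if (is.null(b$theme) || b$theme$kind != "mention") next
      th <- mentions[[b$theme$ref]]$id
      key <- paste(m$event_label, m$trigger_tok, th)
      g <- groups[[key]] %||% list(label = m$event_label,
                                   category = m$category,
                                   trigger_tok = m$trigger_tok, themes = th,
                                   site = NULL, source = NULL,
                                   destination = NULL, causes = character(0),
                                   rule = m$rule)
      for (fld in c("site", "source", "destination")) {
        if (!is.null(b[[fld]]) && b[[fld]]$kind == "mention" && is.null(g[[fld]]))
          g[[fld]] <- mentions[[b[[fld]]$ref]]$id
      }
      if (!is.null(b$cause))
        g$causes <- union(g$causes, binding_ref_id(b$cause, mentions))
      groups[[key]] <- g
    }
  }

  events <- list()
  k <- id_start
  for (g in groups) {
    theme_sets <- if (g$category == "binding" && length(g$themes) > 2) {
      suppressWarnings(binarize_binding(g$themes, binding_mode))
    } else list(g$themes)
    for (ts in theme_sets) {
      args <- list(theme = ts)
      for (fld in c("site", "source", "destination"))
        if (!is.null(g[[fld]])) args[[fld]] <- g[[fld]]
      ev <- new_event(sprintf("E%d", k), doc_id, sent, g$label, g$category,
                      g$trigger_tok, sentence, args, rule = g$rule)
      ev$causes <- g$causes
      events[[ev$id]] <- ev
      k <- k + 1L
    }
  }
  events
}

# argument closure of an event (event ids reachable through args)
event_closure <- function(eid, events) {
  out <- character(0)
  frontier <- eid
  while (length(frontier)) {
    nxt <- character(0)
    for (id in frontier) {
      ev <- events[[id]]
      if (is.null(ev)) next
      for (a in unlist(ev$args)) if (a %in% names(events)) nxt <- c(nxt, a)
    }
    nxt <- setdiff(unique(nxt), c(out, eid))
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Extract nested events (regulations and activations)
#'
#' Step two: causes held by simple-event rules become positive regulations;
#' explicit control triggers over events become regulations of the
#' trigger's sign; control triggers whose controlled argument is an entity
#' become activations. Chains (an event controlling a regulation) are found
#' by iterating to a fixpoint. Signs here are the base signs -- polarity
#' correction ([correct_polarity()]) runs afterwards.
#'
#' @param sentence Annotated `ls_sentence`.
#' @param mentions Sentence mentions with ids.
#' @param simple_events Named list from [extract_simple_events()].
#' @param rules Compiled rules.
#' @param lexicons Lexicon bundle.
#' @param doc_id,sent Provenance.
#' @param id_start Integer seed for new event ids.
#' @param event_alias Optional data frame (`tok`, `id`) from coreference.
#' @return Named list of regulation/activation `ls_event`.
#' @export
extract_nested_events <- function(sentence, mentions, simple_events, rules,
                                  lexicons = default_lexicons(),
                                  doc_id = "doc", sent = 1L, id_start = 1L,
                                  event_alias = NULL) {
  nested <- list()
  k <- id_start
  seen <- character(0)
  all_events <- simple_events

  add_reg <- function(base_label, sign, trigger_tok, controller_id,
                      controlled_id, controlled_is_event, rule) {
    if (identical(controller_id, controlled_id)) return(FALSE)
    kindtag <- if (controlled_is_event) "reg" else "act"
    key <- paste(sign, controller_id, controlled_id, kindtag)
    if (key %in% seen) return(FALSE)
    if (controlled_is_event &&
        controller_id %in% c(controlled_id, event_closure(controlled_id, all_events)))
      return(FALSE)
    label <- paste0(if (sign > 0) "positive_" else "negative_",
                    if (controlled_is_event) "regulation" else "activation")
    ev <- new_event(sprintf("E%d", k), doc_id, sent, label,
                    if (sign > 0) "positive_regulation_activation"
                    else "negative_regulation_activation",
                    trigger_tok, sentence,
                    list(controller = controller_id, controlled = controlled_id),
                    sign = sign, rule = rule)
    nested[[ev$id]] <<- ev
    all_events[[ev$id]] <<- ev
    seen <<- c(seen, key)
    k <<- k + 1L
    TRUE
  }

  # causes captured by simple-event rules -> positive regulations
  for (ev in simple_events) {
    for (cid in ev$causes) {
      add_reg("positive_regulation", 1L, ev$trigger_start, cid, ev$id,
              TRUE, "cause-argument")
    }
  }

  rrules <- active_rules(rules, sentence, REGULATION_CATEGORIES)
  for (round in 1:3) {
    added <- FALSE
    for (r in rrules) {
      ms <- if (r$dialect == "syntax")
        match_dependency_pattern(r, sentence, mentions, all_events, event_alias)
      else match_surface_pattern(r, sentence, mentions)
      ms <- unlist(lapply(ms, expand_coordinations, sentence = sentence,
                          mentions = mentions, events = all_events,
                          lexicons = lexicons), recursive = FALSE)
      for (m in ms) {
        b <- m$bindings
        if (is.null(b$controller) || is.null(b$controlled)) next
        sign <- if (m$event_label == "positive_regulation") 1L else -1L
        controller_id <- binding_ref_id(b$controller, mentions)
        controlled_id <- binding_ref_id(b$controlled, mentions)
        controlled_is_event <- b$controlled$kind == "event"
        if (add_reg(m$event_label, sign, m$trigger_tok, controller_id,
                    controlled_id, controlled_is_event, m$rule))
          added <- TRUE
      }
    }
    if (!added) break
  }
  nested
}

#' Detect whether an event is negated
#'
#' A negation cue (configurable lexicon) negates the event when it attaches
#' to the trigger or to a verb governing the trigger through xcomp/aux
#' chains ("did not block", "fails to activate"). Double negation cancels
#' by parity ("not unable to bind" is not negated).
#'
#' @param event An `ls_event`.
#' @param sentence Its sentence.
#' @param negation Character vector of cues (see [load_negation_lexicon()]).
#' @return Logical flag.
#' @export
detect_negation <- function(event, sentence,
                            negation = default_lexicons()$negation) {
  if (nrow(sentence$deps) == 0) return(FALSE)
  tk <- sentence$tokens
  governors <- event$trigger_start
  u <- event$trigger_start
  repeat {
    p <- dep_parent(sentence$deps, u, c("xcomp", "aux", "aux:pass", "cop"))
    p <- p[p != 0]
    if (length(p) == 0 || p[1] %in% governors) break
    governors <- c(governors, p[1])
    u <- p[1]
  }
  cues <- 0L
  low <- tolower(tk$text)
  # governors themselves that are cues (excluding the trigger)
  cues <- cues + sum(low[setdiff(governors, event$trigger_start)] %in% negation)
  # dependents of governors that are cues
  dep_toks <- sentence$deps$dep[sentence$deps$head %in% governors]
  cues <- cues + sum(low[dep_toks] %in% negation)
  (cues %% 2L) == 1L
}
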