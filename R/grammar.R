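# The rule-template engine. Templates come in two dialects:
#  * "syntax"  -- patterns over the dependency tree: per-role paths of
#                 labeled-edge traversals from a lexicon-matched trigger
#                 token, with direction, optional hops, label disjunction
#                 and lexical constraints on intermediate nodes;
#  * "surface" -- linear token-window patterns over tokens and mentions.
# A template is parameterized by an event label and its trigger lexicon;
# compilation instantiates one executable rule per (template, label).

# Stanford-style -> UD label normalization
DEP_ALIASES <- c(
  nsubjpass = "nsubj:pass", dobj = "obj", auxpass = "aux:pass",
  rcmod = "acl:relcl", agent = "obl:by", poss = "nmod:poss", nn = "compound",
  prep_of = "nmod:of", prep_by = "nmod:by", prep_with = "nmod:with",
  prep_to = "nmod:to", prep_in = "nmod:in", prep_from = "nmod:from",
  prep_into = "nmod:into", prep_at = "nmod:at", prep_on = "nmod:on",
  prep_between = "nmod:between"
)

KNOWN_DEP_LABELS <- c(
  "root", "nsubj", "nsubj:pass", "obj", "iobj", "csubj",
  "obl", "obl:by", "obl:to", "obl:with", "obl:in", "obl:from", "obl:into",
  "obl:at", "obl:on", "obl:upon", "obl:npmod",
  "nmod", "nmod:of", "nmod:by", "nmod:to", "nmod:with", "nmod:in",
  "nmod:from", "nmod:into", "nmod:at", "nmod:on", "nmod:between", "nmod:poss",
  "acl", "acl:relcl", "appos", "compound", "amod", "advmod", "conj", "cc",
  "det", "case", "mark", "aux", "aux:pass", "cop", "xcomp", "ccomp", "advcl",
  "punct", "nummod", "expl", "parataxis", "dep"
)

normalize_dep_label <- function(label) {
  out <- DEP_ALIASES[label]
  ifelse(is.na(out), label, out)
}

#' Construct a rule template
#'
#' @param name Unique template name.
#' @param category One of the grammar categories: `entity`,
#'   `generic_entity`, `modification`, `mutant`, `simple_event`, `binding`,
#'   `hydrolysis`, `translocation`, `positive_regulation_activation`,
#'   `negative_regulation_activation`.
#' @param dialect `"syntax"` (dependency pattern) or `"surface"` (token
#'   pattern).
#' @param trigger_pos For syntax templates: POS class of the trigger
#'   (`"verb"`, `"noun"` or `"any"`).
#' @param roles Named list; each element `list(path=, required=, kind=,
#'   types=)`. `path` is the dependency-path DSL (see Details); `kind` is
#'   `"entity"`, `"event"` or `"either"`; `types` optionally restricts
#'   entity types.
#' @param forbid Character vector of paths that must NOT reach any token for
#'   the rule to fire (used to disambiguate nominalization variants).
#' @param pattern For surface templates: the token-pattern DSL string.
#'
#' @details Path DSL: whitespace-separated steps. `>label` descends an edge,
#' `<label` ascends; `|` separates alternative labels; a `~w1|w2` suffix
#' constrains the surface form/lemma of the node reached; a trailing `?`
#' makes the step optional. Example:
#' `"<obj~cause|causes|caused >nsubj"`.
#'
#' Surface DSL: whitespace-separated items. `T` matches a trigger-lexicon
#' token; `E:role` (or `E:role:type`) matches an entity mention and binds
#' it; `W:a|b` matches a literal token; `R:regex` (or `R:regex:role`)
#' matches a token against a regular expression; `K:type` matches a
#' KB-derived mention of the given entity type. `W`/`R` items accept a
#' trailing `?`.
#' @return An object of class `ls_template`.
#' @export
rule_template <- function(name, category, dialect, trigger_pos = "any",
                          roles = list(), forbid = character(0),
                          pattern = NULL) {
  categories <- c("entity", "generic_entity", "modification", "mutant",
                  "simple_event", "binding", "hydrolysis", "translocation",
                  "positive_regulation_activation",
                  "negative_regulation_activation")
  stopifnot(category %in% categories, dialect %in% c("syntax", "surface"))
  if (dialect == "syntax" && length(roles) == 0)
    stop("syntax template '", name, "' declares no roles")
  if (dialect == "surface" && is.null(pattern))
    stop("surface template '", name, "' has no pattern")
  structure(list(name = name, category = category, dialect = dialect,
                 trigger_pos = trigger_pos, roles = roles, forbid = forbid,
                 pattern = pattern),
            class = "ls_template")
}

# parse one path string into a list of steps
parse_path <- function(path) {
  steps <- strsplit(trimws(path), "\\s+")[[1]]
  lapply(steps, function(s) {
    optional <- grepl("\\?$", s)
    s <- sub("\\?$", "", s)
    m <- regmatches(s, regexec("^([<>])([^~]+)(~(.+))?$", s))[[1]]
    if (length(m) == 0) stop("bad path step: ", s)
    labels <- normalize_dep_label(strsplit(m[3], "|", fixed = TRUE)[[1]])
    bad <- setdiff(labels, KNOWN_DEP_LABELS)
    if (length(bad))
      stop("unknown dependency label(s) in pattern: ", paste(bad, collapse = ", "))
    lex <- if (nzchar(m[5])) tolower(strsplit(m[5], "|", fixed = TRUE)[[1]]) else NULL
    list(dir = if (m[2] == ">") "down" else "up", labels = labels,
         lex = lex, optional = optional)
  })
}

parse_surface <- function(pattern) {
  items <- strsplit(trimws(pattern), "\\s+")[[1]]
  lapply(items, function(it) {
    optional <- grepl("\\?$", it)
    it <- sub("\\?$", "", it)
    if (it == "T") return(list(kind = "trigger", optional = FALSE))
    p <- strsplit(it, ":", fixed = TRUE)[[1]]
    switch(p[1],
      E = list(kind = "entity", role = p[2],
               type = if (length(p) >= 3) p[3] else NULL, optional = FALSE),
      W = list(kind = "word", words = tolower(strsplit(p[2], "|", fixed = TRUE)[[1]]),
               optional = optional),
      R = list(kind = "regex", regex = p[2],
               role = if (length(p) >= 3) p[3] else NULL, optional = optional),
      K = list(kind = "kb", type = p[2], optional = FALSE),
      stop("bad surface item: ", it))
  })
}

#' Compile a template with a trigger lexicon into an executable rule
#'
#' Compilation is total: all errors (unknown dependency labels, an empty
#' lexicon for an event category) surface here, never at match time.
#'
#' @param template An `ls_template`.
#' @param lexicon Trigger lexicon (see [load_trigger_lexicon()]); may be
#'   `NULL` for entity-side categories whose patterns carry no `T` item.
#' @param event_label Event label instantiating the template (defaults to
#'   the category's single label where unambiguous).
#' @return Executable rule of class `ls_rule`.
#' @export
compile_template <- function(template, lexicon = NULL, event_label = NA) {
  needs_lexicon <- template$dialect == "syntax" ||
    any(vapply(parse_surface(template$pattern %||% "W:x"), function(i)
      identical(i$kind, "trigger"), TRUE))
  trigger_forms <- character(0)
  trigger_lemmas <- character(0)
  if (needs_lexicon && template$category %in%
      c("simple_event", "binding", "hydrolysis", "translocation",
        "positive_regulation_activation", "negative_regulation_activation")) {
    if (is.na(event_label)) stop("event template needs an event_label")
    d <- lexicon[[event_label]]
    if (is.null(d) || nrow(d) == 0)
      stop("empty trigger lexicon for event label '", event_label, "'")
    keep <- if (template$dialect == "syntax" && template$trigger_pos != "any")
      d$pos == template$trigger_pos else rep(TRUE, nrow(d))
    if (!any(keep))
      stop("lexicon for '", event_label, "' has no ", template$trigger_pos,
           " forms required by template '", template$name, "'")
    trigger_forms <- d$form[keep]
    trigger_lemmas <- unique(d$lemma[keep])
  }
  compiled_roles <- lapply(template$roles, function(r) {
    r$steps <- parse_path(r$path)
    r$required <- isTRUE(r$required)
    r$kind <- r$kind %||% "entity"
    r
  })
  structure(list(
    name = template$name, category = template$category,
    dialect = template$dialect, event_label = event_label,
    trigger_pos = template$trigger_pos,
    trigger_forms = tolower(trigger_forms), trigger_lemmas = trigger_lemmas,
    roles = compiled_roles,
    forbid = lapply(template$forbid, parse_path),
    surface = if (template$dialect == "surface") parse_surface(template$pattern) else NULL
  ), class = "ls_rule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compile a whole grammar against the lexicon bundle
#'
#' Event-category templates are instantiated once per event label of their
#' category (simple-event templates across all PTM addition/removal types).
#'
#' @param grammar List of `ls_template` (see [default_grammar()]).
#' @param lexicons Lexicon bundle (see [default_lexicons()]).
#' @return List of `ls_rule`.
#' @export
compile_grammar <- function(grammar, lexicons) {
  rules <- list()
  for (tpl in grammar) {
    labels <- category_labels(tpl$category)
    if (length(labels) == 0) {
      rules[[length(rules) + 1L]] <- compile_template(tpl, lexicons$triggers)
    } else {
      for (lb in labels) {
        ok <- tryCatch(
          compile_template(tpl, lexicons$triggers, lb),
          error = function(e) {
            # a label lacking e.g. noun forms simply skips noun templates
            if (grepl("has no (verb|noun) forms", conditionMessage(e))) NULL
            else stop(e)
          })
        if (!is.null(ok)) rules[[length(rules) + 1L]] <- ok
      }
    }
  }
  rules
}

# --- dependency-pattern matching -------------------------------------------

dep_children <- function(deps, u, labels) {
  deps$dep[deps$head == u & normalize_dep_label(deps$label) %in% labels]
}
dep_parent <- function(deps, u, labels) {
  deps$head[deps$dep == u & normalize_dep_label(deps$label) %in% labels]
}

token_matches_lex <- function(tokens, idx, lex) {
  tolower(tokens$text[idx]) %in% lex |
    (!is.na(tokens$lemma[idx]) & tolower(tokens$lemma[idx]) %in% lex)
}

walk_path <- function(sentence, from, steps) {
  frontier <- from
  for (st in steps) {
    nxt <- integer(0)
    for (u in frontier) {
      v <- if (st$dir == "down") dep_children(sentence$deps, u, st$labels)
           else dep_parent(sentence$deps, u, st$labels)
      v <- v[v != 0]
      nxt <- c(nxt, v)
    }
    nxt <- unique(nxt)
    if (!is.null(st$lex) && length(nxt))
      nxt <- nxt[token_matches_lex(sentence$tokens, nxt, st$lex)]
    frontier <- if (st$optional) unique(c(frontier, nxt)) else nxt
    if (length(frontier) == 0) return(integer(0))
  }
  setdiff(frontier, from)
}

pos_class <- function(pos) {
  ifelse(pos %in% c("VERB", "AUX"), "verb",
         ifelse(pos %in% c("NOUN", "PROPN"), "noun", "other"))
}

# resolve a path endpoint token to a mention / event binding
resolve_endpoint <- function(tok, kind, types, mentions, events, event_alias) {
  out <- list()
  if (kind %in% c("entity", "either")) {
    cand <- which(vapply(mentions, function(m)
      m$tok_start <= tok && tok <= m$tok_end, TRUE))
    if (length(cand)) {
      # prefer the mention headed by (ending at) the token, then longest
      heads <- vapply(mentions[cand], function(m) m$tok_end == tok, TRUE)
      pick <- if (any(heads)) cand[heads][1] else cand[1]
      m <- mentions[[pick]]
      if (is.null(types) || m$type %in% types)
        out <- c(out, list(list(kind = "mention", ref = pick)))
    }
  }
  if (kind %in% c("event", "either") && length(out) == 0) {
    for (eid in names(events)) {
      ev <- events[[eid]]
      if (ev$trigger_start <= tok && tok <= ev$trigger_end)
        out <- c(out, list(list(kind = "event", ref = eid)))
    }
    if (length(out) == 0 && !is.null(event_alias)) {
      hit <- event_alias$tok == tok
      if (any(hit))
        out <- c(out, list(list(kind = "event", ref = event_alias$id[hit][1])))
    }
  }
  out
}

#' Match a compiled dependency rule against a sentence
#'
#' Finds trigger tokens by lexicon + POS class, walks each role's path, and
#' binds endpoints to entity mentions (or previously extracted events, for
#' nested rules). Returns one match per combination of role bindings.
#'
#' @param rule An `ls_rule` of dialect "syntax".
#' @param sentence An annotated `ls_sentence`.
#' @param mentions List of `ls_mention` for the sentence.
#' @param events Named list of prior `ls_event` (for event-typed roles).
#' @param event_alias Optional data frame (`tok`, `id`) mapping anaphoric
#'   tokens to resolved event ids (used by coreference re-extraction).
#' @return List of pattern matches: `list(rule, category, event_label,
#'   trigger_tok, trigger, bindings)` where `bindings` maps role to a
#'   single binding `list(kind, ref)`.
#' @export
match_dependency_pattern <- function(rule, sentence, mentions,
                                     events = list(), event_alias = NULL) {
  stopifnot(rule$dialect == "syntax")
  tk <- sentence$tokens
  if (nrow(sentence$deps) == 0) return(list())
  matches <- list()
  trig_ok <- token_matches_lex(tk, seq_len(nrow(tk)), rule$trigger_forms)
  if (rule$trigger_pos != "any" && !anyNA(tk$pos))
    trig_ok <- trig_ok & pos_class(tk$pos) == rule$trigger_pos
  for (t in which(trig_ok)) {
    if (length(rule$forbid)) {
      blocked <- any(vapply(rule$forbid, function(steps)
        length(walk_path(sentence, t, steps)) > 0, TRUE))
      if (blocked) next
    }
    role_bind <- list()
    ok <- TRUE
    for (rn in names(rule$roles)) {
      r <- rule$roles[[rn]]
      ends <- walk_path(sentence, t, r$steps)
      binds <- list()
      for (e in ends)
        binds <- c(binds, resolve_endpoint(e, r$kind, r$types, mentions,
                                           events, event_alias))
      # drop duplicate bindings
      if (length(binds)) {
        key <- vapply(binds, function(b) paste(b$kind, b$ref), "")
        binds <- binds[!duplicated(key)]
      }
      # an "either" role that can resolve to an event is an event argument;
      # entity readings reached via optional hops are discarded
      if (identical(r$kind, "either") && length(binds)) {
        is_ev <- vapply(binds, function(b) b$kind == "event", TRUE)
        if (any(is_ev)) binds <- binds[is_ev]
      }
      if (r$required && length(binds) == 0) { ok <- FALSE; break }
      role_bind[[rn]] <- binds
    }
    if (!ok) next
    # cross-product over roles with >=1 binding (empty optional roles drop out)
    role_bind <- role_bind[vapply(role_bind, length, 0L) > 0]
    combos <- if (length(role_bind) == 0) list(list()) else {
      idx <- expand.grid(lapply(role_bind, seq_along), KEEP.OUT.ATTRS = FALSE)
      lapply(seq_len(nrow(idx)), function(i)
        stats::setNames(lapply(names(role_bind), function(rn)
          role_bind[[rn]][[idx[i, rn]]]), names(role_bind)))
    }
    for (cmb in combos) {
      # identical-path pair roles (e.g. two binding themes) must differ
      refs <- vapply(cmb, function(b) paste(b$kind, b$ref), "")
      if (anyDuplicated(refs)) next
      matches[[length(matches) + 1L]] <- list(
        rule = rule$name, category = rule$category,
        event_label = rule$event_label, trigger_tok = t,
        trigger = c(t, t), bindings = cmb)
    }
  }
  matches
}

#' Match a compiled surface rule against a sentence
#'
#' Linear left-to-right token-window matching; an `E:` item consumes a whole
#' mention span, `T` a trigger-lexicon token, `W:`/`R:` single tokens.
#' Matches never overlap for the same rule (leftmost-longest scan).
#'
#' @inheritParams match_dependency_pattern
#' @param kb Optional KB index for `K:` items.
#' @return List of pattern matches (same shape as
#'   [match_dependency_pattern()]; token-bound roles have
#'   `kind = "tokens"`).
#' @export
match_surface_pattern <- function(rule, sentence, mentions, kb = NULL) {
  stopifnot(rule$dialect == "surface")
  tk <- sentence$tokens
  n <- nrow(tk)
  if (n == 0) return(list())
  low <- tolower(tk$text)
  mention_at <- function(pos, type = NULL) {
    for (i in seq_along(mentions)) {
      m <- mentions[[i]]
      if (m$tok_start == pos && (is.null(type) || m$type == type)) return(i)
    }
    NA_integer_
  }
  matches <- list()
  pos <- 1L
  while (pos <= n) {
    state <- try_surface(rule, tk, low, mentions, mention_at, pos)
    if (!is.null(state)) {
      matches[[length(matches) + 1L]] <- list(
        rule = rule$name, category = rule$category,
        event_label = rule$event_label,
        trigger_tok = state$trigger, trigger = c(state$trigger, state$trigger),
        bindings = state$bindings)
      pos <- state$end + 1L
    } else pos <- pos + 1L
  }
  matches
}

try_surface <- function(rule, tk, low, mentions, mention_at, start) {
  pos <- start
  trigger <- NA_integer_
  bindings <- list()
  for (it in rule$surface) {
    if (pos > nrow(tk)) {
      if (isTRUE(it$optional)) next
      return(NULL)
    }
    if (it$kind == "trigger") {
      if (!(low[pos] %in% rule$trigger_forms)) return(NULL)
      trigger <- pos; pos <- pos + 1L
    } else if (it$kind == "word") {
      if (low[pos] %in% it$words) pos <- pos + 1L
      else if (!it$optional) return(NULL)
    } else if (it$kind == "regex") {
      if (grepl(it$regex, tk$text[pos])) {
        if (!is.null(it$role))
          bindings[[it$role]] <- list(kind = "tokens", ref = pos)
        pos <- pos + 1L
      } else if (!it$optional) return(NULL)
    } else if (it$kind == "entity") {
      mi <- mention_at(pos, it$type)
      if (is.na(mi)) return(NULL)
      bindings[[it$role]] <- list(kind = "mention", ref = mi)
      pos <- mentions[[mi]]$tok_end + 1L
    } else if (it$kind == "kb") {
      mi <- mention_at(pos, it$type)
      if (is.na(mi)) return(NULL)
      bindings[["entity"]] <- list(kind = "mention", ref = mi)
      pos <- mentions[[mi]]$tok_end + 1L
    }
  }
  list(trigger = trigger, bindings = bindings, end = pos - 1L)
}

#' Rule-template inventory by category
#'
#' @param grammar List of `ls_template`; defaults to the shipped grammar.
#' @return Data frame with columns `category`, `syntax`, `surface`, `total`,
#'   one row per category plus the entity/event subtotals and the grand
#'   total.
#' @export
grammar_inventory <- function(grammar = default_grammar()) {
  cats <- c("entity", "generic_entity", "modification", "mutant",
            "simple_event", "binding", "hydrolysis", "translocation",
            "positive_regulation_activation", "negative_regulation_activation")
  tab <- data.frame(category = cats, syntax = 0L, surface = 0L)
  for (tpl in grammar) {
    i <- match(tpl$category, cats)
    if (tpl$dialect == "syntax") tab$syntax[i] <- tab$syntax[i] + 1L
    else tab$surface[i] <- tab$surface[i] + 1L
  }
  ent <- cats[1:4]
  evt <- cats[5:10]
  tab <- rbind(tab,
    data.frame(category = "total_entities",
               syntax = sum(tab$syntax[tab$category %in% ent]),
               surface = sum(tab$surface[tab$category %in% ent])),
    data.frame(category = "total_events",
               syntax = sum(tab$syntax[tab$category %in% evt]),
               surface = sum(tab$surface[tab$category %in% evt])),
    data.frame(category = "total",
               syntax = sum(tab$syntax[1:10]), surface = sum(tab$surface[1:10])))
  tab$total <- tab$syntax + tab$surface
  tab
}

# --- grammar file I/O -------------------------------------------------------

#' Read a grammar from a YAML file
#'
#' Each entry: `name`, `category`, `dialect`, plus either `roles` (mapping
#' role -> `{path, required, kind, types}`) with optional `trigger_pos` and
#' `forbid`, or `pattern` for surface templates.
#' @param path YAML file path.
#' @return List of `ls_template`.
#' @export
load_grammar <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    roles <- lapply(x$roles %||% list(), function(r)
      list(path = r$path, required = isTRUE(r$required),
           kind = r$kind %||% "entity", types = r$types))
    rule_template(x$name, x$category, x$dialect,
                  trigger_pos = x$trigger_pos %||% "any",
                  roles = roles,
                  forbid = as.character(x$forbid %||% character(0)),
                  pattern = x$pattern)
  })
}

#' Write a grammar to YAML
#' @param grammar List of `ls_template`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_grammar <- function(grammar, path) {
  ser <- lapply(grammar, function(t) {
    out <- list(name = t$name, category = t$category, dialect = t$dialect)
    if (t$dialect == "syntax") {
      out$trigger_pos <- t$trigger_pos
      out$roles <- lapply(t$roles, function(r) {
        rr <- list(path = r$path, required = isTRUE(r$required),
                   kind = r$kind %||% "entity")
        if (!is.null(r$types)) rr$types <- r$types
        rr
      })
      if (length(t$forbid)) out$forbid <- as.list(t$forbid)
    } else out$pattern <- t$pattern
    out
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}
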