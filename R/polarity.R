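# Polarity correction for nested events: the sign stated by the trigger
# ("enhances" = positive) is flipped once per polarity-reversal word found
# on the dependency path connecting the trigger to its arguments, including
# adjectival modifiers hanging off that path ("decreased PTPN13 expression
# enhances EphrinB1 phosphorylation" is a negative regulation).

# tokens on the tree path between two tokens (inclusive), via the LCA
tree_path <- function(sentence, a, b) {
  parent <- integer(nrow(sentence$tokens))
  parent[sentence$deps$dep] <- sentence$deps$head
  anc <- function(v) {
    out <- v
    while (parent[v] != 0) { v <- parent[v]; out <- c(out, v) }
    out
  }
  aa <- anc(a); bb <- anc(b)
  lca <- intersect(aa, bb)[1]
  if (is.na(lca)) return(unique(c(aa, bb)))
  c(aa[seq_len(match(lca, aa))], bb[seq_len(match(lca, bb) - 1L)])
}

arg_head_token <- function(ref, mentions_by_id, events, sent) {
  if (ref %in% names(events)) {
    ev <- events[[ref]]
    # arguments resolved across sentences have no in-tree head here
    if (!identical(ev$sent, sent)) return(NA_integer_)
    return(ev$trigger_start)
  }
  m <- mentions_by_id[[ref]]
  if (is.null(m)) return(NA_integer_)
  if (!identical(m$sent, sent)) return(NA_integer_)
  m$tok_end
}

#' Collect polarity-reversal cues for a nested event
#'
#' Scans the dependency path connecting the event trigger to each of its
#' arguments, counting lexicon hits among the intermediate nodes, plus any
#' adjectival modifiers attached to path nodes. Cues inside an argument's
#' own subtree (off the connecting path) are not considered.
#'
#' @param event A regulation/activation `ls_event`.
#' @param sentence Its sentence.
#' @param mentions_by_id Named list of mentions (id -> `ls_mention`).
#' @param events Named list of all events (for event-typed arguments).
#' @param polarity Polarity lexicon data frame (see
#'   [load_polarity_lexicon()]).
#' @return Integer vector of cue token indices (unique).
#' @export
collect_reversal_cues <- function(event, sentence, mentions_by_id,
                                  events = list(),
                                  polarity = default_lexicons()$polarity) {
  if (nrow(sentence$deps) == 0) return(integer(0))
  arg_refs <- unlist(event$args, use.names = FALSE)
  heads <- vapply(arg_refs, arg_head_token, 0L,
                  mentions_by_id = mentions_by_id, events = events,
                  sent = event$sent)
  heads <- heads[!is.na(heads)]
  if (length(heads) == 0) return(integer(0))
  nodes <- unique(unlist(lapply(heads, function(h)
    tree_path(sentence, event$trigger_start, h))))
  low <- tolower(sentence$tokens$text)
  lex <- polarity$form
  interior <- setdiff(nodes, c(event$trigger_start, heads))
  cues <- interior[low[interior] %in% lex]
  amods <- sentence$deps$dep[sentence$deps$head %in% nodes &
                             normalize_dep_label(sentence$deps$label) == "amod"]
  cues <- unique(c(cues, amods[low[amods] %in% lex]))
  sort(cues)
}

#' Apply polarity correction to a nested event
#'
#' Final sign = base sign x (-1)^(number of cues): an odd number of
#' reversal words on the trigger-argument path flips the sign, an even
#' number restores it. Simple events are returned unchanged.
#'
#' @param event An `ls_event`.
#' @param cues Cue token indices from [collect_reversal_cues()].
#' @return The event with final `sign` and correspondingly renamed
#'   `label` (positive_/negative_ regulation or activation).
#' @export
correct_polarity <- function(event, cues) {
  if (!event$category %in% REGULATION_CATEGORIES) return(event)
  flip <- (-1L) ^ (length(cues))
  event$sign <- as.integer(event$sign * flip)
  base <- sub("^(positive|negative)_", "", event$label)
  event$label <- paste0(if (event$sign > 0) "positive_" else "negative_", base)
  event$category <- paste0(if (event$sign > 0) "positive" else "negative",
                           "_regulation_activation")
  event
}
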