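# Trigger, polarity-reversal and negation lexicons. Trigger lexicons are
# stored as (label, lemma, pos) rows; verb lemmas are expanded to their
# inflected forms (3sg, past/participle, gerund) and nouns to plurals at
# load time, with a small irregular table.

EVENT_LABELS_ADDITION <- c("phosphorylation", "ubiquitination", "hydroxylation",
                           "sumoylation", "glycosylation", "acetylation",
                           "farnesylation", "ribosylation", "methylation")
EVENT_LABELS_REMOVAL <- paste0("de", EVENT_LABELS_ADDITION)
SIMPLE_EVENT_LABELS <- c(EVENT_LABELS_ADDITION, EVENT_LABELS_REMOVAL)

IRREGULAR_VERBS <- list(
  bind = c("bind", "binds", "bound", "binding"),
  lead = c("lead", "leads", "led", "leading"),
  undergo = c("undergo", "undergoes", "underwent", "undergone", "undergoing")
)

inflect_verb <- function(lemma) {
  if (!is.null(IRREGULAR_VERBS[[lemma]])) return(IRREGULAR_VERBS[[lemma]])
  if (grepl("e$", lemma)) {
    c(lemma, paste0(lemma, "s"), paste0(lemma, "d"),
      paste0(sub("e$", "", lemma), "ing"))
  } else if (grepl("[^aeiou]y$", lemma)) {
    c(lemma, paste0(sub("y$", "ies", lemma)), paste0(sub("y$", "ied", lemma)),
      paste0(lemma, "ing"))
  } else {
    c(lemma, paste0(lemma, "s"), paste0(lemma, "ed"), paste0(lemma, "ing"))
  }
}

inflect_noun <- function(lemma) {
  pl <- if (grepl("(s|x|ch|sh)$", lemma)) paste0(lemma, "es") else paste0(lemma, "s")
  c(lemma, pl)
}

#' Load a trigger lexicon from TSV
#'
#' Columns: `label` (event label or category), `lemma`, `pos`
#' (`verb`/`noun`). Verb lemmas are expanded to inflected forms and noun
#' lemmas to plurals, so "phosphorylate" covers
#' phosphorylate/phosphorylates/phosphorylated/phosphorylating.
#'
#' @param con Path or character vector of TSV lines (`#` comments allowed).
#' @return A trigger lexicon: named list label -> data frame (`form`,
#'   `lemma`, `pos`), class `ls_lexicon`.
#' @export
load_trigger_lexicon <- function(con) {
  lines <- if (length(con) == 1 && file.exists(con))
    readLines(con, encoding = "UTF-8") else as.character(con)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) stop("trigger lexicon rows need 3 columns: ", ln)
    label <- f[1]; lemma <- tolower(f[2]); pos <- f[3]
    forms <- switch(pos, verb = inflect_verb(lemma), noun = inflect_noun(lemma),
                    stop("pos must be 'verb' or 'noun': ", ln))
    out[[label]] <- rbind(out[[label]],
                          data.frame(form = forms, lemma = lemma, pos = pos,
                                     stringsAsFactors = FALSE))
  }
  out <- lapply(out, function(d) d[!duplicated(d$form), , drop = FALSE])
  structure(out, class = "ls_lexicon")
}

#' Load the polarity-reversal lexicon (TSV: form, pos, weight)
#' @param con Path or character lines.
#' @return Data frame with columns `form`, `pos`, `weight`.
#' @export
load_polarity_lexicon <- function(con) {
  lines <- if (length(con) == 1 && file.exists(con))
    readLines(con, encoding = "UTF-8") else as.character(con)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(form = tolower(rows[, 1]), pos = rows[, 2],
             weight = as.integer(rows[, 3]), stringsAsFactors = FALSE)
}

#' Load the negation-cue lexicon (one form per line)
#' @param con Path or character lines.
#' @return Character vector of lower-cased cues.
#' @export
load_negation_lexicon <- function(con) {
  lines <- if (length(con) == 1 && file.exists(con))
    readLines(con, encoding = "UTF-8") else as.character(con)
  tolower(trimws(lines[!grepl("^\\s*(#|$)", lines)]))
}

lexicon_dir <- function() {
  system.file("extdata", "lexicons", package = "litsignal", mustWork = TRUE)
}

#' Load the default lexicon bundle shipped with the package
#'
#' @return List with elements `triggers` (see [load_trigger_lexicon()]),
#'   `polarity` and `negation`.
#' @export
default_lexicons <- function() {
  d <- lexicon_dir()
  list(triggers = load_trigger_lexicon(file.path(d, "triggers.tsv")),
       polarity = load_polarity_lexicon(file.path(d, "polarity.tsv")),
       negation = load_negation_lexicon(file.path(d, "negation.tsv")))
}

# forms of a label restricted to a POS class ("verb", "noun" or "any")
lexicon_forms <- function(lexicon, label, pos = "any") {
  d <- lexicon[[label]]
  if (is.null(d)) return(character(0))
  if (pos == "any") d$form else d$form[d$pos == pos]
}

# event labels that belong to a grammar category
category_labels <- function(category) {
  switch(category,
    simple_event = SIMPLE_EVENT_LABELS,
    binding = "binding",
    hydrolysis = "hydrolysis",
    translocation = "translocation",
    positive_regulation_activation = "positive_regulation",
    negative_regulation_activation = "negative_regulation",
    character(0))
}
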