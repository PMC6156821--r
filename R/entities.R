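# Entity recognition and grounding against knowledge-base dictionaries,
# plus attachment of mutation / PTM / wild-type states to entity mentions.

PTM_SUBTYPES <- c("phosphorylation", "ubiquitination", "hydroxylation",
                  "sumoylation", "glycosylation", "acetylation",
                  "farnesylation", "ribosylation", "methylation")

ENTITY_TYPES <- c("gene_or_gene_product", "family", "simple_chemical",
                  "site", "cellular_component")

# namespace priority used when ordering groundings (proteins before family
# DBs, curated chemical DB before the metabolome DB); configurable via
# the `priority` argument of ground().
KB_PRIORITY <- c("uniprot", "interpro", "chebi", "hmdb", "go", "uaz")

#' Normalize an entity name to its token-key form
#'
#' Names are tokenized with the same biomedical tokenizer used for text
#' (dashes and slashes split), joined with single spaces and lower-cased, so
#' "HP1-gamma" in a KB matches the token sequence "HP1 - gamma" in text.
#' @param name Character vector of names.
#' @return Character vector of normalized keys.
#' @keywords internal
kb_key <- function(name) {
  vapply(name, function(x) {
    tolower(paste(tokenize(x)$text, collapse = " "))
  }, "", USE.NAMES = FALSE)
}

#' Load a knowledge-base dictionary from TSV
#'
#' Expected columns (tab-separated, `#` comments allowed):
#' `namespace`, `identifier`, `canonical`, `synonyms` (pipe-separated, may be
#' empty) and `entity_type`. Synonyms are deduplicated case-insensitively.
#'
#' @param con Path to a TSV file or a character vector of lines.
#' @return A KB index: list with `entries` (list of KBEntry records) and a
#'   hashed lookup from normalized name to entry positions. Supports exact
#'   and case-insensitive lookup via [kb_lookup()].
#' @export
load_kb <- function(con) {
  lines <- if (length(con) == 1 && file.exists(con))
    readLines(con, encoding = "UTF-8") else as.character(con)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  entries <- list()
  seen_type <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) stop("KB row must have 5 tab-separated columns: ", ln)
    syn <- if (nzchar(f[4])) strsplit(f[4], "|", fixed = TRUE)[[1]] else character(0)
    syn <- syn[!duplicated(tolower(syn))]
    if (!f[5] %in% ENTITY_TYPES)
      stop("unknown entity_type '", f[5], "' in KB row: ", ln)
    if (!nzchar(f[2])) stop("empty identifier in KB row: ", ln)
    key <- paste(f[1], f[2], sep = ":")
    if (!is.null(seen_type[[key]]) && seen_type[[key]] != f[5])
      stop("duplicate KB id ", key, " with conflicting entity types")
    seen_type[[key]] <- f[5]
    entries[[length(entries) + 1L]] <- list(
      namespace = f[1], identifier = f[2], canonical = f[3],
      synonyms = syn, entity_type = f[5])
  }
  lookup <- new.env(parent = emptyenv())
  maxlen <- 1L
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    for (nm in unique(c(e$canonical, e$synonyms))) {
      k <- kb_key(nm)
      maxlen <- max(maxlen, length(strsplit(k, " ", fixed = TRUE)[[1]]))
      lookup[[k]] <- c(lookup[[k]], i)
    }
  }
  structure(list(entries = entries, lookup = lookup, max_ngram = maxlen),
            class = "ls_kb")
}

#' Look up a name in a KB index
#'
#' @param index KB index from [load_kb()].
#' @param name Name to look up.
#' @param exact If `TRUE`, only entries carrying the name with identical
#'   case are returned; default is case-insensitive.
#' @return List of matching KBEntry records (possibly several, e.g. a name
#'   shared by a protein and a family).
#' @export
kb_lookup <- function(index, name, exact = FALSE) {
  idx <- index$lookup[[kb_key(name)]]
  if (is.null(idx)) return(list())
  hits <- index$entries[idx]
  if (exact) {
    hits <- Filter(function(e) name %in% c(e$canonical, e$synonyms), hits)
  }
  hits
}

#' Path to the synthetic knowledge base shipped with the package
#'
#' A small dictionary (UniProt-, InterPro-, ChEBI-, HMDB- and GO-namespaced
#' entries) covering the proteins, chemicals and cellular components used by
#' the synthetic corpus. Identifiers are illustrative fixtures, not a
#' curated resource.
#' @return File path.
#' @export
default_kb_path <- function() {
  system.file("extdata", "kb", "kb_synthetic.tsv", package = "litsignal",
              mustWork = TRUE)
}

#' Load the default synthetic KB
#' @return KB index (see [load_kb()]).
#' @export
default_kb <- function() load_kb(default_kb_path())

SITE_PATTERN <- "^(Ser|Thr|Tyr|Lys|Arg|His|Cys|Asp|Glu|S|T|Y|K|R|H)[0-9]+$"
MUTANT_CODE_PATTERN <- "^[A-Z][0-9]+[A-Z]$"

#' Recognize entity mentions in a sentence
#'
#' Dictionary matching over token n-grams with longest-match-wins and
#' leftmost-first tie-breaking; output spans never overlap. Reaction-site
#' tokens (e.g. "Ser37", "S83") are recognized by grammar pattern even when
#' absent from the KB.
#'
#' @param sentence An `ls_sentence`.
#' @param index KB index from [load_kb()].
#' @param doc_id Document id recorded on the mentions.
#' @param sent Sentence index recorded on the mentions.
#' @return List of `ls_mention` records (ungrounded; see [ground()]).
#' @export
match_entities <- function(sentence, index, doc_id = "doc", sent = 1L) {
  tk <- sentence$tokens
  n <- nrow(tk)
  mentions <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq.int(min(index$max_ngram, n - i + 1L), 1L)) {
      j <- i + len - 1L
      key <- tolower(paste(tk$text[i:j], collapse = " "))
      hit <- index$lookup[[key]]
      if (!is.null(hit)) {
        entries <- index$entries[hit]
        type <- entries[[order(match(vapply(entries, `[[`, "", "namespace"),
                                     KB_PRIORITY))[1]]]$entity_type
        mentions[[length(mentions) + 1L]] <- new_mention(
          doc_id, sent, i, j, tk, type, kb_entries = entries)
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (matched) next
    if (grepl(SITE_PATTERN, tk$text[i]) && !grepl(MUTANT_CODE_PATTERN, tk$text[i])) {
      mentions[[length(mentions) + 1L]] <- new_mention(
        doc_id, sent, i, i, tk, "site", kb_entries = NULL)
    }
    i <- i + 1L
  }
  mentions
}

new_mention <- function(doc_id, sent, tok_start, tok_end, tokens, type,
                        kb_entries = NULL) {
  txt <- substr_tokens(tokens, tok_start, tok_end)
  structure(list(
    id = NA_character_, doc_id = doc_id, sent = as.integer(sent),
    tok_start = as.integer(tok_start), tok_end = as.integer(tok_end),
    start = tokens$start[tok_start], end = tokens$end[tok_end],
    text = txt, type = type,
    groundings = list(), mods = list(),
    kb_entries = kb_entries
  ), class = "ls_mention")
}

substr_tokens <- function(tokens, i, j) {
  paste(tokens$text[i:j], collapse = " ")
}

#' Ground a mention to knowledge-base identifiers
#'
#' Groundings are ordered by namespace priority (UniProt before InterPro for
#' proteins; ChEBI before HMDB for chemicals). Pattern-matched mentions with
#' no KB entry receive a deterministic local identifier in the "uaz"
#' namespace, derived from the mention text, so grounding is idempotent.
#'
#' @param mention An `ls_mention`.
#' @param index KB index (used only for priority resolution; matching
#'   entries travel with the mention).
#' @param priority Character vector of namespaces, highest priority first.
#' @return The mention with `groundings` filled: a list of
#'   `list(namespace, identifier)` pairs.
#' @export
ground <- function(mention, index = NULL, priority = KB_PRIORITY) {
  entries <- mention$kb_entries
  if (is.null(entries) || length(entries) == 0) {
    local_id <- paste0("UAZ-", toupper(gsub("[^A-Za-z0-9]+", "-", mention$text)))
    mention$groundings <- list(list(namespace = "uaz", identifier = local_id))
    return(mention)
  }
  ord <- order(match(vapply(entries, `[[`, "", "namespace"), priority),
               vapply(entries, `[[`, "", "identifier"))
  mention$groundings <- lapply(entries[ord], function(e)
    list(namespace = e$namespace, identifier = e$identifier))
  mention
}

#' Primary grounding id of a mention ("namespace:identifier")
#' @param mention A grounded `ls_mention`.
#' @return Character scalar, or `NA` if ungrounded.
#' @export
grounding_id <- function(mention) {
  if (length(mention$groundings) == 0) return(NA_character_)
  g <- mention$groundings[[1]]
  paste(g$namespace, g$identifier, sep = ":")
}

# participle / prefix cues for PTM state attachment
PTM_PREFIXES <- c(phospho = "phosphorylation", ubiquitin = "ubiquitination",
                  hydroxy = "hydroxylation", sumo = "sumoylation",
                  glyco = "glycosylation", acetyl = "acetylation",
                  farnesyl = "farnesylation", ribosyl = "ribosylation",
                  methyl = "methylation")
PTM_PARTICIPLES <- c(phosphorylated = "phosphorylation",
                     ubiquitinated = "ubiquitination",
                     hydroxylated = "hydroxylation",
                     sumoylated = "sumoylation",
                     glycosylated = "glycosylation",
                     acetylated = "acetylation",
                     farnesylated = "farnesylation",
                     ribosylated = "ribosylation",
                     methylated = "methylation")

#' Attach mutation / PTM / wild-type states to entity mentions
#'
#' Recognized constructions (token-level, after biomedical tokenization):
#' \itemize{
#'   \item "wild type X", "wild-type X", "X-WT": WildType state on X;
#'   \item "X-K134A", "K134A mutant of X": Mutant("K134A") on X;
#'   \item "phospho-X", "phosphorylated X" (any of the nine PTM reaction
#'     types): PTM state on X.
#' }
#'
#' @param sentence An `ls_sentence`.
#' @param mentions Mentions from [match_entities()].
#' @return The mentions with `mods` filled.
#' @export
attach_states <- function(sentence, mentions) {
  tk <- sentence$tokens
  low <- tolower(tk$text)
  n <- nrow(tk)
  for (m in seq_along(mentions)) {
    mn <- mentions[[m]]
    if (!mn$type %in% c("gene_or_gene_product", "family")) next
    i <- mn$tok_start; j <- mn$tok_end
    mods <- list()
    # wild type X  /  wild-type X
    pre2 <- if (i >= 3) paste(low[(i - 2):(i - 1)], collapse = " ") else ""
    pre3 <- if (i >= 4) paste(low[(i - 3):(i - 1)], collapse = " ") else ""
    if (pre2 == "wild type" || pre3 == "wild - type") {
      mods <- c(mods, list(list(kind = "WildType", subtype = NA, site = NA,
                                evidence = c(i - 2L, i - 1L))))
    }
    # X - WT  /  X - K134A
    if (j + 2L <= n && tk$text[j + 1L] == "-") {
      nxt <- tk$text[j + 2L]
      if (toupper(nxt) == "WT") {
        mods <- c(mods, list(list(kind = "WildType", subtype = NA, site = NA,
                                  evidence = c(j + 1L, j + 2L))))
      } else if (grepl(MUTANT_CODE_PATTERN, nxt)) {
        mods <- c(mods, list(list(kind = "Mutant", subtype = nxt, site = NA,
                                  evidence = c(j + 1L, j + 2L))))
      }
    }
    # K134A mutant of X
    if (i >= 4 && low[i - 1L] == "of" && low[i - 2L] %in% c("mutant", "variant") &&
        grepl(MUTANT_CODE_PATTERN, tk$text[i - 3L])) {
      mods <- c(mods, list(list(kind = "Mutant", subtype = tk$text[i - 3L],
                                site = NA, evidence = c(i - 3L, i - 2L))))
    }
    # phospho - X   (prefix form, tokenized at the dash)
    if (i >= 3 && tk$text[i - 1L] == "-" && low[i - 2L] %in% names(PTM_PREFIXES)) {
      mods <- c(mods, list(list(kind = "PTM",
                                subtype = unname(PTM_PREFIXES[low[i - 2L]]),
                                site = NA, evidence = c(i - 2L, i - 1L))))
    }
    # phosphorylated X  (participle premodifier)
    if (i >= 2 && low[i - 1L] %in% names(PTM_PARTICIPLES)) {
      mods <- c(mods, list(list(kind = "PTM",
                                subtype = unname(PTM_PARTICIPLES[low[i - 1L]]),
                                site = NA, evidence = c(i - 1L, i - 1L))))
    }
    mentions[[m]]$mods <- c(mn$mods, mods)
  }
  mentions
}

#' Serialize mentions to JSON standoff
#' @param mentions List of `ls_mention`.
#' @return JSON string.
#' @export
mentions_to_json <- function(mentions) {
  jsonlite::toJSON(lapply(mentions, function(m) {
    list(id = m$id, doc_id = m$doc_id, sent = m$sent,
         span = c(m$start, m$end), text = m$text, type = m$type,
         groundings = m$groundings, mods = m$mods)
  }), auto_unbox = TRUE, null = "null")
}
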