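# Text preprocessing: sentence segmentation, biomedical tokenization and
# CoNLL-U ingestion.  All character offsets are 0-based, half-open and
# document-level (standoff convention); token indices are 1-based as in
# CoNLL-U, with HEAD = 0 denoting the ROOT.

#' Default abbreviation blocklist for sentence segmentation
#'
#' Trailing-period abbreviations common in biomedical prose that must not
#' terminate a sentence. The list is configurable: pass your own character
#' vector to [segment_sentences()].
#'
#' @return Character vector of abbreviations (without the trailing period).
#' @export
default_abbreviations <- function() {
  c("fig", "figs", "et al", "al", "e.g", "i.e", "cf", "vs", "ca", "approx",
    "dr", "no", "ref", "refs", "eq", "resp", "inc", "st", "mt", "min", "max")
}

#' Segment raw text into sentence spans
#'
#' Splits on terminal punctuation (`.`, `!`, `?`) followed by whitespace and
#' an upper-case letter, digit or opening quote/parenthesis, unless the
#' preceding word is a known abbreviation (or a single capital initial).
#'
#' @param raw_text Document text (UTF-8).
#' @param abbreviations Character vector of abbreviations that never end a
#'   sentence (compared case-insensitively, period excluded).
#' @return A data frame with columns `start`, `end`: 0-based half-open
#'   character spans, disjoint and ordered, covering all non-whitespace text.
#' @export
segment_sentences <- function(raw_text, abbreviations = default_abbreviations()) {
  empty <- data.frame(start = integer(0), end = integer(0))
  if (is.null(raw_text) || !nzchar(trimws(raw_text))) return(empty)
  chars <- strsplit(raw_text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  abbr <- tolower(abbreviations)
  is_break <- logical(n)
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    # collapse runs of terminal punctuation: break only at the last one
    if (i < n && chars[i + 1] %in% c(".", "!", "?")) next
    # what follows: must be end-of-text or whitespace + sentence opener
    j <- i + 1
    while (j <= n && chars[j] %in% c("\"", "'", ")", "]")) j <- j + 1
    if (j <= n) {
      if (!grepl("\\s", chars[j])) next
      k <- j
      while (k <= n && grepl("\\s", chars[k])) k <- k + 1
      if (k <= n && !grepl("[[:upper:][:digit:]\"'(“]", chars[k])) next
    }
    if (chars[i] == ".") {
      # preceding word (letters/periods back to previous space)
      b <- i - 1
      while (b >= 1 && !grepl("\\s", chars[b])) b <- b - 1
      word <- paste(chars[seq.int(b + 1, i - 1)[seq.int(b + 1, i - 1) >= b + 1]],
                    collapse = "")
      word <- sub("\\.$", "", tolower(word))
      if (word %in% abbr) next
      if (grepl("^[a-z]$", word)) next                      # single initial
      # two-word abbreviations ("et al.")
      if (b >= 2) {
        b2 <- b - 1
        while (b2 >= 1 && !grepl("\\s", chars[b2])) b2 <- b2 - 1
        two <- paste0(paste(chars[seq.int(b2 + 1, b - 1)], collapse = ""), " ", word)
        if (tolower(two) %in% abbr) next
      }
    }
    is_break[i] <- TRUE
  }
  is_break[n] <- TRUE
  cuts <- which(is_break)
  spans <- empty
  pos <- 1
  for (cut in cuts) {
    s <- pos
    while (s <= cut && grepl("\\s", chars[s])) s <- s + 1
    e <- cut
    while (e >= s && grepl("\\s", chars[e])) e <- e - 1
    if (e >= s) spans <- rbind(spans, data.frame(start = s - 1L, end = e))
    pos <- cut + 1
  }
  spans
}

#' Tokenize a sentence with biomedical conventions
#'
#' Whitespace tokenization followed by punctuation splitting. Dashes and
#' slashes flanked by alphanumeric characters become separate tokens, so a
#' catalysis like "GAP-mediated" or complex members like "Dvl2/aPKC" are
#' visible to downstream pattern rules. Decimal numbers stay whole.
#'
#' @param sentence_text Sentence string (non-empty).
#' @param sentence_offset 0-based document offset of the sentence start.
#' @return Data frame of tokens: `index` (1-based), `text`, `start`, `end`
#'   (0-based half-open, document-level), `pos`, `lemma` (NA until annotated).
#' @export
tokenize <- function(sentence_text, sentence_offset = 0L) {
  stopifnot(is.character(sentence_text), nzchar(sentence_text))
  pat <- "[0-9]+(?:[.,][0-9]+)+|[A-Za-z0-9À-￿']+|[^A-Za-z0-9À-￿[:space:]]"
  m <- gregexpr(pat, sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1) stop("no tokens found in sentence")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  txt <- substring(sentence_text, starts, starts + lens - 1L)
  data.frame(
    index = seq_along(txt),
    text = txt,
    start = sentence_offset + starts - 1L,
    end = sentence_offset + starts + lens - 1L,
    pos = NA_character_,
    lemma = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Construct a sentence object
#'
#' @param tokens Token data frame as produced by [tokenize()] (optionally
#'   with `pos`/`lemma` filled).
#' @param deps Data frame with columns `head` (token index, 0 for ROOT),
#'   `dep` (token index) and `label` (relation string); may be empty until
#'   [annotate()] runs.
#' @param text Sentence text.
#' @param start 0-based document offset of the sentence.
#' @return An object of class `ls_sentence`.
#' @export
ls_sentence <- function(tokens, deps = NULL, text = NULL, start = 0L) {
  if (is.null(deps)) {
    deps <- data.frame(head = integer(0), dep = integer(0),
                       label = character(0), stringsAsFactors = FALSE)
  }
  s <- structure(list(tokens = tokens, deps = deps, text = text,
                      start = as.integer(start)), class = "ls_sentence")
  validate_sentence(s)
  s
}

#' Validate sentence invariants
#'
#' Checks token index consecutiveness, dependency endpoints, the single-ROOT
#' and single-head conventions, and acyclicity of the dependency tree.
#'
#' @param s An `ls_sentence`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_sentence <- function(s) {
  tk <- s$tokens
  if (!identical(as.integer(tk$index), seq_len(nrow(tk))))
    stop("token indices must be consecutive starting at 1")
  if (any(tk$start >= tk$end)) stop("token spans must be non-empty")
  d <- s$deps
  if (nrow(d) > 0) {
    n <- nrow(tk)
    if (any(d$dep < 1 | d$dep > n)) stop("dependency endpoint out of range")
    if (any(d$head < 0 | d$head > n)) stop("dependency head out of range")
    if (anyDuplicated(d$dep)) stop("token with more than one head")
    if (sum(d$head == 0) != 1) stop("sentence must have exactly one ROOT edge")
    if (nrow(d) == n) {
      # full tree: verify acyclicity by walking parent pointers
      parent <- integer(n)
      parent[d$dep] <- d$head
      for (v in seq_len(n)) {
        seen <- logical(n)
        u <- v
        while (u != 0) {
          if (seen[u]) stop("cycle in dependency graph")
          seen[u] <- TRUE
          u <- parent[u]
        }
      }
    }
  }
  invisible(TRUE)
}

#' Construct a document object
#'
#' @param doc_id Document identifier.
#' @param sentences List of `ls_sentence` objects in document order.
#' @param raw_text Full document text (may be reconstructed).
#' @return An object of class `ls_document`.
#' @export
ls_document <- function(doc_id, sentences, raw_text = NULL) {
  structure(list(doc_id = doc_id, sentences = sentences, raw_text = raw_text),
            class = "ls_document")
}

#' Segment and tokenize raw text into an (unannotated) document
#'
#' @param raw_text Document text.
#' @param doc_id Document identifier.
#' @param abbreviations Passed to [segment_sentences()].
#' @return An `ls_document` whose sentences lack POS/lemma/deps until
#'   [annotate()] is applied.
#' @export
read_text <- function(raw_text, doc_id = "doc", abbreviations = default_abbreviations()) {
  spans <- segment_sentences(raw_text, abbreviations)
  sentences <- lapply(seq_len(nrow(spans)), function(i) {
    st <- spans$start[i]; en <- spans$end[i]
    stext <- substr(raw_text, st + 1L, en)
    ls_sentence(tokenize(stext, st), text = stext, start = st)
  })
  ls_document(doc_id, sentences, raw_text)
}

# ---------------------------------------------------------------------------
# CoNLL-U

#' Read one or more documents from CoNLL-U
#'
#' Standard 10-column CoNLL-U: ID, FORM, LEMMA, UPOS, XPOS, FEATS, HEAD,
#' DEPREL, DEPS, MISC, sentences separated by blank lines, `#` comments
#' carrying metadata. `# newdoc id = X` starts a new document. Character
#' offsets are taken from MISC entries `start=<n>|end=<n>` when present and
#' otherwise reconstructed by joining FORMs with single spaces.
#' Multi-word-token ranges and empty nodes are skipped.
#'
#' @param con Path to a CoNLL-U file, or a character vector of lines.
#' @param doc_id Identifier for documents lacking a `# newdoc id`.
#' @return An `ls_document`, or a list of them if the input declares several
#'   documents.
#' @export
read_conllu <- function(con, doc_id = "doc") {
  lines <- if (length(con) == 1 && !grepl("\n", con) && file.exists(con)) {
    readLines(con, encoding = "UTF-8")
  } else if (length(con) == 1 && grepl("\n", con)) {
    strsplit(con, "\n", fixed = TRUE)[[1]]
  } else as.character(con)

  docs <- list()
  cur_doc_id <- doc_id
  cur_sents <- list()
  sent_lines <- list()
  sent_meta <- character(0)
  offset <- 0L

  flush_doc <- function() {
    if (length(cur_sents) > 0) {
      raw <- paste(vapply(cur_sents, function(s) s$text, ""), collapse = " ")
      docs[[length(docs) + 1L]] <<- ls_document(cur_doc_id, cur_sents, raw)
    }
    cur_sents <<- list()
    offset <<- 0L
  }
  flush_sent <- function() {
    if (length(sent_lines) == 0) return(invisible(NULL))
    s <- parse_conllu_sentence(sent_lines, sent_meta, offset)
    cur_sents[[length(cur_sents) + 1L]] <<- s
    offset <<- max(s$tokens$end) + 1L
    sent_lines <<- list()
    sent_meta <<- character(0)
    invisible(NULL)
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln)) { flush_sent(); next }
    if (startsWith(ln, "#")) {
      if (grepl("^#\\s*newdoc id\\s*=", ln)) {
        flush_sent(); flush_doc()
        cur_doc_id <- trimws(sub("^#\\s*newdoc id\\s*=", "", ln))
      } else sent_meta <- c(sent_meta, ln)
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10)
      stop(sprintf("malformed CoNLL-U line %d: expected 10 fields, got %d",
                   i, length(fields)))
    if (grepl("[-.]", fields[1])) next   # multi-word token / empty node
    sent_lines[[length(sent_lines) + 1L]] <- c(fields, line = i)
  }
  flush_sent(); flush_doc()
  if (length(docs) == 1) docs[[1]] else docs
}

parse_conllu_sentence <- function(sent_lines, sent_meta, offset) {
  n <- length(sent_lines)
  ids <- integer(n); form <- character(n); lemma <- character(n)
  upos <- character(n); head <- integer(n); label <- character(n)
  misc <- character(n); lineno <- integer(n)
  for (k in seq_len(n)) {
    f <- sent_lines[[k]]
    lineno[k] <- as.integer(f[["line"]])
    id <- suppressWarnings(as.integer(f[1]))
    if (is.na(id)) stop(sprintf("malformed CoNLL-U line %d: bad ID '%s'",
                                lineno[k], f[1]))
    ids[k] <- id
    form[k] <- f[2]; lemma[k] <- f[3]; upos[k] <- f[4]
    hd <- suppressWarnings(as.integer(f[7]))
    if (is.na(hd)) stop(sprintf("malformed CoNLL-U line %d: bad HEAD '%s'",
                                lineno[k], f[7]))
    head[k] <- hd
    label[k] <- f[8]
    misc[k] <- f[10]
  }
  if (!identical(ids, seq_len(n)))
    stop(sprintf("malformed CoNLL-U sentence near line %d: non-consecutive IDs",
                 lineno[1]))
  if (any(head > n))
    stop(sprintf("structural error near line %d: HEAD points to nonexistent ID",
                 lineno[which(head > n)[1]]))

  starts <- ends <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    if (misc[k] != "_" && nzchar(misc[k])) {
      kv <- strsplit(misc[k], "|", fixed = TRUE)[[1]]
      for (p in kv) {
        if (startsWith(p, "start=")) starts[k] <- as.integer(sub("start=", "", p))
        if (startsWith(p, "end=")) ends[k] <- as.integer(sub("end=", "", p))
      }
    }
  }
  if (anyNA(starts) || anyNA(ends)) {
    pos <- offset
    for (k in seq_len(n)) {
      starts[k] <- pos
      ends[k] <- pos + nchar(form[k])
      pos <- ends[k] + 1L
    }
  }
  text_meta <- grep("^#\\s*text\\s*=", sent_meta, value = TRUE)
  stext <- if (length(text_meta)) trimws(sub("^#\\s*text\\s*=", "", text_meta[1]))
           else paste(form, collapse = " ")

  tokens <- data.frame(index = ids, text = form, start = starts, end = ends,
                       pos = ifelse(upos == "_", NA_character_, upos),
                       lemma = ifelse(lemma == "_", NA_character_, lemma),
                       stringsAsFactors = FALSE)
  deps <- data.frame(head = head, dep = ids, label = label,
                     stringsAsFactors = FALSE)
  tryCatch(
    ls_sentence(tokens, deps, stext, starts[1]),
    error = function(e) stop(sprintf("structural error near line %d: %s",
                                     lineno[1], conditionMessage(e)))
  )
}

#' Write a document to CoNLL-U
#'
#' Inverse of [read_conllu()]: emits 10-column lines with character offsets
#' in MISC (`start=|end=`) so a round trip preserves offsets exactly.
#'
#' @param document An `ls_document` or list of them.
#' @param path Optional output path; when `NULL`, lines are returned.
#' @return Character vector of lines (invisibly when `path` given).
#' @export
write_conllu <- function(document, path = NULL) {
  docs <- if (inherits(document, "ls_document")) list(document) else document
  out <- character(0)
  for (doc in docs) {
    out <- c(out, sprintf("# newdoc id = %s", doc$doc_id))
    for (s in doc$sentences) {
      out <- c(out, sprintf("# text = %s", s$text))
      tk <- s$tokens
      hd <- rep(0L, nrow(tk)); lb <- rep("_", nrow(tk))
      if (nrow(s$deps) > 0) { hd[s$deps$dep] <- s$deps$head; lb[s$deps$dep] <- s$deps$label }
      for (i in seq_len(nrow(tk))) {
        out <- c(out, paste(
          tk$index[i], tk$text[i],
          ifelse(is.na(tk$lemma[i]), "_", tk$lemma[i]),
          ifelse(is.na(tk$pos[i]), "_", tk$pos[i]),
          "_", "_", hd[i], lb[i], "_",
          sprintf("start=%d|end=%d", tk$start[i], tk$end[i]),
          sep = "\t"))
      }
      out <- c(out, "")
    }
  }
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Fill POS, lemma and dependency annotations via a parser provider
#'
#' The provider contract: a function taking a character vector of token
#' texts and returning a list (or data frame) with elements `pos`, `lemma`,
#' `head` and `label`, one value per token. Sentences that already carry a
#' full annotation are left untouched, so documents ingested from gold
#' CoNLL-U pass through unchanged.
#'
#' @param document An `ls_document`.
#' @param provider Parser provider function (see Details).
#' @return The annotated `ls_document`.
#' @export
annotate <- function(document, provider) {
  for (i in seq_along(document$sentences)) {
    s <- document$sentences[[i]]
    done <- nrow(s$deps) > 0 && !anyNA(s$tokens$pos)
    if (done) next
    ann <- tryCatch(provider(s$tokens$text), error = function(e)
      stop(sprintf("parser provider failed on document '%s', sentence %d: %s",
                   document$doc_id, i, conditionMessage(e))))
    n <- nrow(s$tokens)
    if (length(ann$pos) != n || length(ann$head) != n)
      stop(sprintf("parser provider returned wrong arity on document '%s', sentence %d",
                   document$doc_id, i))
    s$tokens$pos <- as.character(ann$pos)
    s$tokens$lemma <- as.character(ann$lemma)
    s$deps <- data.frame(head = as.integer(ann$head), dep = seq_len(n),
                         label = as.character(ann$label), stringsAsFactors = FALSE)
    validate_sentence(s)
    document$sentences[[i]] <- s
  }
  document
}
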