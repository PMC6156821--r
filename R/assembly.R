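# Network assembly: normalize event mentions into directed interaction
# records, aggregate evidence across papers, filter for redundancy, and
# merge with curated prior networks in SIF format.

#' Normalize extracted events into interaction records
#'
#' Mapping: a regulation whose controlled argument is a simple event on
#' theme T becomes `controls_state_change` (subtype = the simple event's
#' label, signed) from controller to T; an activation becomes
#' `controls_activity`; a binding becomes symmetric `in_complex_with`
#' (canonically ordered participant ids). Participants that are events, or
#' entities without grounding, are dropped with a message.
#'
#' @param extraction An `ls_extraction` (grounded, polarity-final).
#' @return Data frame of interaction records: `source`, `relation`,
#'   `subtype`, `sign`, `target`, `doc_id`, `sent`, `trigger`, `negated`.
#' @export
normalize_interactions <- function(extraction) {
  mentions <- extraction$mentions
  events <- extraction$events
  rows <- list()
  gid <- function(ref) {
    m <- mentions[[ref]]
    if (is.null(m)) return(NA_character_)
    grounding_id(m)
  }
  emit <- function(source, relation, subtype, sign, target, ev) {
    rows[[length(rows) + 1L]] <<- data.frame(
      source = source, relation = relation, subtype = subtype,
      sign = as.integer(sign), target = target,
      doc_id = ev$doc_id, sent = ev$sent, trigger = ev$trigger_text,
      negated = ev$negated, stringsAsFactors = FALSE)
  }
  for (ev in events) {
    if (ev$label == "binding") {
      ids <- vapply(ev$args$theme, gid, "")
      if (anyNA(ids) || length(ids) != 2) {
        message("dropping binding with ungrounded participant(s): ", ev$id)
        next
      }
      ids <- sort(ids)
      emit(ids[1], "in_complex_with", NA_character_, 1L, ids[2], ev)
    } else if (ev$category %in% REGULATION_CATEGORIES) {
      ctrl <- ev$args$controller
      ctrd <- ev$args$controlled
      src <- if (ctrl %in% names(mentions)) gid(ctrl) else NA_character_
      if (is.na(src)) {
        message("dropping nested event with non-entity controller: ", ev$id)
        next
      }
      if (ctrd %in% names(events)) {
        inner <- events[[ctrd]]
        if (!inner$label %in% c(SIMPLE_EVENT_LABELS, "hydrolysis",
                                "translocation", "binding")) {
          message("dropping regulation of a nested event (no direct target): ",
                  ev$id)
          next
        }
        for (th in inner$args$theme) {
          tgt <- gid(th)
          if (is.na(tgt)) next
          emit(src, "controls_state_change", inner$label, ev$sign, tgt, ev)
        }
      } else {
        tgt <- gid(ctrd)
        if (is.na(tgt)) {
          message("dropping activation with ungrounded target: ", ev$id)
          next
        }
        emit(src, "controls_activity", NA_character_, ev$sign, tgt, ev)
      }
    }
    # bare simple events without controller do not form directed edges
  }
  if (length(rows) == 0) {
    return(data.frame(source = character(0), relation = character(0),
                      subtype = character(0), sign = integer(0),
                      target = character(0), doc_id = character(0),
                      sent = integer(0), trigger = character(0),
                      negated = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Aggregate interaction records across documents
#'
#' Records identical in (source, relation, subtype, sign, target) are
#' merged. By default evidence counts distinct source papers (doc ids),
#' not mentions: the same edge stated twice in one paper counts once.
#' Negated evidence never creates an edge; it is tallied on the matching
#' non-negated record's `negated_evidence_count` when one exists.
#'
#' @param records Data frame(s) from [normalize_interactions()] (rows from
#'   several documents may be concatenated).
#' @param count `"papers"` (default) or `"mentions"`.
#' @return Aggregated data frame with `evidence_count`,
#'   `negated_evidence_count` and a `provenance` list-column of
#'   `doc_id:sent:trigger` strings.
#' @export
aggregate_evidence <- function(records, count = c("papers", "mentions")) {
  count <- match.arg(count)
  if (nrow(records) == 0) {
    out <- records[, c("source", "relation", "subtype", "sign", "target")]
    out$evidence_count <- integer(0)
    out$negated_evidence_count <- integer(0)
    out$provenance <- list()
    return(out)
  }
  key <- paste(records$source, records$relation, records$subtype,
               records$sign, records$target, sep = "\r")
  pos <- records[!records$negated, , drop = FALSE]
  neg <- records[records$negated, , drop = FALSE]
  pos_key <- key[!records$negated]
  neg_key <- key[records$negated]
  uk <- unique(pos_key)
  out <- do.call(rbind, lapply(uk, function(k) {
    grp <- pos[pos_key == k, , drop = FALSE]
    ec <- if (count == "papers") length(unique(grp$doc_id)) else nrow(grp)
    nec <- if (count == "papers")
      length(unique(neg$doc_id[neg_key == k])) else sum(neg_key == k)
    data.frame(source = grp$source[1], relation = grp$relation[1],
               subtype = grp$subtype[1], sign = grp$sign[1],
               target = grp$target[1], evidence_count = ec,
               negated_evidence_count = nec, stringsAsFactors = FALSE)
  }))
  out$provenance <- lapply(uk, function(k) {
    grp <- pos[pos_key == k, , drop = FALSE]
    paste(grp$doc_id, grp$sent, grp$trigger, sep = ":")
  })
  out
}

#' Redundancy filter: keep interactions seen in at least k papers
#'
#' @param records Aggregated records (see [aggregate_evidence()]).
#' @param k Minimum evidence count (default 2, the "seen at least twice"
#'   high-confidence setting).
#' @return The surviving subset.
#' @export
filter_redundancy <- function(records, k = 2L) {
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be an integer >= 1")
  records[records$evidence_count >= k, , drop = FALSE]
}

#' Read a SIF network
#'
#' Tab-separated `source  relation  target`, with an optional 4th origin
#' column (`curated`/`extracted`). Duplicate rows are dropped.
#' @param con Path or character lines.
#' @param default_origin Origin tag applied when the 4th column is absent.
#' @return Data frame `source`, `relation`, `target`, `origin`.
#' @export
read_sif <- function(con, default_origin = "curated") {
  lines <- if (length(con) == 1 && file.exists(con))
    readLines(con, encoding = "UTF-8") else as.character(con)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- data.frame(source = character(0), relation = character(0),
                    target = character(0), origin = character(0),
                    stringsAsFactors = FALSE)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed SIF line %d: expected at least 3 columns", i))
    out <- rbind(out, data.frame(
      source = f[1], relation = f[2], target = f[3],
      origin = if (length(f) >= 4) f[4] else default_origin,
      stringsAsFactors = FALSE))
  }
  unique(out)
}

#' Write a network to SIF
#' @param network Data frame with `source`, `relation`, `target` and
#'   optionally `origin`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sif <- function(network, path) {
  cols <- c("source", "relation", "target",
            intersect("origin", names(network)))
  writeLines(do.call(paste, c(unname(network[cols]), sep = "\t")), path)
  invisible(path)
}

#' Merge extracted interactions with a curated prior network
#'
#' The union keeps origin tags; edges present in both (by source, relation,
#' target) are reported as the overlap.
#'
#' @param extracted Aggregated records ([aggregate_evidence()]) or a SIF
#'   data frame tagged `extracted`.
#' @param prior SIF data frame ([read_sif()]).
#' @return List: `network` (edges with origin tags, deduplicated) and
#'   `overlap` (edges found in both sources).
#' @export
merge_prior <- function(extracted, prior) {
  ex <- if ("evidence_count" %in% names(extracted)) {
    data.frame(source = extracted$source, relation = extracted$relation,
               target = extracted$target, origin = "extracted",
               stringsAsFactors = FALSE)
  } else extracted[, c("source", "relation", "target", "origin")]
  pr <- prior[, c("source", "relation", "target", "origin")]
  net <- unique(rbind(ex, pr))
  ekey <- paste(ex$source, ex$relation, ex$target)
  pkey <- paste(pr$source, pr$relation, pr$target)
  both <- intersect(unique(ekey), unique(pkey))
  overlap <- unique(ex[ekey %in% both, c("source", "relation", "target")])
  list(network = net, overlap = overlap)
}
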