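test_that("normalize maps regulations, activations and bindings to edges", {
  docs <- verbatim_docs()
  ex <- extract_document(docs[["t2-paraphrastic-causative"]], kb = test_kb(),
                         rules = test_rules(), lexicons = test_lexicons())
  rec <- normalize_interactions(ex)
  csc <- rec[rec$relation == "controls_state_change", ]
  expect_identical(nrow(csc), 1L)
  expect_identical(csc$source, "uniprot:Q9HCE7")   # Smurf1
  expect_identical(csc$target, "uniprot:P61586")   # RhoA
  expect_identical(csc$subtype, "hydrolysis")
  expect_identical(csc$sign, 1L)
  # binding -> in_complex_with, canonical order
  ex <- extract_document(docs[["t2-subject-apposition"]], kb = test_kb(),
                         rules = test_rules(), lexicons = test_lexicons())
  rec <- suppressMessages(normalize_interactions(ex))
  icw <- rec[rec$relation == "in_complex_with", ]
  expect_identical(nrow(icw), 1L)
  expect_true(icw$source < icw$target)
  # activation -> controls_activity
  ex <- extract_document(docs[["t2-combination"]], kb = test_kb(),
                         rules = test_rules(), lexicons = test_lexicons())
  rec <- normalize_interactions(ex)
  expect_true("controls_activity" %in% rec$relation)
  # empty extraction -> empty records
  empty <- structure(list(doc_id = "e", mentions = list(), events = list()),
                     class = "ls_extraction")
  expect_identical(nrow(normalize_interactions(empty)), 0L)
})

test_that("evidence is aggregated at paper granularity", {
  rec <- make_records(
    list("A", "controls_activity", "B", "doc1", FALSE),
    list("A", "controls_activity", "B", "doc2", FALSE),
    list("C", "controls_activity", "D", "doc1", FALSE),
    list("C", "controls_activity", "D", "doc1", FALSE),  # same paper twice
    list("E", "controls_activity", "F", "doc1", FALSE))
  agg <- aggregate_evidence(rec)
  get <- function(s) agg$evidence_count[agg$source == s]
  expect_identical(get("A"), 2L)
  expect_identical(get("C"), 1L)   # paper-level counting
  expect_identical(get("E"), 1L)
  # mention-level mode counts each statement
  aggm <- aggregate_evidence(rec, count = "mentions")
  expect_identical(aggm$evidence_count[aggm$source == "C"], 2L)
  # opposite-sign edges are kept separate
  rec2 <- make_records(list("A", "controls_activity", "B", "d1", FALSE),
                       list("A", "controls_activity", "B", "d2", FALSE))
  rec2$sign[2] <- -1L
  expect_identical(nrow(aggregate_evidence(rec2)), 2L)
  # negated evidence creates no edge but is tallied on the matching record
  rec3 <- make_records(list("A", "controls_activity", "B", "d1", FALSE),
                       list("A", "controls_activity", "B", "d2", TRUE),
                       list("X", "controls_activity", "Y", "d3", TRUE))
  agg3 <- aggregate_evidence(rec3)
  expect_identical(nrow(agg3), 1L)
  expect_identical(agg3$negated_evidence_count, 1L)
  # evidence conservation: counts equal provenance lengths in mention mode
  aggp <- aggregate_evidence(rec, count = "mentions")
  expect_identical(aggp$evidence_count,
                   vapply(aggp$provenance, length, 0L))
})

test_that("the redundancy filter matches the brute-force oracle and is monotone", {
  rec <- make_records(
    list("A", "r", "B", "d1", FALSE), list("A", "r", "B", "d2", FALSE),
    list("C", "r", "D", "d1", FALSE),
    list("E", "r", "F", "d1", FALSE), list("E", "r", "F", "d2", FALSE),
    list("E", "r", "F", "d3", FALSE))
  agg <- aggregate_evidence(rec)    # counts {2, 1, 3}
  expect_identical(nrow(filter_redundancy(agg, 2)), 2L)
  expect_identical(filter_redundancy(agg, 1), agg)     # k = 1 is identity
  expect_error(filter_redundancy(agg, 0), "k must be")
  sizes <- vapply(1:4, function(k) nrow(filter_redundancy(agg, k)), 0L)
  expect_true(all(diff(sizes) <= 0))                   # monotone in k
  # randomized corpus agrees with the oracle
  set.seed(42)
  pairs <- expand.grid(s = LETTERS[1:4], t = letters[1:4],
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(60), function(i) {
    p <- pairs[sample(nrow(pairs), 1), ]
    list(p$s, "r", p$t, sprintf("doc%d", sample(5, 1)), FALSE)
  })
  agg2 <- aggregate_evidence(do.call(make_records, rows))
  for (k in 1:5)
    expect_identical(filter_redundancy(agg2, k), oracle_filter(agg2, k))
})

test_that("SIF I/O and prior-network merging follow set arithmetic", {
  prior <- read_sif(c("TP53\tcontrols_activity\tMDM2\tcurated",
                      "KRAS\tcontrols_activity\tRAF1\tcurated",
                      "KRAS\tcontrols_activity\tRAF1\tcurated"))  # duplicate
  expect_identical(nrow(prior), 2L)
  expect_error(read_sif("just-one-column"), "line 1")
  ex <- data.frame(source = c("KRAS", "EGFR", "AKT1"),
                   relation = "controls_activity",
                   target = c("RAF1", "KRAS", "GSK3B"),
                   origin = "extracted", stringsAsFactors = FALSE)
  m <- merge_prior(ex, prior)
  # oracle: union 3 + 2 - 1 shared = 4 unique edges, overlap = 1
  ukey <- unique(paste(m$network$source, m$network$relation, m$network$target))
  expect_length(ukey, 4)
  expect_identical(nrow(m$overlap), 1L)
  expect_identical(m$overlap$source, "KRAS")
  # empty prior -> extracted edges only
  m0 <- merge_prior(ex, prior[0, ])
  expect_identical(nrow(m0$network), 3L)
  expect_identical(nrow(m0$overlap), 0L)
  # merge is idempotent in edge content
  m2 <- merge_prior(m$network[m$network$origin == "extracted", ], prior)
  expect_setequal(paste(m2$network$source, m2$network$target),
                  paste(m$network$source, m$network$target))
  # round trip through a SIF file
  path <- withr::local_tempfile(fileext = ".sif")
  write_sif(m$network, path)
  back <- read_sif(path)
  expect_identical(nrow(back), nrow(unique(m$network)))
})
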