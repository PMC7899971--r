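test_that("tokenization lowercases, strips, removes stopwords and stems", {
  expect_equal(tokenize_and_normalize("The trees are protected"),
               c("tree", "protect"))
  expect_equal(tokenize_and_normalize(""), character(0))
  expect_equal(tokenize_and_normalize("the and of is"), character(0))
  # punctuation and digits split tokens; single letters dropped;
  # "down" is on the vendored stopword list
  expect_equal(tokenize_and_normalize("Cut-down 40 acres, i.e. 9x!",
                                      stemmer = "none"),
               c("cut", "acres"))
  # stopword removal happens after lowercasing
  expect_equal(tokenize_and_normalize("THE Forest"), "forest")
})

test_that("the Porter stemmer reproduces published reference stems", {
  words <- c("caresses", "ponies", "ties", "caress", "cats",
             "feed", "agreed", "plastered", "bled", "motoring", "sing",
             "conflated", "troubled", "sized", "hopping", "tanned",
             "falling", "hissing", "fizzed", "failing", "filing",
             "happy", "sky", "relational", "conditional", "rational",
             "valenci", "hesitancy", "digitizer", "conformabli",
             "radicalli", "differentli", "vileli", "analogousli",
             "vietnamization", "predication", "operator", "feudalism",
             "decisiveness", "hopefulness", "callousness", "formaliti",
             "sensitiviti", "sensibiliti",
             "triplicate", "formative", "formalize", "electriciti",
             "electrical", "hopeful", "goodness",
             "revival", "allowance", "inference", "airliner", "gyroscopic",
             "adjustable", "defensible", "irritant", "replacement",
             "adjustment", "dependent", "adoption", "homologou",
             "communism", "activate", "angulariti", "homologous",
             "effective", "bowdlerize",
             "probate", "rate", "cease", "controll", "roll")
  stems <- c("caress", "poni", "ti", "caress", "cat",
             "feed", "agre", "plaster", "bled", "motor", "sing",
             "conflat", "troubl", "size", "hop", "tan",
             "fall", "hiss", "fizz", "fail", "file",
             "happi", "sky", "relat", "condit", "ration",
             "valenc", "hesit", "digit", "conform",
             "radic", "differ", "vile", "analog",
             "vietnam", "predic", "oper", "feudal",
             "decis", "hope", "callous", "formal",
             "sensit", "sensibl",
             "triplic", "form", "formal", "electr",
             "electr", "hope", "good",
             "reviv", "allow", "infer", "airlin", "gyroscop",
             "adjust", "defens", "irrit", "replac",
             "adjust", "depend", "adopt", "homolog",
             "commun", "activ", "angular", "homolog",
             "effect", "bowdler",
             "probat", "rate", "ceas", "control", "roll")
  expect_equal(porter_stem(words), stems)
})

toy_docs <- function() {
  # 6 docs over an artificial vocabulary; "rare" appears fewer than the
  # frequency threshold used below
  mk <- function(id, tokens, score) list(id = id, tokens = tokens, score = score)
  common <- rep(c("forest", "timber", "protect"), each = 4)
  list(
    mk("d1", c(common, "rare"), 5),
    mk("d2", common, 4),
    mk("d3", common, 3),
    mk("d4", c(rep("forest", 6), rep("timber", 5)), 2),    # 11 tokens: short
    mk("d5", common, 0),                                   # score zero
    mk("d6", c(common, "rare", "rare"), 6))
}

test_that("frequency, length and score filters apply with a full ledger", {
  dtm <- build_dtm(toy_docs(), min_word_freq = 4, min_doc_length = 12,
                   exclude_score_zero = TRUE)
  # "rare" occurs 3 times (< 4) in the retained corpus: excluded
  expect_false("rare" %in% dtm$vocabulary)
  # d4 has 11 post-filter tokens (< 12): excluded with the length rule
  expect_true("d4" %in% dtm$exclusion_ledger$id)
  expect_equal(dtm$exclusion_ledger$rule[dtm$exclusion_ledger$id == "d4"],
               "min_doc_length")
  # d5 excluded by score regardless of length
  expect_equal(dtm$exclusion_ledger$rule[dtm$exclusion_ledger$id == "d5"],
               "score_zero")
  # ledger completeness: input = kept + excluded
  expect_equal(length(toy_docs()),
               length(dtm$kept_ids) + nrow(dtm$exclusion_ledger))
  # kept documents meet the length bound
  expect_true(all(Matrix::rowSums(dtm$counts) >= 12))
})

test_that("filters are idempotent", {
  dtm <- build_dtm(toy_docs(), min_word_freq = 4, min_doc_length = 12)
  redo <- lapply(seq_along(dtm$kept_ids), function(i)
    list(id = dtm$kept_ids[i],
         tokens = rep(dtm$vocabulary, times = as.numeric(dtm$counts[i, ])),
         score = dtm$scores[i]))
  dtm2 <- build_dtm(redo, min_word_freq = 4, min_doc_length = 12)
  expect_equal(dtm2$kept_ids, dtm$kept_ids)
  expect_equal(dtm2$vocabulary, dtm$vocabulary)
  expect_equal(as.matrix(dtm2$counts), as.matrix(dtm$counts))
  expect_equal(nrow(dtm2$exclusion_ledger), 0L)
})

test_that("interacting filters reach a fixed point", {
  # removing the short document drops "glue" below the frequency threshold,
  # which in turn shortens d1; the filters must iterate to a stable state
  mk <- function(id, tokens, score) list(id = id, tokens = tokens, score = score)
  docs <- list(
    mk("d1", c(rep("aaa", 5), rep("glue", 2)), 3),
    mk("d2", c(rep("aaa", 5), rep("bbb", 5)), 4),
    mk("d3", c(rep("glue", 2), rep("bbb", 1)), 5))
  dtm <- build_dtm(docs, min_word_freq = 4, min_doc_length = 6)
  # d3 too short -> drops glue to 2 (< 4) -> d1 falls to 5 tokens -> dropped
  expect_setequal(dtm$kept_ids, "d2")
  expect_setequal(dtm$vocabulary, c("aaa", "bbb"))
  # a second pass changes nothing
  redo <- list(mk("d2", rep(c("aaa", "bbb"), each = 5), 4))
  expect_equal(build_dtm(redo, 4, 6)$kept_ids, "d2")
})

test_that("empty surviving corpora raise an informative error", {
  mk <- function(id, tokens, score) list(id = id, tokens = tokens, score = score)
  expect_error(build_dtm(list(mk("a", c("x", "y"), 1)), 10, 15),
               "binding filter")
  expect_error(build_dtm(list(mk("a", rep("x", 30), 0)), 1, 1),
               "binding filter")
})

test_that("corpus summaries use exact totals and the population SD", {
  mk <- function(id, n) list(id = id, tokens = rep(c("aa", "bb"), n / 2),
                             score = 3)
  dtm <- build_dtm(list(mk("a", 20), mk("b", 30)), min_word_freq = 1,
                   min_doc_length = 1)
  s <- corpus_summary(dtm)
  expect_equal(s$documents, 2L)
  expect_equal(s$total_tokens, 50L)
  expect_equal(s$mean_length, 25)
  expect_equal(s$sd_length, 5)          # population SD, dividing by n
  s1 <- corpus_summary(build_dtm(list(mk("a", 20)), 1, 1))
  expect_equal(s1$sd_length, 0)
})

test_that("document-term matrices round-trip through MatrixMarket files", {
  dtm <- build_dtm(toy_docs(), min_word_freq = 4, min_doc_length = 12)
  dir <- tempfile()
  write_dtm(dtm, dir)
  dtm2 <- read_dtm(dir)
  expect_equal(as.matrix(dtm2$counts), as.matrix(dtm$counts))
  expect_equal(dtm2$vocabulary, dtm$vocabulary)
  expect_equal(dtm2$kept_ids, dtm$kept_ids)
  expect_equal(nrow(dtm2$exclusion_ledger), nrow(dtm$exclusion_ledger))
})

test_that("corpus files read back from JSONL and CSV", {
  df <- data.frame(id = c("a", "b"), text = c("one tree", "two trees"),
                   score = c(3, 0), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".jsonl")
  write_corpus(df, f)
  expect_equal(read_corpus(f), df)
  fcsv <- tempfile(fileext = ".csv")
  write.csv(df, fcsv, row.names = FALSE)
  expect_equal(read_corpus(fcsv), df)
})
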