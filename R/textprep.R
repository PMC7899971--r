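#' Tokenize and normalize free text
#'
#' Lowercases, splits on non-alphabetic characters (so punctuation and
#' digits are dropped), discards single-letter tokens, removes stopwords
#' (after lowercasing), and stems the remainder.  Token order is preserved,
#' though downstream modeling uses only bag-of-words counts.
#'
#' @param text character scalar (or vector, tokenized per element).
#' @param stopwords character vector of stopwords; default
#'   [english_stopwords()].
#' @param stemmer `"porter"` (default) or `"none"`.
#' @return For scalar input a character vector of processed tokens; for
#'   vector input a list of such vectors.
#' @examples
#' tokenize_and_normalize("The trees are protected")
#' @export
tokenize_and_normalize <- function(text, stopwords = english_stopwords(),
                                   stemmer = c("porter", "none")) {
  stemmer <- match.arg(stemmer)
  one <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    toks <- strsplit(tolower(x), "[^a-z]+")[[1]]
    toks <- toks[nchar(toks) > 1L]
    toks <- toks[!(toks %in% stopwords)]
    if (stemmer == "porter") toks <- porter_stem(toks)
    toks
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Tokenize a raw corpus
#'
#' Applies [tokenize_and_normalize()] to every document of a raw corpus
#' (data frame with columns `id`, `text`, `score`).
#'
#' @param corpus data frame with columns `id`, `text`, `score`.
#' @param stopwords,stemmer passed to [tokenize_and_normalize()].
#' @return List of documents, each `list(id, tokens, score)`.
#' @export
tokenize_corpus <- function(corpus, stopwords = english_stopwords(),
                            stemmer = c("porter", "none")) {
  stemmer <- match.arg(stemmer)
  stopifnot(all(c("id", "text", "score") %in% names(corpus)))
  if (anyDuplicated(corpus$id)) stop("document ids must be unique")
  lapply(seq_len(nrow(corpus)), function(i)
    list(id = as.character(corpus$id[i]),
         tokens = tokenize_and_normalize(corpus$text[i], stopwords, stemmer),
         score = corpus$score[i]))
}

# normalize heterogeneous inputs to list(id, tokens, score)
as_token_docs <- function(documents) {
  if (is.data.frame(documents)) {
    stopifnot(all(c("id", "tokens") %in% names(documents)))
    sc <- if ("score" %in% names(documents)) documents$score
          else rep(NA_real_, nrow(documents))
    documents <- lapply(seq_len(nrow(documents)), function(i)
      list(id = as.character(documents$id[i]),
           tokens = documents$tokens[[i]], score = sc[i]))
  }
  documents
}

#' Build a filtered document-term matrix
#'
#' Applies, in order: (1) exclusion of rubric-score-0 documents (responses
#' deemed non-scorable); (2) removal of words whose corpus frequency is
#' below `min_word_freq`; (3) exclusion of documents whose post-filter
#' token total is below `min_doc_length`.  Because removing documents can
#' push word frequencies back below threshold, the two count filters are
#' re-applied alternately until a fixed point, so the result is idempotent.
#' Every excluded document is recorded in the ledger with the rule that
#' removed it.
#'
#' @param documents tokenized documents as returned by [tokenize_corpus()]
#'   (or a data frame with `id`, `tokens` list-column, `score`).
#' @param min_word_freq minimum corpus frequency for a word type to stay in
#'   the vocabulary (default 10).
#' @param min_doc_length minimum post-filter token count for a document to
#'   stay in the corpus (default 15).
#' @param exclude_score_zero drop documents with rubric score 0 first
#'   (default TRUE).
#' @param freq_mode `"corpus"` counts total occurrences (default);
#'   `"document"` counts the number of documents containing the word.
#' @return Object of class `dtm_counts`: sparse counts matrix (documents x
#'   vocabulary, `Matrix::dgCMatrix`), `vocabulary`, `kept_ids`, `scores`
#'   for kept documents, and `exclusion_ledger` (data frame id, rule).
#' @export
build_dtm <- function(documents, min_word_freq = 10L, min_doc_length = 15L,
                      exclude_score_zero = TRUE,
                      freq_mode = c("corpus", "document")) {
  freq_mode <- match.arg(freq_mode)
  documents <- as_token_docs(documents)
  ids <- vapply(documents, function(d) d$id, character(1))
  if (anyDuplicated(ids)) stop("document ids must be unique")
  scores <- vapply(documents, function(d) as.numeric(d$score %||% NA_real_),
                   numeric(1))
  ledger <- data.frame(id = character(0), rule = character(0))

  keep <- rep(TRUE, length(documents))
  if (exclude_score_zero) {
    z <- !is.na(scores) & scores == 0
    if (any(z)) {
      ledger <- rbind(ledger, data.frame(id = ids[z], rule = "score_zero"))
      keep[z] <- FALSE
    }
  }
  docs <- documents[keep]
  ids_k <- ids[keep]
  scores_k <- scores[keep]

  tok <- lapply(docs, function(d) as.character(d$tokens))
  vocab_ok <- NULL
  repeat {
    # word-frequency filter on the pooled retained corpus
    all_tok <- unlist(tok, use.names = FALSE)
    if (length(all_tok) == 0L) {
      if (!length(tok)) break
      freq <- integer(0)
    }
    freq <- if (freq_mode == "corpus") table(all_tok)
            else table(unlist(lapply(tok, unique), use.names = FALSE))
    vocab_ok <- names(freq)[freq >= min_word_freq]
    tok2 <- lapply(tok, function(t) t[t %in% vocab_ok])
    # document-length filter on post-filter totals
    lens <- lengths(tok2)
    short <- lens < min_doc_length
    if (!any(short)) { tok <- tok2; break }
    ledger <- rbind(ledger,
                    data.frame(id = ids_k[short], rule = "min_doc_length"))
    tok <- tok[!short]
    ids_k <- ids_k[!short]
    scores_k <- scores_k[!short]
    if (!length(tok)) break
  }

  if (!length(tok) || !length(vocab_ok))
    stop("no documents survive preprocessing (binding filter: ",
         if (!length(tok)) "min_doc_length" else "min_word_freq", ")")

  # re-derive the final vocabulary from the surviving corpus
  tok <- lapply(tok, function(t) t[t %in% vocab_ok])
  vocab <- sort(unique(unlist(tok, use.names = FALSE)))
  i_idx <- integer(0); j_idx <- integer(0); x_val <- integer(0)
  for (d in seq_along(tok)) {
    tt <- table(factor(tok[[d]], levels = vocab))
    nz <- which(tt > 0)
    i_idx <- c(i_idx, rep.int(d, length(nz)))
    j_idx <- c(j_idx, nz)
    x_val <- c(x_val, as.integer(tt[nz]))
  }
  counts <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x_val,
                                 dims = c(length(tok), length(vocab)),
                                 dimnames = list(ids_k, vocab))
  structure(list(counts = counts, vocabulary = vocab, kept_ids = ids_k,
                 scores = scores_k, exclusion_ledger = ledger,
                 min_word_freq = min_word_freq,
                 min_doc_length = min_doc_length,
                 freq_mode = freq_mode),
            class = "dtm_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.dtm_counts <- function(x, ...) {
  s <- corpus_summary(x)
  cat("Document-term counts:", s$documents, "documents,",
      s$vocabulary_size, "word types,", s$total_tokens, "tokens\n")
  cat("mean document length", round(s$mean_length, 1),
      "(SD", paste0(round(s$sd_length, 1), ");"),
      nrow(x$exclusion_ledger), "documents excluded\n")
  invisible(x)
}

#' Summarize a document-term matrix
#'
#' @param dtm a [build_dtm()] result.
#' @return List with `documents`, `total_tokens`, `vocabulary_size`,
#'   `mean_length` and `sd_length` (population SD, dividing by n).
#' @export
corpus_summary <- function(dtm) {
  stopifnot(inherits(dtm, "dtm_counts"))
  lens <- Matrix::rowSums(dtm$counts)
  list(documents = nrow(dtm$counts),
       total_tokens = as.integer(sum(lens)),
       vocabulary_size = ncol(dtm$counts),
       mean_length = mean(lens),
       sd_length = sqrt(mean((lens - mean(lens))^2)))
}

#' Read a corpus from JSONL or CSV
#'
#' JSONL files have one JSON object per line with fields `id`, `text`,
#' `score`; CSV files have those columns.
#'
#' @param path file path (`.jsonl`/`.json` or `.csv`).
#' @return Data frame with columns `id`, `text`, `score`.
#' @export
read_corpus <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- data.frame(id = vapply(recs, function(r) as.character(r$id),
                                 character(1)),
                     text = vapply(recs, function(r) as.character(r$text),
                                   character(1)),
                     score = vapply(recs, function(r) as.numeric(r$score),
                                    numeric(1)),
                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "text", "score") %in% names(df)))
  df$id <- as.character(df$id)
  df
}

#' Write a corpus to JSONL
#'
#' @param corpus data frame with columns `id`, `text`, `score`.
#' @param path output path.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus)))
    writeLines(jsonlite::toJSON(list(id = corpus$id[i], text = corpus$text[i],
                                     score = corpus$score[i]),
                                auto_unbox = TRUE), con)
  invisible(path)
}

#' Write a document-term matrix to disk
#'
#' Writes MatrixMarket counts (`dtm.mtx`), a vocabulary TSV (`vocab.tsv`),
#' kept ids with scores (`documents.tsv`) and the exclusion ledger
#' (`exclusions.csv`) into `dir`.
#'
#' @param dtm a [build_dtm()] result.
#' @param dir output directory (created if missing).
#' @export
write_dtm <- function(dtm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dtm$counts, file.path(dir, "dtm.mtx"))
  utils::write.table(data.frame(index = seq_along(dtm$vocabulary),
                                word = dtm$vocabulary),
                     file.path(dir, "vocab.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(id = dtm$kept_ids, score = dtm$scores),
                     file.path(dir, "documents.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(dtm$exclusion_ledger, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a document-term matrix written by [write_dtm()]
#'
#' @param dir directory containing `dtm.mtx`, `vocab.tsv`, `documents.tsv`
#'   and `exclusions.csv`.
#' @return A `dtm_counts` object.
#' @export
read_dtm <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "dtm.mtx")), "CsparseMatrix")
  vocab <- utils::read.table(file.path(dir, "vocab.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)$word
  docs <- utils::read.table(file.path(dir, "documents.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  ledger <- utils::read.csv(file.path(dir, "exclusions.csv"),
                            stringsAsFactors = FALSE)
  dimnames(counts) <- list(as.character(docs$id), vocab)
  structure(list(counts = counts, vocabulary = vocab,
                 kept_ids = as.character(docs$id), scores = docs$score,
                 exclusion_ledger = ledger,
                 min_word_freq = NA_integer_, min_doc_length = NA_integer_,
                 freq_mode = "corpus"),
            class = "dtm_counts")
}
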