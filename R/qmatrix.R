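#' Construct a Q-matrix
#'
#' A Q-matrix is the binary item-by-attribute incidence matrix that declares
#' which skills (attributes) each item measures.  It fixes the admissible
#' effect terms of the diagnostic item model: an item can carry a main effect
#' only for attributes flagged in its row, and an interaction only among
#' flagged attributes.
#'
#' @param incidence matrix (or data frame) of 0/1 entries, items in rows,
#'   attributes in columns.  Every row must flag at least one attribute.
#' @param items optional character vector of item labels (defaults to row
#'   names or `item_1 ...`).
#' @param attributes optional character vector of attribute labels (defaults
#'   to column names or `attr_1 ...`).
#' @return An object of class `qmatrix`: the binary incidence matrix with
#'   item and attribute dimnames.
#' @examples
#' q <- qmatrix(rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 0, 1)),
#'              attributes = c("Idea", "Structure", "Integration"))
#' q
#' @export
qmatrix <- function(incidence, items = NULL, attributes = NULL) {
  m <- as.matrix(incidence)
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || !all(m %in% c(0L, 1L)))
    stop("Q-matrix entries must be 0 or 1 with no missing values")
  if (any(rowSums(m) == 0L))
    stop("every Q-matrix row must flag at least one attribute (all-zero row found)")
  if (is.null(items)) {
    items <- rownames(m)
    if (is.null(items)) items <- paste0("item_", seq_len(nrow(m)))
  }
  if (is.null(attributes)) {
    attributes <- colnames(m)
    if (is.null(attributes)) attributes <- paste0("attr_", seq_len(ncol(m)))
  }
  dimnames(m) <- list(items, attributes)
  structure(m, class = c("qmatrix", "matrix"))
}

#' @exportS3Method base::print
print.qmatrix <- function(x, ...) {
  cat("Q-matrix:", nrow(x), "items x", ncol(x), "attributes\n")
  print(unclass(x))
  invisible(x)
}

#' Read a Q-matrix from CSV
#'
#' Expects a header row; the first column holds item labels and the remaining
#' columns one attribute each.
#'
#' @param path path to the CSV file.
#' @return A [qmatrix()].
#' @export
read_qmatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  qmatrix(as.matrix(df[, -1, drop = FALSE]),
          items = as.character(df[[1]]),
          attributes = colnames(df)[-1])
}

#' Write a Q-matrix to CSV
#'
#' @param q a [qmatrix()].
#' @param path output path.
#' @export
write_qmatrix <- function(q, path) {
  df <- data.frame(item = rownames(q), unclass(q), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Enumerate all mastery profiles
#'
#' Returns the 2^S binary attribute profiles in the canonical order in which
#' the first attribute is the most significant bit: for S = 3 the order is
#' 000, 001, 010, 011, 100, 101, 110, 111.
#'
#' @param n_attr number of attributes S.
#' @param attributes optional attribute labels for the columns.
#' @return Integer matrix of dimension 2^S x S.
#' @export
all_profiles <- function(n_attr, attributes = NULL) {
  stopifnot(n_attr >= 1)
  idx <- 0:(2L^n_attr - 1L)
  m <- matrix(vapply(idx, function(i)
    as.integer(intToBits(i))[n_attr:1], integer(n_attr)),
    ncol = n_attr, byrow = TRUE)
  if (is.null(attributes)) attributes <- paste0("attr_", seq_len(n_attr))
  dimnames(m) <- list(apply(m, 1, paste, collapse = ""), attributes)
  m
}

#' Build the effect structure implied by a Q-matrix
#'
#' For each item, enumerates every subset (up to `max_order` attributes) of
#' the attributes flagged in that item's Q-matrix row.  Singleton terms are
#' main effects; pairs are two-way interactions, and so on.  Terms are
#' ordered by (size, lexicographic attribute index).
#'
#' @param q a [qmatrix()].
#' @param max_order maximum interaction order (1 = main effects only,
#'   2 = add two-way interactions, ...).
#' @return An object of class `effect_structure`: a list with one element per
#'   item, each a list of integer vectors of attribute indices, plus
#'   attribute labels as an attribute.
#' @examples
#' q <- qmatrix(rbind(c(1, 0, 1)))
#' build_effect_structure(q, max_order = 2)
#' @export
build_effect_structure <- function(q, max_order = 2L) {
  stopifnot(inherits(q, "qmatrix"), max_order >= 1)
  terms_for <- function(flags) {
    attrs <- unname(which(flags == 1L))
    out <- list()
    for (sz in seq_len(min(max_order, length(attrs)))) {
      idx <- utils::combn(seq_along(attrs), sz, simplify = FALSE)
      out <- c(out, lapply(idx, function(i) attrs[i]))
    }
    out
  }
  es <- lapply(seq_len(nrow(q)), function(j) terms_for(q[j, ]))
  names(es) <- rownames(q)
  structure(es, attributes_labels = colnames(q),
            class = "effect_structure")
}

#' @exportS3Method base::print
print.effect_structure <- function(x, ...) {
  labs <- attr(x, "attributes_labels")
  cat("Effect structure for", length(x), "items\n")
  for (j in seq_along(x)) {
    terms <- vapply(x[[j]], function(t)
      paste(labs[t], collapse = ":"), character(1))
    cat("  ", names(x)[j], ": ", paste(terms, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Drop one term (vector of attribute indices) from an item's term list.
drop_effect_term <- function(es, item, term) {
  keep <- !vapply(es[[item]], function(t) identical(sort(t), sort(term)),
                  logical(1))
  es[[item]] <- es[[item]][keep]
  es
}

# Evaluate effect terms at each profile: profiles (P x S) -> design (P x T)
# where column t is the product of profile columns in term t.
effect_design <- function(profiles, terms) {
  if (length(terms) == 0L)
    return(matrix(0, nrow(profiles), 0))
  matrix(vapply(terms, function(t)
    apply(profiles[, t, drop = FALSE], 1, prod), numeric(nrow(profiles))),
    nrow = nrow(profiles))
}
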