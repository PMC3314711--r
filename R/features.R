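#' The bundled PubMed stopword list
#'
#' The standard NCBI/PubMed stopword list (function words and ubiquitous
#' units), one term per line, used by default in [tokenize()].
#'
#' @return A character vector of stopwords.
#' @export
pubmed_stopwords <- function() {
  readr::read_lines(system.file("extdata", "pubmed_stopwords.txt",
                                package = "epitriage"), progress = FALSE)
}

#' Tokenize classification text
#'
#' Lowercases, splits on non-alphanumeric characters, keeps tokens of
#' length >= 2 that are not pure digits, and removes stopwords. Token order
#' is preserved. Operates on a character vector and returns one token
#' vector per element.
#'
#' @param text Character vector of document texts.
#' @param stopwords Character vector of stopwords (default: the bundled
#'   PubMed list).
#' @return A list of character vectors (empty for empty text).
#' @export
tokenize <- function(text, stopwords = pubmed_stopwords()) {
  toks <- stringr::str_split(stringr::str_to_lower(text), "[^a-z0-9]+")
  purrr::map(toks, function(tk) {
    tk <- tk[nchar(tk) >= 2 & !stringr::str_detect(tk, "^[0-9]+$")]
    tk[!tk %in% stopwords]
  })
}

#' Build a document-frequency vocabulary
#'
#' Counts, for every term, the number of documents containing it (not the
#' number of occurrences) and drops rare terms.
#'
#' @param tokens List of token vectors, one per document (see [tokenize()]).
#' @param min_df Minimum document frequency; terms seen in fewer documents
#'   are excluded (default 3, so a term in only 2 documents is dropped).
#' @return A `vocabulary` tibble with columns `term`, `df`, carrying the
#'   corpus size as attribute `N`.
#' @export
build_vocabulary <- function(tokens, min_df = 3) {
  if (min_df < 1) abort("min_df must be >= 1")
  if (length(tokens) == 0) abort("cannot build a vocabulary from an empty corpus")
  present <- unlist(purrr::map(tokens, unique), use.names = FALSE)
  df <- table(present)
  out <- tibble(term = names(df), df = as.integer(df)) %>%
    filter(.data$df >= min_df) %>%
    arrange(.data$term)
  attr(out, "N") <- length(tokens)
  class(out) <- c("vocabulary", class(out))
  out
}

#' Inverse document frequency
#'
#' `idf(t) = ln(N / df(t))` with the natural log; 0 when a term occurs in
#' every document.
#'
#' @param terms Character vector of terms, all present in `vocabulary`.
#' @param vocabulary A [build_vocabulary()] result.
#' @return Numeric vector of IDF weights (>= 0).
#' @export
idf <- function(terms, vocabulary) {
  i <- match(terms, vocabulary$term)
  if (anyNA(i)) {
    abort(paste0("term(s) not in vocabulary: ",
                 paste(terms[is.na(i)], collapse = ", ")))
  }
  log(attr(vocabulary, "N") / vocabulary$df[i])
}

binary_entropy <- function(p) {
  # H in bits, with 0*log(0) = 0
  q <- 1 - p
  h <- numeric(length(p))
  nz <- p > 0 & p < 1
  h[nz] <- -(p[nz] * log2(p[nz]) + q[nz] * log2(q[nz]))
  h
}

#' Information gain of terms for a binary labelling
#'
#' `IG(t) = H(C) - [P(t) H(C | t present) + P(!t) H(C | t absent)]`, all
#' entropies base 2, so IG is in bits and bounded by the class entropy.
#' Symmetric in the two labels.
#'
#' @param tokens List of token vectors, one per document.
#' @param labels Binary label vector (two distinct values), one per document.
#' @param vocabulary Optional [build_vocabulary()] result restricting (and
#'   ordering) the scored terms; by default every term in `tokens` with the
#'   rare-word filter at 3 is scored.
#' @return A tibble with columns `term`, `ig`, sorted by decreasing `ig`
#'   (ties broken lexicographically).
#' @export
information_gain <- function(tokens, labels, vocabulary = NULL) {
  if (length(tokens) != length(labels)) {
    abort("tokens and labels must have the same length")
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) {
    abort("information gain requires exactly two classes in the corpus")
  }
  if (is.null(vocabulary)) vocabulary <- build_vocabulary(tokens)
  pos <- as.character(labels) == lv[2]
  n <- length(tokens); npos <- sum(pos)
  uniq <- purrr::map(tokens, unique)
  term_all <- unlist(uniq, use.names = FALSE)
  pos_all <- rep(pos, lengths(uniq))
  keep <- term_all %in% vocabulary$term
  term_all <- term_all[keep]; pos_all <- pos_all[keep]
  n_t <- table(factor(term_all, levels = vocabulary$term))
  n_t_pos <- table(factor(term_all[pos_all], levels = vocabulary$term))
  nt <- as.integer(n_t); ntp <- as.integer(n_t_pos)
  h_c <- binary_entropy(npos / n)
  p_t <- nt / n
  h_given_t <- ifelse(nt > 0, binary_entropy(ifelse(nt > 0, ntp / pmax(nt, 1), 0)), 0)
  n_abs <- n - nt
  h_given_not <- ifelse(n_abs > 0,
                        binary_entropy(ifelse(n_abs > 0, (npos - ntp) / pmax(n_abs, 1), 0)),
                        0)
  ig <- h_c - (p_t * h_given_t + (1 - p_t) * h_given_not)
  tibble(term = vocabulary$term, ig = pmax(ig, 0)) %>%
    arrange(dplyr::desc(.data$ig), .data$term)
}

#' Select the top-k features by information gain
#'
#' Keeps the `k` highest-IG terms (all of them if fewer are available),
#' with ties at the boundary broken lexicographically so selection is
#' deterministic, and attaches each term's IDF weight.
#'
#' @param ig_scores Tibble from [information_gain()].
#' @param vocabulary The [build_vocabulary()] result the scores were
#'   computed against (source of IDF weights and corpus size).
#' @param k Number of features to keep (default 100).
#' @return A `feature_set` tibble with columns `term`, `ig`, `idf`, in
#'   selection order, carrying attributes `N` and `k`.
#' @export
select_top_k <- function(ig_scores, vocabulary, k = 100) {
  if (k < 1) abort("k must be >= 1")
  sel <- ig_scores %>%
    arrange(dplyr::desc(.data$ig), .data$term) %>%
    head(k) %>%
    mutate(idf = idf(.data$term, vocabulary))
  attr(sel, "N") <- attr(vocabulary, "N")
  attr(sel, "k") <- k
  class(sel) <- c("feature_set", class(sel))
  sel
}

#' One-call feature selection for a binary task
#'
#' Vocabulary, information gain and top-k selection in one step, computed on
#' the supplied (training) documents only.
#'
#' @inheritParams information_gain
#' @inheritParams select_top_k
#' @inheritParams build_vocabulary
#' @return A `feature_set` (see [select_top_k()]).
#' @export
build_feature_set <- function(tokens, labels, k = 100, min_df = 3) {
  vocab <- build_vocabulary(tokens, min_df = min_df)
  ig <- information_gain(tokens, labels, vocab)
  select_top_k(ig, vocab, k = k)
}

#' Vectorize documents over a feature set
#'
#' Each document becomes a row of TF-IDF weights: the raw in-document count
#' of each feature term times the term's IDF, optionally scaled to unit
#' Euclidean length (all-zero rows are left at zero).
#'
#' @param tokens List of token vectors, one per document.
#' @param feature_set A [select_top_k()] result.
#' @param normalize Scale each non-zero row to unit length (default `TRUE`).
#' @return A numeric matrix, documents x features, with feature terms as
#'   column names.
#' @export
vectorize <- function(tokens, feature_set, normalize = TRUE) {
  terms <- feature_set$term
  k <- length(terms)
  m <- matrix(0, nrow = length(tokens), ncol = k,
              dimnames = list(NULL, terms))
  for (i in seq_along(tokens)) {
    idx <- match(tokens[[i]], terms)
    idx <- idx[!is.na(idx)]
    if (length(idx)) m[i, ] <- tabulate(idx, nbins = k)
  }
  m <- sweep(m, 2, feature_set$idf, `*`)
  if (normalize && nrow(m) > 0) {
    nrm <- sqrt(rowSums(m^2))
    nz <- nrm > 0
    m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  }
  m
}

#' Serialize / load a feature set as TSV
#'
#' Columns `term`, `ig`, `idf`; the corpus size `N` and selection size `k`
#' travel as `#` header comments.
#'
#' @param feature_set A `feature_set`.
#' @param path Output path.
#' @return `path` (write) or the restored `feature_set` (read).
#' @export
write_feature_set <- function(feature_set, path) {
  hdr <- c(paste0("# N=", attr(feature_set, "N")),
           paste0("# k=", attr(feature_set, "k")))
  readr::write_lines(hdr, path)
  readr::write_tsv(as_tibble(feature_set)[, c("term", "ig", "idf")], path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  hdr <- readr::read_lines(path, n_max = 2, progress = FALSE)
  tbl <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(term = "c", ig = "d", idf = "d"),
                         progress = FALSE)
  attr(tbl, "N") <- as.integer(sub("# N=", "", hdr[1], fixed = TRUE))
  attr(tbl, "k") <- as.integer(sub("# k=", "", hdr[2], fixed = TRUE))
  class(tbl) <- c("feature_set", class(tbl))
  tbl
}
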