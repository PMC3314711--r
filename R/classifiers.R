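#' Train a binary linear SVM
#'
#' Soft-margin linear SVM (C-SVC: minimise `(1/2)||w||^2 + C * sum(hinge)`),
#' fitted with libsvm via \pkg{e1071}. The returned model is a plain linear
#' scorer `w . x + b`, oriented so the `positive` class gets positive
#' scores; fitting is deterministic given the inputs.
#'
#' @param x Numeric matrix, documents x features (see [vectorize()]).
#' @param y Binary label vector (two distinct values).
#' @param positive Which label is the positive class (default: the
#'   lexicographically larger of the two).
#' @param C Soft-margin cost (default 1).
#' @return A `linear_model`: list with `w` (named weights), `b`, `C`,
#'   `positive`, `negative`.
#' @export
train_linear_svm <- function(x, y, positive = NULL, C = 1) {
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2) {
    abort(paste0("linear SVM needs both classes present; got: ",
                 paste(lv, collapse = ", ")))
  }
  positive <- positive %||% lv[2]
  if (!positive %in% lv) abort(paste0("positive label '", positive, "' not in data"))
  fit <- e1071::svm(x, factor(y, levels = lv), kernel = "linear", cost = C,
                    scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients decision values so its first internal class is positive;
  # read that off the decision-value column name and flip if needed
  dv <- attr(predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  pos_side <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (pos_side != positive) {
    w <- -w; b <- -b
  }
  names(w) <- colnames(x)
  structure(list(w = w, b = b, C = C, positive = positive,
                 negative = setdiff(lv, positive)),
            class = "linear_model")
}

#' Decision score of a linear model
#'
#' `w . x + b`: the sign is the raw class call, the magnitude the margin
#' (confidence).
#'
#' @param model A `linear_model`.
#' @param x Numeric vector or matrix on the model's feature space.
#' @return Numeric score(s).
#' @export
decision_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$w)) {
    abort(paste0("dimension mismatch: model has ", length(model$w),
                 " features, input has ", ncol(x)))
  }
  as.vector(x %*% model$w + model$b)
}

# label-stratified split of indices into m disjoint subsets covering 1..n
stratified_partition <- function(y, m, seed) {
  y <- as.character(y)
  withr::with_seed(seed, {
    folds <- integer(length(y))
    start <- 0L # rotate across classes so global fold sizes stay balanced
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- ((start + seq_along(idx) - 1L) %% m) + 1L
      start <- start + length(idx)
    }
    folds
  })
}

#' Train a leave-one-subset-out SVM ensemble
#'
#' The training set is split into `m` disjoint, label-stratified subsets
#' (seeded shuffle); member `i` is a linear SVM trained on all documents
#' except subset `i`. All members share the feature space of `x`. At
#' prediction time the ensemble score is the arithmetic mean of the member
#' scores.
#'
#' @inheritParams train_linear_svm
#' @param m Number of subsets/members (default 10).
#' @param seed Integer seed for the stratified shuffle (required).
#' @return An `ensemble_model`: members, subset assignment, `m`, `seed`,
#'   `C`, `positive`.
#' @export
train_ensemble <- function(x, y, positive = NULL, m = 10, seed, C = 1) {
  if (m < 2) abort("ensemble needs m >= 2 subsets")
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2) abort("ensemble training needs both classes present")
  positive <- positive %||% lv[2]
  if (min(table(y)) < m) {
    abort(paste0("need at least m = ", m, " examples of each class; got ",
                 paste(table(y), collapse = "/")))
  }
  subset_of <- stratified_partition(y, m, seed)
  members <- purrr::map(seq_len(m), function(i) {
    keep <- subset_of != i
    train_linear_svm(x[keep, , drop = FALSE], y[keep], positive = positive, C = C)
  })
  structure(list(members = members, subset_of = subset_of, m = m,
                 seed = seed, C = C, positive = positive,
                 terms = colnames(x)),
            class = "ensemble_model")
}

#' Ensemble decision score
#'
#' Arithmetic mean of the member decision scores; invariant to member order.
#'
#' @param ensemble An `ensemble_model`.
#' @param x Numeric vector or matrix on the ensemble's feature space.
#' @return Numeric score(s).
#' @export
ensemble_score <- function(ensemble, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  scores <- vapply(ensemble$members, decision_score, numeric(nrow(x)), x = x)
  if (nrow(x) == 1) mean(scores) else rowMeans(scores)
}

#' @export
tidy.linear_model <- function(x, ...) {
  tibble(term = c(names(x$w), "(bias)"), weight = c(unname(x$w), x$b))
}

#' @export
glance.ensemble_model <- function(x, ...) {
  tibble(m = x$m, C = x$C, seed = x$seed, positive = x$positive,
         n_features = length(x$terms))
}

#' Train a multinomial Naive Bayes classifier
#'
#' The baseline comparator for the curatability gate: a multinomial
#' bag-of-words model with Laplace smoothing `alpha` over the training
#' vocabulary. Scoring returns the log posterior odds of the positive
#' class; tokens outside the training vocabulary are ignored.
#'
#' @param tokens List of token vectors, one per document.
#' @param y Binary label vector.
#' @param positive The positive class (default lexicographically larger).
#' @param alpha Laplace smoothing constant (> 0, default 1).
#' @return An `nb_model` with class log-priors and per-term class-
#'   conditional log-probabilities.
#' @export
train_naive_bayes <- function(tokens, y, positive = NULL, alpha = 1) {
  if (alpha <= 0) abort("alpha must be > 0")
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2) abort("naive Bayes needs both classes present")
  positive <- positive %||% lv[2]
  negative <- setdiff(lv, positive)
  vocab <- sort(unique(unlist(tokens, use.names = FALSE)))
  count_class <- function(cl) {
    tk <- unlist(tokens[y == cl], use.names = FALSE)
    cnt <- table(factor(tk, levels = vocab))
    as.numeric(cnt)
  }
  n_pos <- count_class(positive)
  n_neg <- count_class(negative)
  v <- length(vocab)
  structure(list(
    vocab = vocab,
    log_prior = log(c(pos = sum(y == positive), neg = sum(y == negative)) / length(y)),
    log_p_pos = log((n_pos + alpha) / (sum(n_pos) + alpha * v)),
    log_p_neg = log((n_neg + alpha) / (sum(n_neg) + alpha * v)),
    alpha = alpha, positive = positive, negative = negative
  ), class = "nb_model")
}

#' Naive Bayes log posterior odds
#'
#' @param model An `nb_model`.
#' @param tokens A single token vector, or a list of them.
#' @return Numeric score(s): `log P(positive | d) - log P(negative | d)`.
#'   An empty document scores the log prior odds.
#' @export
nb_score <- function(model, tokens) {
  if (!is.list(tokens)) tokens <- list(tokens)
  delta <- model$log_p_pos - model$log_p_neg
  prior <- model$log_prior[["pos"]] - model$log_prior[["neg"]]
  vapply(tokens, function(tk) {
    idx <- match(tk, model$vocab)
    idx <- idx[!is.na(idx)]
    prior + sum(delta[idx])
  }, numeric(1))
}
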