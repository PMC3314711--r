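#' Misclassification-cost matrices
#'
#' A cost matrix is a square, non-negative table with rows indexed by the
#' true category and columns by the predicted one, zero on the diagonal.
#' It drives the combiner twice: as per-document instance weights during
#' training ([instance_weights()]) and as the expected-cost criterion at
#' decision time ([min_expected_cost_decision()]).
#'
#' `build_priority_cost_matrix()` encodes curation priorities at Level 1:
#' confusing two high-priority categories costs `c_hh` (default 1),
#' confusing two low-priority ones costs `c_ll` (default 0.2), losing a
#' high-priority document to a low-priority category costs `c_hl` (default
#' 5), and the reverse `c_lh` (default 1).
#'
#' @param partition A [priority_partition()] list (`high`, `low` character
#'   vectors); their concatenation fixes the sibling order.
#' @param c_hh,c_ll,c_hl,c_lh Non-negative costs (see above).
#' @return A `cost_matrix` (numeric matrix with dimnames).
#' @export
build_priority_cost_matrix <- function(partition, c_hh = 1, c_ll = 0.2,
                                       c_hl = 5, c_lh = 1) {
  costs <- c(c_hh, c_ll, c_hl, c_lh)
  if (any(costs < 0)) abort("costs must be non-negative")
  cats <- c(partition$high, partition$low)
  is_high <- cats %in% partition$high
  n <- length(cats)
  m <- matrix(0, n, n, dimnames = list(true = cats, predicted = cats))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m[i, j] <- if (is_high[i] && is_high[j]) c_hh
      else if (!is_high[i] && !is_high[j]) c_ll
      else if (is_high[i]) c_hl
      else c_lh
  }
  new_cost_matrix(m)
}

#' @rdname build_priority_cost_matrix
#'
#' @description
#' `build_catchall_cost_matrix()` encodes the Level-2/3 rule used when an
#' "Other"/"Various" bucket is among the siblings: predicting a specific
#' document into a catch-all costs `c_to_catchall` (default 5), pulling a
#' catch-all document into a specific category costs `c_from_catchall`
#' (default 0.2, also used between two catch-alls), and confusing two
#' specific categories costs `c_spec` (default 1). This discourages the
#' classifier from dumping borderline documents into the heterogeneous
#' bucket.
#'
#' @param siblings Character vector of sibling category names (canonical
#'   order).
#' @param catch_all Logical vector marking the catch-all siblings.
#' @param c_spec,c_to_catchall,c_from_catchall Non-negative costs.
#' @export
build_catchall_cost_matrix <- function(siblings, catch_all, c_spec = 1,
                                       c_to_catchall = 5, c_from_catchall = 0.2) {
  if (any(c(c_spec, c_to_catchall, c_from_catchall) < 0)) {
    abort("costs must be non-negative")
  }
  if (!any(catch_all)) {
    abort("no catch-all sibling flagged; use uniform_cost_matrix() instead")
  }
  n <- length(siblings)
  m <- matrix(0, n, n, dimnames = list(true = siblings, predicted = siblings))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m[i, j] <- if (catch_all[i]) c_from_catchall
      else if (catch_all[j]) c_to_catchall
      else c_spec
  }
  new_cost_matrix(m)
}

#' @rdname build_priority_cost_matrix
#'
#' @description
#' `uniform_cost_matrix()` is the cost-insensitive baseline: 0 on the
#' diagonal, 1 everywhere else, under which minimum expected cost reduces
#' to maximum probability.
#' @export
uniform_cost_matrix <- function(siblings) {
  n <- length(siblings)
  m <- matrix(1, n, n, dimnames = list(true = siblings, predicted = siblings))
  diag(m) <- 0
  new_cost_matrix(m)
}

new_cost_matrix <- function(m) {
  if (nrow(m) != ncol(m)) abort("cost matrix must be square")
  if (any(m < 0)) abort("cost matrix entries must be non-negative")
  if (any(diag(m) != 0)) abort("cost matrix diagonal must be zero")
  class(m) <- c("cost_matrix", class(m))
  m
}

#' Read an explicit cost matrix from YAML or JSON
#'
#' Expects a mapping with `categories` (sibling order) and `costs` (a list
#' of rows, true-by-predicted).
#'
#' @param path Path to the config file.
#' @return A `cost_matrix`.
#' @export
load_cost_matrix <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cats <- as.character(cfg$categories)
  m <- do.call(rbind, lapply(cfg$costs, as.numeric))
  if (is.null(cats) || length(cats) != nrow(m)) {
    abort("cost config needs 'categories' matching the 'costs' table size")
  }
  dimnames(m) <- list(true = cats, predicted = cats)
  new_cost_matrix(m)
}

#' Per-document training weights from a cost matrix
#'
#' A document with true class `i` gets weight `rowSums(C)[i] / mean(rowSums(C))`:
#' classes whose misclassification is expensive are emphasised during
#' combiner training. A uniform matrix yields all-1 weights, and weights
#' are invariant to scaling the matrix by a positive constant.
#'
#' @param labels Character vector of true categories (all within the
#'   matrix's rownames).
#' @param cost_matrix A `cost_matrix`.
#' @return Numeric weights, one per document.
#' @export
instance_weights <- function(labels, cost_matrix) {
  rs <- rowSums(cost_matrix)
  if (all(rs == 0)) abort("all-zero cost matrix: weights undefined")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), rownames(cost_matrix))
  if (length(bad)) {
    abort(paste0("label(s) outside the cost matrix: ", paste(bad, collapse = ", ")))
  }
  unname(rs[labels] / mean(rs))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward + analytic gradients for the 1-hidden-layer softmax MLP under
# weighted cross-entropy; kept separate so a finite-difference oracle can
# check it on tiny networks
mlp_gradients <- function(W1, W2, X, Y, w) {
  n <- nrow(X)
  Xb <- cbind(1, X)
  A1 <- sigmoid(Xb %*% W1)
  A1b <- cbind(1, A1)
  P <- softmax_rows(A1b %*% W2)
  loss <- -sum(w * log(rowSums(P * Y))) / n
  dZ2 <- (P - Y) * (w / n)
  gW2 <- t(A1b) %*% dZ2
  dA1 <- dZ2 %*% t(W2[-1, , drop = FALSE])
  dZ1 <- dA1 * A1 * (1 - A1)
  gW1 <- t(Xb) %*% dZ1
  list(loss = loss, gW1 = gW1, gW2 = gW2, probs = P)
}

#' Train the neural-network combiner
#'
#' A feed-forward multilayer perceptron with one hidden layer of `h`
#' sigmoid units (default: half the number of categories, at least 2) and a
#' softmax output over the sibling categories. It takes a document's
#' per-sibling ensemble score profile and returns category probabilities.
#' Training minimises instance-weighted cross-entropy by online (per-
#' document) gradient descent with momentum, documents shuffled each epoch,
#' from a seeded random initialisation, so results are reproducible
#' bit-for-bit given the seed. Inputs are standardised internally
#' (training-set statistics are stored in the model).
#'
#' @param profiles Numeric matrix, documents x siblings, of ensemble scores
#'   (canonical sibling order as columns, named).
#' @param labels Character vector of true categories.
#' @param weights Optional per-document weights (see [instance_weights()]);
#'   default all 1.
#' @param classes Category order for the output layer; defaults to the
#'   column names of `profiles`.
#' @param h Hidden-layer width; default `max(2, floor(K/2))` for `K`
#'   categories.
#' @param seed Integer seed for weight initialisation (required).
#' @param epochs Training epochs (default 500).
#' @param lr Learning rate (default 0.3).
#' @param momentum Momentum coefficient (default 0.2).
#' @return An `mlp_model`.
#' @export
train_mlp <- function(profiles, labels, weights = NULL, classes = NULL,
                      h = NULL, seed, epochs = 500, lr = 0.3, momentum = 0.2) {
  classes <- classes %||% colnames(profiles)
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  K <- length(classes)
  if (K < 2) abort("combiner needs at least 2 categories")
  labels <- as.character(labels)
  if (!all(labels %in% classes)) {
    abort(paste0("label(s) outside the class set: ",
                 paste(setdiff(labels, classes), collapse = ", ")))
  }
  h <- h %||% max(2L, K %/% 2L)
  if (h < 1) abort("hidden-layer width h must be >= 1")
  if (epochs < 1) abort("epochs must be >= 1")
  X <- as.matrix(profiles)
  if (any(!is.finite(X))) abort("score profiles must be finite")
  n <- nrow(X); p <- ncol(X)
  center <- colMeans(X)
  scale_ <- apply(X, 2, sd); scale_[scale_ == 0 | is.na(scale_)] <- 1
  X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), match(labels, classes))] <- 1
  w <- weights %||% rep(1, n)
  w <- w / mean(w)
  yi <- match(labels, classes)
  fit <- withr::with_seed(seed, {
    W1 <- matrix(runif((p + 1) * h, -0.5, 0.5), p + 1, h)
    W2 <- matrix(runif((h + 1) * K, -0.5, 0.5), h + 1, K)
    V1 <- W1 * 0; V2 <- W2 * 0
    Xb <- cbind(1, X)
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        a1 <- sigmoid(drop(Xb[i, ] %*% W1))
        a1b <- c(1, a1)
        z2 <- drop(a1b %*% W2)
        pr <- exp(z2 - max(z2)); pr <- pr / sum(pr)
        d2 <- w[i] * pr; d2[yi[i]] <- d2[yi[i]] - w[i]
        d1 <- drop(W2[-1, , drop = FALSE] %*% d2) * a1 * (1 - a1)
        V2 <- momentum * V2 - lr * outer(a1b, d2)
        V1 <- momentum * V1 - lr * outer(Xb[i, ], d1)
        W2 <- W2 + V2
        W1 <- W1 + V1
      }
    }
    list(W1 = W1, W2 = W2)
  })
  W1 <- fit$W1; W2 <- fit$W2
  structure(list(W1 = W1, W2 = W2, classes = classes, center = center,
                 scale = scale_, h = h, seed = seed, epochs = epochs,
                 lr = lr, momentum = momentum,
                 final_loss = mlp_gradients(W1, W2, X, Y, w)$loss),
            class = "mlp_model")
}

#' Combiner category probabilities
#'
#' @param mlp An `mlp_model`.
#' @param profile A score profile (vector of length = input width) or a
#'   matrix of profiles.
#' @return A probability vector summing to 1 (or a matrix of them).
#' @export
predict_probs <- function(mlp, profile) {
  X <- if (is.null(dim(profile))) matrix(profile, nrow = 1) else as.matrix(profile)
  if (ncol(X) != length(mlp$center)) {
    abort(paste0("profile length ", ncol(X), " does not match combiner input width ",
                 length(mlp$center)))
  }
  X <- sweep(sweep(X, 2, mlp$center), 2, mlp$scale, "/")
  A1 <- sigmoid(cbind(1, X) %*% mlp$W1)
  P <- softmax_rows(cbind(1, A1) %*% mlp$W2)
  colnames(P) <- mlp$classes
  if (nrow(P) == 1) P[1, ] else P
}

#' Minimum-expected-cost category decision
#'
#' Picks the predicted column `j` minimising `sum_i p_i C[i, j]`. Ties go
#' to the smallest canonical index. Under a uniform 0/1 matrix this is the
#' maximum-probability decision; the decision is invariant to positive
#' scaling of the matrix.
#'
#' @param probs A probability vector (or matrix of rows) over the true
#'   categories.
#' @param cost_matrix A `cost_matrix` of matching size.
#' @return Integer index (or vector) of the chosen predicted category.
#' @export
min_expected_cost_decision <- function(probs, cost_matrix) {
  P <- if (is.null(dim(probs))) matrix(probs, nrow = 1) else as.matrix(probs)
  if (ncol(P) != nrow(cost_matrix)) {
    abort("probability vector length must match the cost matrix size")
  }
  expected <- P %*% unclass(cost_matrix)
  out <- apply(expected, 1, which.min)
  if (length(out) == 1) out[[1]] else out
}

#' @export
glance.mlp_model <- function(x, ...) {
  tibble(h = x$h, epochs = x$epochs, lr = x$lr, momentum = x$momentum,
         seed = x$seed, final_loss = x$final_loss,
         n_classes = length(x$classes))
}
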