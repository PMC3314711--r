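#' ROC curve and AUC
#'
#' AUC is computed by the Mann-Whitney pair-counting formulation (via
#' average ranks): the probability that a random positive scores above a
#' random negative, with tied pairs counting one half. The ROC points sweep
#' cutoffs over midpoints between sorted unique scores plus the +/-Inf
#' endpoints, calling a document positive when its score is >= the cutoff.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels, one per score.
#' @param positive Which label is positive (default: lexicographically
#'   larger).
#' @return A `roc_result`: list with `points` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) abort("ROC needs both classes present")
  positive <- positive %||% lv[2]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores) # average ranks handle ties as half-pairs
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  u <- sort(unique(scores))
  cutoffs <- c(Inf, if (length(u) > 1) rev(u[-length(u)] + diff(u) / 2), -Inf)
  pts <- purrr::map_dfr(cutoffs, function(th) {
    call_pos <- scores >= th
    tibble(threshold = th,
           fpr = sum(call_pos & !pos) / n_neg,
           tpr = sum(call_pos & pos) / n_pos)
  })
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", format(x$auc, digits = 4),
      sprintf("(%d positives, %d negatives)\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fn,fp,tn Non-negative counts (true/false positives/negatives).
#' @return A tibble with `sensitivity` and `specificity` as percentages.
#' @export
sensitivity_specificity <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) abort("counts must be non-negative")
  if (tp + fn == 0) abort("no positives: sensitivity undefined")
  if (tn + fp == 0) abort("no negatives: specificity undefined")
  tibble(sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp))
}

#' Percent agreement from a confusion matrix
#'
#' Trace over total, optionally restricted to the rows (true categories)
#' where the level applies - branches that skip a level are masked out.
#'
#' @param mat Square count matrix, rows = true, columns = predicted.
#' @param applicable Optional logical mask over rows.
#' @return Accuracy as a percentage.
#' @export
accuracy_from_confusion <- function(mat, applicable = NULL) {
  applicable <- applicable %||% rep(TRUE, nrow(mat))
  m <- mat[applicable, applicable, drop = FALSE]
  total <- sum(mat[applicable, , drop = FALSE])
  if (total == 0) abort("no documents after masking")
  100 * sum(diag(mat)[applicable]) / total
}

#' Priority breakdown of a Level-1 confusion matrix
#'
#' Splits predictions by the high/low curation-priority partition: for each
#' predicted block, how many were correct, confused within the block, or
#' pulled across the priority boundary; plus percent-correct within each
#' true-priority block. The cross-boundary count `pred_low$from_high` is
#' the number of high-priority documents lost to low-priority categories -
#' the error the cost matrices exist to suppress.
#'
#' @param mat Square count matrix over Level-1 categories (rows true,
#'   columns predicted, dimnames set).
#' @param partition A [priority_partition()] list.
#' @return A `priority_breakdown` list: tibble `by_prediction` plus
#'   `pct_correct_high`, `pct_correct_low` (over true categories).
#' @export
priority_breakdown <- function(mat, partition) {
  cats <- rownames(mat)
  if (!setequal(cats, c(partition$high, partition$low))) {
    abort("partition does not cover the matrix categories")
  }
  hi <- cats %in% partition$high
  block <- function(pred_hi) {
    cols <- if (pred_hi) hi else !hi
    total <- sum(mat[, cols])
    correct <- sum(diag(mat)[if (pred_hi) hi else !hi])
    within <- sum(mat[cols, cols]) - correct
    across <- sum(mat[!cols, cols])
    tibble(predicted = if (pred_hi) "high" else "low",
           total = total, correct = correct,
           incorrect_same_priority = within,
           incorrect_other_priority = across)
  }
  out <- structure(list(
    by_prediction = bind_rows(block(TRUE), block(FALSE)),
    pct_correct_high = 100 * sum(diag(mat)[hi]) / sum(mat[hi, ]),
    pct_correct_low = 100 * sum(diag(mat)[!hi]) / sum(mat[!hi, ])
  ), class = "priority_breakdown")
  out
}

#' @export
print.priority_breakdown <- function(x, ...) {
  print(x$by_prediction)
  cat(sprintf("correct within true-high: %.1f%%; within true-low: %.1f%%\n",
              x$pct_correct_high, x$pct_correct_low))
  invisible(x)
}

#' Stratified k-fold cross-validation plan
#'
#' Folds are disjoint, cover all indices, and hold each class's per-fold
#' count within one document of balance.
#'
#' @param n Number of documents.
#' @param k Number of folds (>= 2).
#' @param labels Stratification labels (length `n`).
#' @param seed Integer seed for the shuffle.
#' @return A `cv_plan` tibble (`index`, `fold`) with attributes `k`, `seed`.
#' @export
kfold_plan <- function(n, k, labels, seed) {
  if (k < 2) abort("k must be >= 2")
  if (n < k) abort("need at least k documents")
  if (length(labels) != n) abort("labels must have length n")
  fold <- stratified_partition(labels, k, seed)
  out <- tibble(index = seq_len(n), fold = fold)
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  class(out) <- c("cv_plan", class(out))
  out
}

# out-of-fold ensemble scores for one binary task; feature selection is
# redone inside each fold on the training part only
cv_binary_scores <- function(tokens, y, positive, plan, control) {
  y <- as.character(y)
  scores <- rep(NA_real_, length(tokens))
  k <- attr(plan, "k")
  for (f in seq_len(k)) {
    tr <- plan$index[plan$fold != f]
    te <- plan$index[plan$fold == f]
    if (length(unique(y[tr])) < 2) {
      warn(paste0("fold ", f, " lost a class in training; scores stay NA"))
      next
    }
    fs <- build_feature_set(tokens[tr], y[tr] == positive,
                            k = control$k_features, min_df = control$min_df)
    xtr <- vectorize(tokens[tr], fs, normalize = control$normalize)
    xte <- vectorize(tokens[te], fs, normalize = control$normalize)
    ens <- train_ensemble(xtr, y[tr], positive = positive, m = control$m,
                          seed = attr(plan, "seed") + f, C = control$C)
    scores[te] <- ensemble_score(ens, xte)
  }
  scores
}

# out-of-fold per-sibling score profiles for a multi-category sibling set
cv_sibling_profiles <- function(tokens, labels, classes, plan, control) {
  profiles <- matrix(NA_real_, nrow = length(tokens), ncol = length(classes),
                     dimnames = list(NULL, classes))
  for (cl in classes) {
    profiles[, cl] <- cv_binary_scores(tokens, ifelse(labels == cl, cl, ".rest"),
                                       positive = cl, plan = plan,
                                       control = control)
  }
  profiles
}

#' Cross-validated per-category performance of a sibling set
#'
#' The table behind per-node reporting: for each category of one sibling
#' set, the out-of-fold one-vs-rest ensemble AUC and the combiner's
#' category-prediction accuracy (the combiner is itself cross-validated on
#' the pooled out-of-fold score profiles, using the same folds).
#'
#' @param corpus Labelled corpus tibble (from [join_corpus()] or
#'   [generate_corpus()]).
#' @param tax A [taxonomy].
#' @param parent Sibling-set parent: `NULL` for the Level-1 set, otherwise
#'   a node name.
#' @param control A [triage_control()] list.
#' @param seed Integer seed.
#' @return A tibble: `category`, `n`, `auc`, `combiner_accuracy` (percent).
#' @export
cv_node_performance <- function(corpus, tax, parent = NULL,
                                control = triage_control(), seed = 1) {
  set <- sibling_set_docs(corpus, tax, parent)
  if (is.null(set) || length(unique(set$label)) < 2) {
    abort("sibling set has fewer than 2 labelled categories")
  }
  classes <- set$classes
  k <- if (is.null(parent)) control$folds_level1 else control$folds_deeper
  plan <- kfold_plan(nrow(set$docs), k, set$label, seed = seed)
  tokens <- tokenize(classification_text(set$docs))
  profiles <- cv_sibling_profiles(tokens, set$label, classes, plan, control)
  aucs <- purrr::map_dbl(classes, function(cl) {
    roc_auc(profiles[, cl], ifelse(set$label == cl, cl, ".rest"),
            positive = cl)$auc
  })
  # second-stage CV for the combiner on the pooled out-of-fold profiles
  pred <- rep(NA_character_, nrow(profiles))
  cm <- uniform_cost_matrix(classes)
  for (f in seq_len(attr(plan, "k"))) {
    tr <- plan$index[plan$fold != f]; te <- plan$index[plan$fold == f]
    mlp <- train_mlp(profiles[tr, , drop = FALSE], set$label[tr],
                     classes = classes, seed = seed + 100 + f,
                     epochs = control$epochs, lr = control$lr,
                     momentum = control$momentum)
    probs <- predict_probs(mlp, profiles[te, , drop = FALSE])
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
    pred[te] <- classes[min_expected_cost_decision(probs, cm)]
  }
  acc <- purrr::map_dbl(classes, function(cl) {
    100 * mean(pred[set$label == cl] == cl)
  })
  tibble(category = classes,
         n = as.integer(table(factor(set$label, levels = classes))),
         auc = aucs, combiner_accuracy = acc)
}

#' Compare flat and hierarchical one-vs-rest training for a branch
#'
#' For every category under `parent`, two out-of-fold AUCs: *hierarchical*,
#' where negatives are restricted to same-parent siblings, and *flat*,
#' where negatives are all other curatable documents in the corpus. A
#' paired two-sided t-test compares the per-category AUC columns.
#'
#' @inheritParams cv_node_performance
#' @param parent Name of the branch node whose children are compared.
#' @return A `flat_hier_comparison`: tibble `by_category` (`category`, `n`,
#'   `flat_auc`, `hier_auc`) plus the means and t-test.
#' @export
compare_flat_vs_hierarchical <- function(corpus, tax, parent,
                                         control = triage_control(), seed = 1) {
  set <- sibling_set_docs(corpus, tax, parent)
  if (is.null(set) || length(set$classes) < 2) {
    abort(paste0("branch '", parent, "' has fewer than 2 categories"))
  }
  classes <- set$classes
  # hierarchical: within the branch
  plan_h <- kfold_plan(nrow(set$docs), control$folds_deeper, set$label, seed = seed)
  tokens_h <- tokenize(classification_text(set$docs))
  prof_h <- cv_sibling_profiles(tokens_h, set$label, classes, plan_h, control)
  # flat: against all curatable documents
  cur <- corpus %>% filter(.data$level0 == "curatable")
  flat_label <- set$label[match(cur$pmid, set$docs$pmid)]
  flat_label[is.na(flat_label)] <- ".outside"
  plan_f <- kfold_plan(nrow(cur), control$folds_deeper, flat_label, seed = seed + 1)
  tokens_f <- tokenize(classification_text(cur))
  by_cat <- purrr::map_dfr(classes, function(cl) {
    hier_auc <- roc_auc(prof_h[, cl], ifelse(set$label == cl, cl, ".rest"),
                        positive = cl)$auc
    sc <- cv_binary_scores(tokens_f, ifelse(flat_label == cl, cl, ".rest"),
                           positive = cl, plan = plan_f, control = control)
    flat_auc <- roc_auc(sc, ifelse(flat_label == cl, cl, ".rest"),
                        positive = cl)$auc
    tibble(category = cl, n = sum(set$label == cl),
           flat_auc = flat_auc, hier_auc = hier_auc)
  })
  flat_hier_comparison(by_cat)
}

#' Assemble a flat-vs-hierarchical comparison from per-category AUC columns
#'
#' @param by_category Tibble with columns `category`, `flat_auc`,
#'   `hier_auc` (and optionally `n`).
#' @return A `flat_hier_comparison` with column means and the paired
#'   two-sided t-test.
#' @export
flat_hier_comparison <- function(by_category) {
  tt <- tryCatch(paired_t_test(by_category$flat_auc, by_category$hier_auc),
                 error = function(e) NULL)
  structure(list(by_category = as_tibble(by_category),
                 mean_flat = mean(by_category$flat_auc),
                 mean_hier = mean(by_category$hier_auc),
                 t_test = tt),
            class = "flat_hier_comparison")
}

#' @export
print.flat_hier_comparison <- function(x, ...) {
  print(x$by_category)
  cat(sprintf("mean AUC: flat %.3f, hierarchical %.3f", x$mean_flat, x$mean_hier))
  if (!is.null(x$t_test)) {
    cat(sprintf("; paired t-test p = %.3f", x$t_test$p_value))
  } else {
    cat("; no difference (zero-variance differences)")
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.flat_hier_comparison <- function(x, ...) x$by_category

#' @export
glance.flat_hier_comparison <- function(x, ...) {
  tibble(mean_flat = x$mean_flat, mean_hier = x$mean_hier,
         statistic = x$t_test$statistic %||% NA_real_,
         df = x$t_test$df %||% NA_real_,
         p_value = x$t_test$p_value %||% NA_real_)
}

#' @export
autoplot.flat_hier_comparison <- function(object, ...) {
  long <- object$by_category %>%
    tidyr::pivot_longer(c("flat_auc", "hier_auc"),
                        names_to = "scheme", values_to = "auc") %>%
    mutate(scheme = ifelse(.data$scheme == "flat_auc", "flat", "hierarchical"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$auc, y = .data$category,
                                     colour = .data$scheme)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = .data$category), colour = "grey70") +
    ggplot2::labs(x = "Out-of-fold AUC", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare uniform and cost-sensitive combining on one sibling set
#'
#' Computes the set's out-of-fold score profiles once, then trains two
#' combiners on them with the same seed: a cost-insensitive one (uniform
#' weights, argmax decision) and a cost-sensitive one (instance weights
#' from the node's cost matrix, minimum-expected-cost decision). Out-of-
#' fold predictions of both are returned side by side, so the effect of
#' the cost matrix on the error profile - e.g. how many true high-priority
#' documents are lost to low-priority categories, or how many documents
#' are dumped into a catch-all - can be read off directly.
#'
#' @inheritParams cv_node_performance
#' @return A `cost_scheme_comparison`: tibble `predictions` (`pmid`,
#'   `true`, `uniform`, `cost_sensitive`), the `classes`, `catch_all`
#'   flags, `cost_matrix`, and a `summary` tibble of error counts per
#'   scheme.
#' @export
compare_cost_schemes <- function(corpus, tax, parent = NULL,
                                 control = triage_control(), seed = 1) {
  set <- sibling_set_docs(corpus, tax, parent)
  if (is.null(set) || length(set$classes) < 2) {
    abort("sibling set has fewer than 2 categories")
  }
  classes <- set$classes
  k <- if (is.null(parent)) control$folds_level1 else control$folds_deeper
  plan <- kfold_plan(nrow(set$docs), k, set$label, seed = seed)
  tokens <- tokenize(classification_text(set$docs))
  profiles <- cv_sibling_profiles(tokens, set$label, classes, plan, control)
  cm_cost <- node_cost_matrix(set, tax,
                              modifyList(control, list(cost_sensitive = TRUE)))
  cm_unif <- uniform_cost_matrix(classes)
  decide <- function(weights, cm) {
    pred <- rep(NA_character_, nrow(profiles))
    for (f in seq_len(attr(plan, "k"))) {
      tr <- plan$index[plan$fold != f]; te <- plan$index[plan$fold == f]
      mlp <- train_mlp(profiles[tr, , drop = FALSE], set$label[tr],
                       weights = weights[tr], classes = classes,
                       h = control$h, seed = seed + 400 + f,
                       epochs = control$epochs, lr = control$lr,
                       momentum = control$momentum)
      probs <- predict_probs(mlp, profiles[te, , drop = FALSE])
      if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
      pred[te] <- classes[min_expected_cost_decision(probs, cm)]
    }
    pred
  }
  n <- nrow(profiles)
  pred_u <- decide(rep(1, n), cm_unif)
  pred_c <- decide(instance_weights(set$label, cm_cost), cm_cost)
  predictions <- tibble(pmid = set$docs$pmid, true = set$label,
                        uniform = pred_u, cost_sensitive = pred_c)
  part <- priority_partition(tax)
  is_high <- function(x) x %in% part$high
  summarise_scheme <- function(pred, scheme) {
    tibble(scheme = scheme,
           errors = sum(pred != set$label),
           true_high_pred_low = if (set$child_level == 1L)
             sum(is_high(set$label) & !is_high(pred)) else NA_integer_,
           pred_catchall = if (any(set$catch_all))
             sum(pred %in% classes[set$catch_all]) else NA_integer_)
  }
  structure(list(predictions = predictions, classes = classes,
                 catch_all = set$catch_all, cost_matrix = cm_cost,
                 summary = bind_rows(summarise_scheme(pred_u, "uniform"),
                                     summarise_scheme(pred_c, "cost_sensitive"))),
            class = "cost_scheme_comparison")
}

#' @export
print.cost_scheme_comparison <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cost_scheme_comparison <- function(x, ...) x$summary

#' Paired two-sided t-test
#'
#' Classical paired t statistic with `n - 1` degrees of freedom. Errors on
#' zero-variance differences (including identical columns), where the
#' statistic is undefined.
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return A tibble: `estimate` (mean difference y - x), `statistic`, `df`,
#'   `p_value`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- y - x
  if (sd(d) == 0) abort("zero-variance differences: paired t-test undefined")
  tt <- t.test(y, x, paired = TRUE, alternative = "two.sided")
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value)
}

#' Read a confusion-matrix fixture (TSV, first column = true category)
#'
#' @param path Path to the TSV.
#' @return A square integer matrix with dimnames.
#' @export
read_confusion_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Recompute the published benchmark arithmetic from bundled fixtures
#'
#' The package ships the published independent-benchmark evaluation tables
#' of the IEDB triage study as plain-text fixtures: the 287-document
#' Level-1 confusion matrix, the per-branch Level-2/3 correct-prediction
#' counts, the Level-0 decision counts on the 1,388-document benchmark, and
#' the 7 paired flat/hierarchical AUCs for the Autoimmunity branch. This
#' function re-derives every headline statistic from those raw counts with
#' the package's own analytics.
#'
#' @param dir Directory holding the fixtures (default: the installed
#'   copies).
#' @param tax Taxonomy supplying the priority partition.
#' @return A list: `level1_accuracy`, `high_priority_accuracy`,
#'   `low_priority_accuracy`, `true_high_predicted_low`,
#'   `level0_sensitivity`, `level0_specificity`, `level2_accuracy`,
#'   `level3_accuracy`, `flat_mean_auc`, `hier_mean_auc`, `paired_t_p`,
#'   plus the underlying objects.
#' @export
benchmark_report <- function(dir = system.file("extdata", "benchmark",
                                               package = "epitriage"),
                             tax = default_taxonomy()) {
  part <- priority_partition(tax)
  conf <- read_confusion_tsv(file.path(dir, "level1_confusion.tsv"))
  brk <- priority_breakdown(conf, part)
  l0 <- yaml::read_yaml(file.path(dir, "level0_counts.yaml"))
  tp <- l0$confirmed_curatable
  fn <- l0$curatable_missed
  fp <- l0$predicted_curatable - tp
  tn <- l0$predicted_uncuratable - fn
  ss <- sensitivity_specificity(tp, fn, fp, tn)
  l23 <- readr::read_tsv(file.path(dir, "level23_correct.tsv"),
                         col_types = readr::cols(level1 = "c", expert_n = "i",
                                                 level2_correct = "i",
                                                 level3_correct = "i"),
                         progress = FALSE)
  l2 <- l23 %>% filter(!is.na(.data$level2_correct))
  l3 <- l23 %>% filter(!is.na(.data$level3_correct))
  auc_tbl <- readr::read_tsv(file.path(dir, "flat_vs_hier_auc.tsv"),
                             col_types = readr::cols(category = "c", n = "i",
                                                     flat_auc = "d",
                                                     hier_auc = "d"),
                             progress = FALSE)
  cmp <- flat_hier_comparison(auc_tbl)
  list(
    level1_accuracy = accuracy_from_confusion(conf),
    high_priority_accuracy = brk$pct_correct_high,
    low_priority_accuracy = brk$pct_correct_low,
    true_high_predicted_low =
      brk$by_prediction$incorrect_other_priority[brk$by_prediction$predicted == "low"],
    level0_sensitivity = ss$sensitivity,
    level0_specificity = ss$specificity,
    level2_accuracy = 100 * sum(l2$level2_correct) / sum(l2$expert_n),
    level3_accuracy = 100 * sum(l3$level3_correct) / sum(l3$expert_n),
    flat_mean_auc = cmp$mean_flat,
    hier_mean_auc = cmp$mean_hier,
    paired_t_p = cmp$t_test$p_value,
    confusion = conf, breakdown = brk, comparison = cmp, level23 = l23
  )
}
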