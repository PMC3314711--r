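#' Control parameters for hierarchy training
#'
#' Collects the tunables of the triage pipeline with the defaults used
#' throughout: 100 information-gain-selected features per task, rare-word
#' floor at 3 documents, linear SVM with `C = 1`, 10-member ensembles,
#' 10-fold cross-validation at Levels 0-1 and 5-fold deeper, a 95%
#' Level-0 sensitivity target, and cost-sensitive combining (instance
#' reweighting plus minimum-expected-cost decisions) switched on. The two
#' cost mechanisms are individually switchable.
#'
#' @param k_features Features per classification task.
#' @param min_df Rare-word document-frequency floor.
#' @param C SVM soft-margin cost.
#' @param m Ensemble members (leave-one-subset-out).
#' @param normalize Unit-length document vectors.
#' @param folds_level0,folds_level1,folds_deeper Cross-validation folds.
#' @param min_examples Minimum documents per category for a sibling set to
#'   be trainable; starved sets fall back to majority-class assignment.
#' @param target_sensitivity Level-0 sensitivity target.
#' @param cost_sensitive Use priority/catch-all cost matrices (else uniform).
#' @param use_instance_weights Reweight combiner training by cost row-sums.
#' @param use_cost_decision Decide by minimum expected cost (else argmax).
#' @param c_hh,c_ll,c_hl,c_lh Priority-matrix costs (Level 1).
#' @param c_spec,c_to_catchall,c_from_catchall Catch-all matrix costs
#'   (Levels 2-3).
#' @param epochs,lr,momentum,h Combiner training parameters (`h = NULL`
#'   means half the category count, at least 2).
#' @return A named list of class `triage_control`.
#' @export
triage_control <- function(k_features = 100, min_df = 3, C = 1, m = 10,
                           normalize = TRUE, folds_level0 = 10,
                           folds_level1 = 10, folds_deeper = 5,
                           min_examples = 5, target_sensitivity = 0.95,
                           cost_sensitive = TRUE, use_instance_weights = TRUE,
                           use_cost_decision = TRUE,
                           c_hh = 1, c_ll = 0.2, c_hl = 5, c_lh = 1,
                           c_spec = 1, c_to_catchall = 5, c_from_catchall = 0.2,
                           epochs = 500, lr = 0.3, momentum = 0.2, h = NULL) {
  out <- as.list(environment())
  class(out) <- "triage_control"
  out
}

#' Calibrate the Level-0 curatability threshold
#'
#' Sweeps cutoffs over midpoints of the sorted unique validation scores
#' (plus the +/-Inf endpoints; a document is called curatable when its
#' score is >= the threshold). Among cutoffs reaching the target
#' sensitivity it returns the one maximising specificity (ties: the lowest
#' such cutoff, keeping the sensitivity margin). If only the
#' accept-everything cutoff reaches the target, `-Inf` is returned with a
#' warning.
#'
#' @param scores Validation scores (typically pooled out-of-fold).
#' @param labels Binary labels; `positive` marks the curatable class.
#' @param target_sensitivity Required sensitivity (default 0.95).
#' @param positive The curatable label (default lexicographically larger).
#' @return The threshold, with attributes `sensitivity` and `specificity`
#'   (its validation rates, as fractions).
#' @export
calibrate_level0_threshold <- function(scores, labels, target_sensitivity = 0.95,
                                       positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) abort("threshold calibration needs both classes present")
  positive <- positive %||% lv[2]
  pos <- labels == positive
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) u[-length(u)] + diff(u) / 2, Inf)
  stats_at <- purrr::map_dfr(cand, function(th) {
    call_pos <- scores >= th
    tibble(threshold = th,
           sensitivity = sum(call_pos & pos) / sum(pos),
           specificity = sum(!call_pos & !pos) / sum(!pos))
  })
  feasible <- stats_at %>% filter(.data$sensitivity >= target_sensitivity)
  best <- feasible %>%
    filter(.data$specificity == max(.data$specificity)) %>%
    slice(1)
  if (is.infinite(best$threshold) && best$threshold < 0 && nrow(feasible) == 1) {
    warn("sensitivity target only reachable by accepting everything; threshold -Inf")
  }
  structure(best$threshold, sensitivity = best$sensitivity,
            specificity = best$specificity)
}

# resolve a sibling set: its documents (curatable, labelled at the child
# level), child-level labels, canonical class order and catch-all flags.
# parent: NULL for the Level-1 set, "L1" or "L1/L2" otherwise.
sibling_set_docs <- function(corpus, tax, parent = NULL) {
  cur <- corpus %>% filter(.data$level0 == "curatable")
  if (is.null(parent)) {
    kids <- taxonomy_children(tax, NULL)
    docs <- cur %>% filter(!is.na(.data$level1))
    label <- docs$level1
  } else {
    path <- strsplit(parent, "/", fixed = TRUE)[[1]]
    pname <- path[length(path)]
    kids <- taxonomy_children(tax, pname)
    if (nrow(kids) == 0) return(NULL)
    child_level <- unique(kids$level)
    if (length(path) == 1) {
      docs <- cur %>% filter(.data$level1 == pname)
    } else {
      docs <- cur %>% filter(.data$level1 == path[1], .data$level2 == pname)
    }
    lab_col <- paste0("level", child_level)
    docs <- docs %>% filter(!is.na(.data[[lab_col]]))
    label <- docs[[lab_col]]
  }
  present <- kids$name[kids$name %in% unique(label)]
  list(docs = docs, label = label, classes = present,
       catch_all = kids$catch_all[match(present, kids$name)],
       child_level = if (is.null(parent)) 1L else unique(kids$level),
       parent = parent)
}

# all trainable sibling-set keys of a taxonomy: ROOT plus every node with
# children, keyed "L1" or "L1/L2"
sibling_set_keys <- function(tax) {
  keys <- "ROOT"
  l1 <- taxonomy_children(tax, NULL)
  for (a in l1$name) {
    kids <- taxonomy_children(tax, a)
    if (nrow(kids) == 0) next
    keys <- c(keys, a)
    for (b in kids$name[kids$level == 2L]) {
      if (nrow(taxonomy_children(tax, b)) > 0) keys <- c(keys, paste(a, b, sep = "/"))
    }
  }
  keys
}

node_cost_matrix <- function(set, tax, control) {
  if (!control$cost_sensitive) return(uniform_cost_matrix(set$classes))
  if (set$child_level == 1L) {
    part <- priority_partition(tax)
    part$high <- intersect(part$high, set$classes)
    part$low <- intersect(part$low, set$classes)
    build_priority_cost_matrix(part, c_hh = control$c_hh, c_ll = control$c_ll,
                               c_hl = control$c_hl, c_lh = control$c_lh)
  } else if (any(set$catch_all)) {
    build_catchall_cost_matrix(set$classes, set$catch_all,
                               c_spec = control$c_spec,
                               c_to_catchall = control$c_to_catchall,
                               c_from_catchall = control$c_from_catchall)
  } else {
    uniform_cost_matrix(set$classes)
  }
}

train_sibling_node <- function(corpus, tax, key, control, seed) {
  parent <- if (identical(key, "ROOT")) NULL else key
  set <- sibling_set_docs(corpus, tax, parent)
  if (is.null(set) || nrow(set$docs) == 0) return(NULL)
  k <- if (is.null(parent)) control$folds_level1 else control$folds_deeper
  viable_min <- max(control$min_examples, ceiling(control$m * k / (k - 1)))
  counts <- table(set$label)
  viable <- names(counts)[counts >= viable_min]
  classes <- intersect(set$classes, viable)
  base <- list(key = key, parent = parent, child_level = set$child_level)
  if (length(classes) < 2) {
    maj <- names(counts)[which.max(counts)]
    return(c(base, list(fallback = maj,
                        basis = if (length(set$classes) == 1) "single" else "majority",
                        classes = set$classes)))
  }
  keep <- set$label %in% classes
  docs <- set$docs[keep, ]
  label <- set$label[keep]
  catch_all <- set$catch_all[match(classes, set$classes)]
  tokens <- tokenize(classification_text(docs))
  tasks <- list()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    fs <- build_feature_set(tokens, label == cl, k = control$k_features,
                            min_df = control$min_df)
    x <- vectorize(tokens, fs, normalize = control$normalize)
    ens <- train_ensemble(x, ifelse(label == cl, cl, ".rest"), positive = cl,
                          m = control$m, seed = seed + i, C = control$C)
    tasks[[cl]] <- list(feature_set = fs, ensemble = ens)
  }
  plan <- kfold_plan(nrow(docs), k, label, seed = seed + 200)
  profiles <- cv_sibling_profiles(tokens, label, classes, plan, control)
  set$classes <- classes
  set$catch_all <- catch_all
  cm <- node_cost_matrix(set, tax, control)
  w <- if (control$use_instance_weights) instance_weights(label, cm) else NULL
  mlp <- train_mlp(profiles, label, weights = w, classes = classes,
                   h = control$h, seed = seed + 300, epochs = control$epochs,
                   lr = control$lr, momentum = control$momentum)
  c(base, list(classes = classes, catch_all = catch_all, tasks = tasks,
               mlp = mlp, cost_matrix = cm,
               oof = tibble(pmid = docs$pmid, label = label) %>%
                 dplyr::bind_cols(as_tibble(profiles))))
}

#' Train the full triage hierarchy
#'
#' Fits the complete model bundle on a labelled corpus: the Level-0
#' curatability ensemble (calibrated to the target sensitivity on pooled
#' out-of-fold cross-validation scores), then, for every sibling set of the
#' taxonomy with at least two sufficiently populated categories, per-
#' category one-vs-rest SVM ensembles whose negatives are restricted to
#' same-parent siblings, with their own feature selection, and a cost-
#' weighted neural-network combiner trained on out-of-fold score profiles.
#' Starved sibling sets fall back to majority-class assignment (logged).
#'
#' @param corpus Labelled corpus tibble: `pmid`, `title`, `abstract`,
#'   `level0`..`level3` (see [join_corpus()], [generate_corpus()]).
#' @param tax A [taxonomy]; label paths are validated against it.
#' @param control A [triage_control()].
#' @param seed Integer master seed; all internal shuffles derive from it.
#' @return A `triage_bundle`.
#' @export
train_triage <- function(corpus, tax = default_taxonomy(),
                         control = triage_control(), seed = 1) {
  validate_labels(corpus %>% select("pmid", "level0", "level1", "level2",
                                    "level3"), tax)
  tokens <- tokenize(classification_text(corpus))
  log <- character()
  level0 <- NULL
  if (length(unique(corpus$level0)) == 2) {
    fs0 <- build_feature_set(tokens, corpus$level0 == "curatable",
                             k = control$k_features, min_df = control$min_df)
    x0 <- vectorize(tokens, fs0, normalize = control$normalize)
    ens0 <- train_ensemble(x0, corpus$level0, positive = "curatable",
                           m = control$m, seed = seed + 10, C = control$C)
    plan0 <- kfold_plan(nrow(corpus), control$folds_level0, corpus$level0,
                        seed = seed + 20)
    oof0 <- cv_binary_scores(tokens, corpus$level0, positive = "curatable",
                             plan = plan0, control = control)
    thr <- calibrate_level0_threshold(oof0, corpus$level0,
                                      target_sensitivity = control$target_sensitivity,
                                      positive = "curatable")
    level0 <- list(feature_set = fs0, ensemble = ens0, threshold = thr,
                   oof = tibble(pmid = corpus$pmid, score = oof0,
                                label = corpus$level0))
  } else {
    log <- c(log, "level0: single class in corpus; gate disabled (all pass)")
  }
  nodes <- list()
  keys <- sibling_set_keys(tax)
  for (i in seq_along(keys)) {
    node <- train_sibling_node(corpus, tax, keys[i], control,
                               seed = seed + 1000 * i)
    if (is.null(node)) next
    if (!is.null(node$fallback)) {
      log <- c(log, paste0("node ", keys[i], ": fallback to '", node$fallback,
                           "' (", node$basis, ")"))
    }
    nodes[[keys[i]]] <- node
  }
  structure(list(taxonomy = tax, control = control, seed = seed,
                 level0 = level0, nodes = nodes, log = log),
            class = "triage_bundle")
}

#' @export
print.triage_bundle <- function(x, ...) {
  cat("<triage_bundle> seed", x$seed, "\n")
  if (!is.null(x$level0)) {
    cat(sprintf("  Level 0: threshold %.4f (val sens %.1f%%, spec %.1f%%)\n",
                as.numeric(x$level0$threshold),
                100 * attr(x$level0$threshold, "sensitivity"),
                100 * attr(x$level0$threshold, "specificity")))
  }
  for (key in names(x$nodes)) {
    n <- x$nodes[[key]]
    cat("  node ", key, ": ",
        if (!is.null(n$fallback)) paste0("fallback -> ", n$fallback)
        else paste0(length(n$classes), " categories"), "\n", sep = "")
  }
  if (length(x$log)) cat("  notes:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' @export
glance.triage_bundle <- function(x, ...) {
  tibble(seed = x$seed,
         threshold = if (is.null(x$level0)) NA_real_ else as.numeric(x$level0$threshold),
         n_nodes = length(x$nodes),
         n_fallback = sum(purrr::map_lgl(x$nodes, ~ !is.null(.x$fallback))))
}

#' @export
tidy.triage_bundle <- function(x, ...) {
  purrr::map_dfr(x$nodes, function(n) {
    tibble(node = n$key, child_level = n$child_level,
           n_categories = length(n$classes),
           fallback = n$fallback %||% NA_character_)
  })
}

# score a set of documents through one sibling node; returns the chosen
# category, the decision basis, and the per-sibling score profile
predict_node <- function(node, tokens, control) {
  n <- length(tokens)
  if (!is.null(node$fallback)) {
    return(list(category = rep(node$fallback, n), basis = rep(node$basis, n),
                profile = NULL))
  }
  profiles <- matrix(NA_real_, n, length(node$classes),
                     dimnames = list(NULL, node$classes))
  for (cl in node$classes) {
    task <- node$tasks[[cl]]
    x <- vectorize(tokens, task$feature_set, normalize = control$normalize)
    profiles[, cl] <- ensemble_score(task$ensemble, x)
  }
  probs <- predict_probs(node$mlp, profiles)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, node$classes))
  cm <- if (control$use_cost_decision) node$cost_matrix
        else uniform_cost_matrix(node$classes)
  idx <- min_expected_cost_decision(probs, cm)
  list(category = node$classes[idx],
       basis = rep(if (control$use_cost_decision) "min-cost" else "argmax", n),
       profile = profiles)
}

#' Classify a corpus through the trained hierarchy
#'
#' Each document is gated at Level 0 (score vs the calibrated threshold);
#' documents called uncuratable stop there with `NA` categories. Curatable
#' documents get a Level-1 assignment from the combiner, then descend
#' greedily into the predicted branch, stopping where the taxonomy skips or
#' ends (e.g. branches with no Level-2/3 assignments). Deterministic given
#' the bundle.
#'
#' @param bundle A [train_triage()] result.
#' @param corpus Corpus tibble (`pmid`, `title`, `abstract`).
#' @return A tibble: `pmid`, `level0_score`, `level0_call`, `level1`,
#'   `level2`, `level3`, `basis`, with a per-level count summary as
#'   attribute `"summary"`.
#' @export
classify_corpus <- function(bundle, corpus) {
  control <- bundle$control
  res <- tibble(pmid = corpus$pmid,
                level0_score = NA_real_, level0_call = "curatable",
                level1 = NA_character_, level2 = NA_character_,
                level3 = NA_character_, basis = NA_character_)
  if (nrow(corpus) == 0) {
    attr(res, "summary") <- triage_summary(res)
    return(res)
  }
  tokens <- tokenize(classification_text(corpus))
  if (!is.null(bundle$level0)) {
    x0 <- vectorize(tokens, bundle$level0$feature_set,
                    normalize = control$normalize)
    res$level0_score <- ensemble_score(bundle$level0$ensemble, x0)
    res$level0_call <- ifelse(res$level0_score >= as.numeric(bundle$level0$threshold),
                              "curatable", "uncuratable")
  }
  cur_idx <- which(res$level0_call == "curatable")
  root <- bundle$nodes[["ROOT"]]
  if (length(cur_idx) > 0 && !is.null(root)) {
    p1 <- predict_node(root, tokens[cur_idx], control)
    res$level1[cur_idx] <- p1$category
    res$basis[cur_idx] <- p1$basis
    for (l1 in unique(p1$category)) {
      idx1 <- cur_idx[p1$category == l1]
      node1 <- bundle$nodes[[l1]]
      if (is.null(node1)) next
      p2 <- predict_node(node1, tokens[idx1], control)
      lvl_col <- paste0("level", node1$child_level) # level3 for skip branches
      res[[lvl_col]][idx1] <- p2$category
      if (node1$child_level == 2L) {
        for (l2 in unique(p2$category)) {
          node2 <- bundle$nodes[[paste(l1, l2, sep = "/")]]
          if (is.null(node2)) next
          idx2 <- idx1[p2$category == l2]
          p3 <- predict_node(node2, tokens[idx2], control)
          res$level3[idx2] <- p3$category
        }
      }
    }
  }
  attr(res, "summary") <- triage_summary(res)
  res
}

#' @rdname classify_corpus
#' @param record A single-row corpus tibble (or a list with `pmid`,
#'   `title`, `abstract`).
#' @export
classify_document <- function(bundle, record) {
  classify_corpus(bundle, as_tibble(record))
}

#' Per-level assignment counts of a triage result
#'
#' @param results A [classify_corpus()] result.
#' @return A tibble: `level`, `category`, `n` (with `NA` categories counted),
#'   summing to the corpus size at every level.
#' @export
triage_summary <- function(results) {
  purrr::map_dfr(c("level0_call", "level1", "level2", "level3"), function(col) {
    results %>%
      count(category = .data[[col]]) %>%
      mutate(level = sub("_call", "", sub("level", "", col)), .before = 1)
  }) %>%
    mutate(level = paste0("level", .data$level))
}

#' Write triage results as TSV
#'
#' @param results A [classify_corpus()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triage_results <- function(results, path) {
  readr::write_tsv(results %>% select("pmid", "level0_score", "level0_call",
                                      "level1", "level2", "level3", "basis"),
                   path, na = "NA", progress = FALSE)
  invisible(path)
}
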