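#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the triage pipeline
#' assumes in real abstracts: a shared background vocabulary (Zipf-
#' distributed) mixed with small per-category signal vocabularies along
#' each document's taxonomy path, curatable/uncuratable imbalance, and a
#' dominant Infectious Disease branch. Defaults: `alpha = 0.7` of tokens
#' from the background, 20 signal terms per taxonomy node, Poisson(150)
#' document length, 75% uncuratable documents, and a 5x weight on the
#' Infectious Disease leaf - roughly a 2,000-document desk-scale corpus
#' under the bundled taxonomy.
#'
#' @param taxonomy A [taxonomy] (default: the bundled tree).
#' @param docs_per_leaf Curatable documents per leaf path (before weights).
#' @param leaf_weights Named multipliers on specific Level-1 branches
#'   (applied to every leaf under that branch).
#' @param uncuratable_fraction Fraction of the final corpus that is
#'   uncuratable.
#' @param doc_length Mean document length (tokens), Poisson.
#' @param alpha Background mixing weight: each token comes from the
#'   background with probability `alpha`, otherwise from one of the
#'   document's path-node signal vocabularies.
#' @param signal_terms Signal vocabulary size per taxonomy node.
#' @param background_terms Background vocabulary size.
#' @param term_space Upper bound on total distinct terms (sanity check).
#' @param overlap List of `list(from =, to =, fraction =)` entries: the
#'   first `fraction * signal_terms` terms of node `to` are replaced by
#'   node `from`'s leading terms, making the pair confusable. Default none
#'   (signal vocabularies pairwise disjoint).
#' @param seed Master seed (mandatory); every corpus is reproducible from
#'   its config alone.
#' @return A `generator_config` list.
#' @export
generator_config <- function(taxonomy = default_taxonomy(), docs_per_leaf = 23,
                             leaf_weights = c("Infectious Disease" = 5),
                             uncuratable_fraction = 0.75, doc_length = 150,
                             alpha = 0.7, signal_terms = 20,
                             background_terms = 2000, term_space = 10000,
                             overlap = list(), seed = 1) {
  if (uncuratable_fraction < 0 || uncuratable_fraction >= 1) {
    abort("uncuratable_fraction must be in [0, 1)")
  }
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (doc_length <= 0) abort("doc_length must be positive")
  if (is.null(seed)) abort("a seed is mandatory")
  out <- as.list(environment())
  class(out) <- "generator_config"
  out
}

#' Build the topic model behind the generator
#'
#' Deterministic given the config: a Zipf background distribution plus a
#' uniform signal vocabulary for every taxonomy node and for the two
#' curatability pseudo-nodes (`curatable`, shared by every curatable
#' document's path, and `uncuratable`). Signal vocabularies are pairwise
#' disjoint and disjoint from the background unless `overlap` entries
#' deliberately share terms between a confusable pair.
#'
#' @param tax A [taxonomy].
#' @param config A [generator_config()].
#' @return A `topic_model`: `background` (tibble `term`, `prob`), `nodes`
#'   (named list of signal-term vectors), `alpha`, the taxonomy.
#' @export
build_topic_model <- function(tax, config = generator_config(taxonomy = tax)) {
  node_names <- c("curatable", "uncuratable", tax$nodes$name)
  s <- config$signal_terms
  v_bg <- config$background_terms
  if (s * length(node_names) + v_bg > config$term_space) {
    abort(paste0("term budget exceeded: ", s, " x ", length(node_names),
                 " signal terms + ", v_bg, " background terms > term_space = ",
                 config$term_space))
  }
  prob <- 1 / seq_len(v_bg)
  background <- tibble(term = sprintf("bw%05d", seq_len(v_bg)),
                       prob = prob / sum(prob))
  nodes <- purrr::map(seq_along(node_names), function(i) {
    sprintf("sg%dx%d", i, seq_len(s))
  })
  names(nodes) <- node_names
  # each overlap entry claims the next unused block of the target's terms,
  # so several sources can feed one heterogeneous (catch-all-like) node
  offset <- setNames(rep(0L, length(nodes)), names(nodes))
  for (ov in config$overlap) {
    n_shared <- floor(ov$fraction * s)
    if (n_shared > 0) {
      pos <- offset[[ov$to]] + seq_len(n_shared)
      if (max(pos) > s) abort("overlap entries exceed the target node's vocabulary")
      nodes[[ov$to]][pos] <- nodes[[ov$from]][seq_len(n_shared)]
      offset[[ov$to]] <- offset[[ov$to]] + n_shared
    }
  }
  structure(list(background = background, nodes = nodes,
                 alpha = config$alpha, doc_length = config$doc_length,
                 taxonomy = tax, seed = config$seed),
            class = "topic_model")
}

# draw one document's tokens from the mixture; uses the current RNG stream
draw_tokens <- function(model, path_nodes) {
  len <- max(1L, rpois(1, model$doc_length))
  from_bg <- runif(len) < model$alpha
  toks <- character(len)
  n_bg <- sum(from_bg)
  if (n_bg > 0) {
    toks[from_bg] <- sample(model$background$term, n_bg, replace = TRUE,
                            prob = model$background$prob)
  }
  n_sig <- len - n_bg
  if (n_sig > 0) {
    which_node <- sample(path_nodes, n_sig, replace = TRUE)
    sig <- character(n_sig)
    for (nd in unique(which_node)) {
      pick <- which_node == nd
      sig[pick] <- sample(model$nodes[[nd]], sum(pick), replace = TRUE)
    }
    toks[!from_bg] <- sig
  }
  toks
}

doc_path_nodes <- function(level0, level1, level2, level3) {
  if (level0 == "uncuratable") return("uncuratable")
  c("curatable", level1[!is.na(level1)], level2[!is.na(level2)],
    level3[!is.na(level3)])
}

#' Sample one labelled document
#'
#' Document length is Poisson; each token is background with probability
#' `alpha`, otherwise drawn uniformly from one of the label path's node
#' vocabularies. Uncuratable documents mix background with a disjoint
#' uncuratable vocabulary only. The first eight tokens become the title.
#'
#' @param model A [build_topic_model()] result.
#' @param level0 `"curatable"` or `"uncuratable"`.
#' @param level1,level2,level3 Label path (validated against the model's
#'   taxonomy; `NA` where absent).
#' @param pmid Identifier for the record.
#' @param seed Seed for this document's draw.
#' @return A one-row tibble: `pmid`, `title`, `abstract`, `level0`..`level3`.
#' @export
sample_document <- function(model, level0, level1 = NA, level2 = NA,
                            level3 = NA, pmid = "1", seed) {
  rec <- tibble(pmid = as.character(pmid), level0 = level0,
                level1 = as.character(level1), level2 = as.character(level2),
                level3 = as.character(level3))
  validate_labels(rec, model$taxonomy)
  toks <- withr::with_seed(seed,
    draw_tokens(model, doc_path_nodes(level0, level1, level2, level3)))
  n_title <- min(8L, length(toks))
  tibble(pmid = as.character(pmid),
         title = paste(toks[seq_len(n_title)], collapse = " "),
         abstract = paste(toks[-seq_len(n_title)], collapse = " ")) %>%
    dplyr::bind_cols(rec[, -1])
}

#' Generate a labelled synthetic corpus
#'
#' Curatable documents are spread over the taxonomy's leaf paths
#' (`docs_per_leaf`, scaled by `leaf_weights` on their Level-1 branch);
#' uncuratable documents are appended so they make up
#' `uncuratable_fraction` of the corpus. Fully deterministic given the
#' config.
#'
#' @param config A [generator_config()].
#' @return A labelled corpus tibble (`pmid`, `title`, `abstract`,
#'   `level0`..`level3`) with the config attached as attribute `"config"`.
#' @export
generate_corpus <- function(config = generator_config()) {
  tax <- config$taxonomy
  model <- build_topic_model(tax, config)
  leaves <- leaf_paths(tax)
  w <- rep(1, nrow(leaves))
  if (length(config$leaf_weights)) {
    hit <- leaves$level1 %in% names(config$leaf_weights)
    w[hit] <- config$leaf_weights[leaves$level1[hit]]
  }
  n_leaf <- as.integer(round(config$docs_per_leaf * w))
  n_cur <- sum(n_leaf)
  f <- config$uncuratable_fraction
  n_unc <- as.integer(round(n_cur * f / (1 - f)))
  plan <- bind_rows(
    leaves[rep(seq_len(nrow(leaves)), n_leaf), ] %>%
      mutate(level0 = "curatable", .before = 1),
    tibble(level0 = rep("uncuratable", n_unc), level1 = NA_character_,
           level2 = NA_character_, level3 = NA_character_)
  )
  docs <- withr::with_seed(config$seed, {
    purrr::map_dfr(seq_len(nrow(plan)), function(i) {
      r <- plan[i, ]
      toks <- draw_tokens(model, doc_path_nodes(r$level0, r$level1,
                                                r$level2, r$level3))
      n_title <- min(8L, length(toks))
      tibble(pmid = sprintf("SYN%06d", i),
             title = paste(toks[seq_len(n_title)], collapse = " "),
             abstract = paste(toks[-seq_len(n_title)], collapse = " "))
    })
  })
  out <- dplyr::bind_cols(docs, plan)
  attr(out, "config") <- config
  out
}

#' Write a synthetic benchmark to disk
#'
#' Emits a MEDLINE-dialect corpus (`corpus.medline`), a label table
#' (`labels.tsv`) and a JSON manifest recording the full generator config;
#' regeneration from the manifest reproduces the files byte for byte.
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the paths written.
#' @export
generate_benchmark <- function(config, dir, force = FALSE) {
  paths <- file.path(dir, c("corpus.medline", "labels.tsv", "manifest.json"))
  if (any(file.exists(paths)) && !force) {
    abort(paste0("output exists in ", dir, " (use force = TRUE)"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(config)
  write_abstracts(corpus %>% select("pmid", "title", "abstract"), paths[1],
                  format = "medline")
  write_label_table(corpus, paths[2])
  manifest <- unclass(config)
  manifest$taxonomy <- as.list(config$taxonomy$nodes)
  manifest$leaf_weights <- as.list(config$leaf_weights)
  jsonlite::write_json(manifest, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}

#' @rdname generate_benchmark
#' @param path Path to a benchmark `manifest.json`.
#' @export
load_generator_manifest <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  generator_config(
    taxonomy = taxonomy(as_tibble(l$taxonomy)),
    docs_per_leaf = l$docs_per_leaf,
    leaf_weights = unlist(l$leaf_weights) %||% c(),
    uncuratable_fraction = l$uncuratable_fraction,
    doc_length = l$doc_length, alpha = l$alpha,
    signal_terms = l$signal_terms, background_terms = l$background_terms,
    term_space = l$term_space,
    overlap = l$overlap %||% list(), seed = l$seed
  )
}

#' Purpose-built generator presets
#'
#' `confusable_config()`: two Level-1 categories - a rare high-priority one
#' and a 10x larger low-priority one - where the rare category shares 90%
#' of its signal terms with the big one and only 10% of tokens carry signal
#' at all. Borderline documents abound, so a cost-insensitive combiner
#' loses high-priority documents to the big low-priority category; the
#' priority cost matrix is designed to suppress exactly that error.
#'
#' `nested_config()`: two Level-1 branches of three Level-2 leaves each,
#' where each leaf shares half its signal with a leaf of the *other*
#' branch. Distinguishing a leaf from its own siblings (hierarchical
#' training) is easy; distinguishing it from the whole corpus (flat
#' training) runs into the cross-branch twins.
#'
#' `catchall_config()`: one branch with three specific Level-2 categories
#' plus an `OTH` catch-all whose vocabulary is largely borrowed from all
#' three siblings - heterogeneous, as real "Other" categories are - so an
#' unweighted combiner over-predicts it.
#'
#' @param seed Master seed.
#' @param docs_per_leaf Documents per leaf (see each preset's imbalance).
#' @return A [generator_config()].
#' @export
confusable_config <- function(seed = 1, docs_per_leaf = 40) {
  tax <- taxonomy(tibble(
    name = c("RareDisease", "CommonDisease"), level = 1L,
    parent = NA_character_, priority = c("high", "low")))
  generator_config(
    taxonomy = tax, docs_per_leaf = docs_per_leaf,
    leaf_weights = c(CommonDisease = 10), uncuratable_fraction = 0,
    alpha = 0.9,
    overlap = list(list(from = "CommonDisease", to = "RareDisease",
                        fraction = 0.9)),
    seed = seed)
}

#' @rdname confusable_config
#' @export
nested_config <- function(seed = 1, docs_per_leaf = 60) {
  tax <- taxonomy(bind_rows(
    tibble(name = c("BranchA", "BranchB"), level = 1L, parent = NA_character_,
           priority = c("high", "low")),
    tibble(name = c("A1", "A2", "A3"), level = 2L, parent = "BranchA",
           priority = NA_character_),
    tibble(name = c("B1", "B2", "B3"), level = 2L, parent = "BranchB",
           priority = NA_character_)))
  generator_config(
    taxonomy = tax, docs_per_leaf = docs_per_leaf, leaf_weights = c(),
    uncuratable_fraction = 0, alpha = 0.9,
    overlap = list(list(from = "B1", to = "A1", fraction = 0.5),
                   list(from = "B2", to = "A2", fraction = 0.5),
                   list(from = "B3", to = "A3", fraction = 0.5)),
    seed = seed)
}

#' @rdname confusable_config
#' @export
catchall_config <- function(seed = 1, docs_per_leaf = 50) {
  tax <- taxonomy(bind_rows(
    tibble(name = "Disease", level = 1L, parent = NA_character_,
           priority = "high"),
    tibble(name = c("S1", "S2", "S3", "OTH"), level = 2L, parent = "Disease",
           priority = NA_character_, catch_all = c(FALSE, FALSE, FALSE, TRUE))))
  generator_config(
    taxonomy = tax, docs_per_leaf = docs_per_leaf, leaf_weights = c(),
    uncuratable_fraction = 0, alpha = 0.9,
    overlap = list(list(from = "S1", to = "OTH", fraction = 0.3),
                   list(from = "S2", to = "OTH", fraction = 0.3),
                   list(from = "S3", to = "OTH", fraction = 0.3)),
    seed = seed)
}
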