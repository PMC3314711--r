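# JSON serialization of trained model bundles: a bundle directory holds
# manifest.json (provenance: seeds, control, counts) and model.json (all
# weights). Text-only, documented container; no binary formats.

fs_to_list <- function(fs) {
  list(term = fs$term, ig = fs$ig, idf = fs$idf,
       N = attr(fs, "N"), k = attr(fs, "k"))
}

fs_from_list <- function(l) {
  out <- tibble(term = unlist(l$term), ig = unlist(l$ig), idf = unlist(l$idf))
  attr(out, "N") <- l$N
  attr(out, "k") <- l$k
  class(out) <- c("feature_set", class(out))
  out
}

ens_to_list <- function(ens) {
  list(m = ens$m, seed = ens$seed, C = ens$C, positive = ens$positive,
       terms = ens$terms,
       members = purrr::map(ens$members, ~ list(w = unname(.x$w), b = .x$b,
                                                negative = .x$negative)))
}

ens_from_list <- function(l) {
  terms <- unlist(l$terms)
  members <- purrr::map(l$members, function(mm) {
    w <- unlist(mm$w); names(w) <- terms
    structure(list(w = w, b = mm$b, C = l$C, positive = l$positive,
                   negative = mm$negative), class = "linear_model")
  })
  structure(list(members = members, m = l$m, seed = l$seed, C = l$C,
                 positive = l$positive, terms = terms),
            class = "ensemble_model")
}

mlp_to_list <- function(mlp) {
  mlp[c("W1", "W2", "classes", "center", "scale", "h", "seed", "epochs",
        "lr", "momentum", "final_loss")]
}

mlp_from_list <- function(l) {
  structure(list(W1 = as.matrix(l$W1), W2 = as.matrix(l$W2),
                 classes = unlist(l$classes),
                 center = unlist(l$center), scale = unlist(l$scale),
                 h = l$h, seed = l$seed, epochs = l$epochs, lr = l$lr,
                 momentum = l$momentum, final_loss = l$final_loss),
            class = "mlp_model")
}

cm_to_list <- function(cm) {
  list(categories = rownames(cm), costs = unclass(cm))
}

cm_from_list <- function(l) {
  m <- as.matrix(l$costs)
  cats <- unlist(l$categories)
  dimnames(m) <- list(true = cats, predicted = cats)
  new_cost_matrix(m)
}

#' Save / load a trained triage bundle
#'
#' Serializes every model component (feature sets, ensemble weights,
#' combiner weights, cost matrices, taxonomy, control, threshold) to a
#' JSON container: `<dir>/model.json` plus a lightweight
#' `<dir>/manifest.json` carrying provenance only (seed, control, node
#' keys, package version) - the manifest is what reproducibility checks
#' should hash.
#'
#' @param bundle A [train_triage()] result.
#' @param dir Output directory (created; errors if it already holds a
#'   bundle unless `force`).
#' @param force Overwrite an existing bundle.
#' @return `dir` (save) or the restored `triage_bundle` (load).
#' @export
save_triage_bundle <- function(bundle, dir, force = FALSE) {
  if (file.exists(file.path(dir, "model.json")) && !force) {
    abort(paste0("bundle already exists at ", dir, " (use force = TRUE)"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- list(
    taxonomy = as.list(bundle$taxonomy$nodes),
    control = unclass(bundle$control),
    seed = bundle$seed,
    level0 = if (!is.null(bundle$level0)) list(
      feature_set = fs_to_list(bundle$level0$feature_set),
      ensemble = ens_to_list(bundle$level0$ensemble),
      threshold = as.numeric(bundle$level0$threshold),
      threshold_sensitivity = attr(bundle$level0$threshold, "sensitivity"),
      threshold_specificity = attr(bundle$level0$threshold, "specificity")
    ),
    nodes = purrr::map(bundle$nodes, function(n) {
      if (!is.null(n$fallback)) {
        n[c("key", "parent", "child_level", "fallback", "basis", "classes")]
      } else {
        list(key = n$key, parent = n$parent, child_level = n$child_level,
             classes = n$classes, catch_all = n$catch_all,
             cost_matrix = cm_to_list(n$cost_matrix),
             mlp = mlp_to_list(n$mlp),
             tasks = purrr::map(n$tasks, ~ list(
               feature_set = fs_to_list(.x$feature_set),
               ensemble = ens_to_list(.x$ensemble))))
      }
    }),
    log = bundle$log
  )
  jsonlite::write_json(model, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package = "epitriage",
    version = as.character(utils::packageVersion("epitriage")),
    seed = bundle$seed,
    control = unclass(bundle$control),
    threshold = if (!is.null(bundle$level0)) as.numeric(bundle$level0$threshold),
    nodes = names(bundle$nodes),
    log = bundle$log
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}

#' @rdname save_triage_bundle
#' @export
load_triage_bundle <- function(dir) {
  path <- file.path(dir, "model.json")
  if (!file.exists(path)) abort(paste0("no bundle at ", dir))
  l <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  control <- l$control
  class(control) <- "triage_control"
  level0 <- NULL
  if (!is.null(l$level0)) {
    thr <- structure(l$level0$threshold,
                     sensitivity = l$level0$threshold_sensitivity,
                     specificity = l$level0$threshold_specificity)
    level0 <- list(feature_set = fs_from_list(l$level0$feature_set),
                   ensemble = ens_from_list(l$level0$ensemble),
                   threshold = thr)
  }
  nodes <- purrr::map(l$nodes, function(n) {
    out <- list(key = n$key, parent = n$parent, child_level = n$child_level,
                classes = unlist(n$classes))
    if (!is.null(n$fallback)) {
      c(out, list(fallback = n$fallback, basis = n$basis))
    } else {
      c(out, list(catch_all = unlist(n$catch_all),
                  cost_matrix = cm_from_list(n$cost_matrix),
                  mlp = mlp_from_list(n$mlp),
                  tasks = purrr::map(n$tasks, ~ list(
                    feature_set = fs_from_list(.x$feature_set),
                    ensemble = ens_from_list(.x$ensemble)))))
    }
  })
  structure(list(taxonomy = taxonomy(as_tibble(l$taxonomy)), control = control,
                 seed = l$seed, level0 = level0, nodes = nodes,
                 log = unlist(l$log)),
            class = "triage_bundle")
}
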