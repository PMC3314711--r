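#' Category taxonomies for hierarchical triage
#'
#' A taxonomy is the tree of disease/topic categories that curatable
#' abstracts are routed through: Level 1 holds the broad disease areas,
#' Levels 2 and 3 increasingly specific sub-categories. Every Level-1
#' category carries a curation `priority` flag (`"high"` or `"low"`), and
#' any category may be flagged `catch_all` (an "Other"/"Various" bucket
#' collecting heterogeneous documents). Two structural irregularities are
#' supported because real curation trees have them: a Level-1 branch may
#' *skip Level 2* (its children sit directly at Level 3), and a branch may
#' terminate early (`max_level`), receiving no assignments below it.
#'
#' @param nodes A data frame with columns `name`, `level` (1, 2 or 3),
#'   `parent` (`NA` for Level-1 nodes), `priority` (`"high"`/`"low"`,
#'   Level-1 only), `catch_all` (logical), `skip_level2` (logical, Level-1
#'   only) and `max_level` (integer, Level-1 only; 1 means the branch gets
#'   no Level-2/3 assignments).
#' @return A validated `taxonomy` object.
#' @seealso [load_taxonomy()], [default_taxonomy()], [priority_partition()]
#' @export
taxonomy <- function(nodes) {
  nodes <- as_tibble(nodes)
  required <- c("name", "level", "parent", "priority", "catch_all",
                "skip_level2", "max_level")
  for (col in setdiff(required, names(nodes))) {
    nodes[[col]] <- switch(col,
      catch_all = FALSE, skip_level2 = FALSE,
      max_level = NA_integer_, priority = NA_character_,
      parent = NA_character_)
  }
  nodes <- nodes %>%
    mutate(
      name = as.character(.data$name),
      level = as.integer(.data$level),
      parent = as.character(.data$parent),
      priority = as.character(.data$priority),
      catch_all = as.logical(.data$catch_all) %|NA|% FALSE,
      skip_level2 = as.logical(.data$skip_level2) %|NA|% FALSE,
      max_level = dplyr::coalesce(as.integer(.data$max_level),
                                  ifelse(.data$level == 1L, 3L, NA_integer_))
    ) %>%
    select(dplyr::all_of(required))
  out <- structure(list(nodes = nodes), class = "taxonomy")
  validate_taxonomy(out)
  out
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

validate_taxonomy <- function(tax) {
  nodes <- tax$nodes
  if (nrow(nodes) == 0) abort("taxonomy config is empty: no categories defined")
  if (any(!nodes$level %in% 1:3)) {
    abort(paste0("taxonomy node(s) with level outside 1..3: ",
                 paste(nodes$name[!nodes$level %in% 1:3], collapse = ", ")))
  }
  l1 <- nodes %>% filter(.data$level == 1L)
  if (nrow(l1) == 0) abort("taxonomy has no Level-1 categories")
  if (any(!is.na(l1$parent))) {
    abort(paste0("Level-1 node with a parent (must be root): ",
                 paste(l1$name[!is.na(l1$parent)], collapse = ", ")))
  }
  missing_prio <- l1$name[is.na(l1$priority) | !l1$priority %in% c("high", "low")]
  if (length(missing_prio)) {
    abort(paste0("Level-1 node(s) missing a high/low priority flag: ",
                 paste(missing_prio, collapse = ", ")))
  }
  deeper <- nodes %>% filter(.data$level > 1L)
  if (any(is.na(deeper$parent))) {
    abort(paste0("orphan node (no parent): ",
                 paste(deeper$name[is.na(deeper$parent)], collapse = ", ")))
  }
  # each deeper node's parent must exist at the structurally correct level:
  # level-2 nodes hang off level-1; level-3 nodes hang off level-2, or off a
  # level-1 node whose branch skips level 2.
  for (i in seq_len(nrow(deeper))) {
    nm <- deeper$name[i]; lv <- deeper$level[i]; pa <- deeper$parent[i]
    ok_parent_levels <- if (lv == 2L) 1L else c(2L, 1L)
    pmatch_ <- nodes %>% filter(.data$name == pa, .data$level %in% ok_parent_levels)
    if (nrow(pmatch_) == 0) {
      abort(paste0("orphan node '", nm, "' (level ", lv,
                   "): parent '", pa, "' not found at an allowed level"))
    }
    if (lv == 3L && all(pmatch_$level == 1L) && !any(pmatch_$skip_level2)) {
      abort(paste0("node '", nm, "' sits at Level 3 under Level-1 parent '",
                   pa, "', but that branch is not flagged skip_level2"))
    }
    if (lv == 2L && any(pmatch_$skip_level2)) {
      abort(paste0("node '", nm, "' is a Level-2 child of '", pa,
                   "', which is flagged skip_level2"))
    }
  }
  dup <- nodes %>%
    count(.data$level, .data$parent, .data$name) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate sibling name(s): ", paste(dup$name, collapse = ", ")))
  }
  invisible(tax)
}

#' Load a taxonomy from a YAML or JSON config file
#'
#' The config lists Level-1 categories, each with a `priority` flag and
#' optional nested `children`; children of a `skip_level2` branch are taken
#' to be Level-3 nodes. See `system.file("extdata", "default_taxonomy.yaml",
#' package = "epitriage")` for the reference layout.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config.
#' @return A validated [taxonomy] object.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) abort(paste0("taxonomy config not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$categories) || length(cfg$categories) == 0) {
    abort("taxonomy config is empty: no 'categories' entry")
  }
  rows <- list()
  add_node <- function(node, level, parent, skip2_branch) {
    rows[[length(rows) + 1L]] <<- tibble(
      name = as.character(node$name),
      level = as.integer(level),
      parent = parent %||% NA_character_,
      priority = as.character(node$priority %||% NA_character_),
      catch_all = isTRUE(node$catch_all),
      skip_level2 = isTRUE(node$skip_level2),
      max_level = as.integer(node$max_level %||% NA_integer_)
    )
    kids <- node$children %||% list()
    child_level <- if (level == 1L && isTRUE(node$skip_level2)) 3L else level + 1L
    for (kid in kids) add_node(kid, child_level, as.character(node$name), FALSE)
  }
  for (cat in cfg$categories) add_node(cat, 1L, NULL, FALSE)
  taxonomy(bind_rows(rows))
}

#' The bundled default curation taxonomy
#'
#' Seven Level-1 disease areas (Allergy, Autoimmunity, Infectious Disease
#' and Transplantation flagged high priority; Cancer, HIV and Other low),
#' Autoimmunity's seven Level-2 sub-categories, and the seven Level-3
#' antigen/topic categories under Diabetes (with OTH and VAR flagged
#' catch-all). Transplantation and Cancer branches skip Level 2; HIV
#' terminates at Level 1. Deeper branches of a production tree are supplied
#' by user config.
#'
#' @return A [taxonomy] object.
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "default_taxonomy.yaml",
                            package = "epitriage"))
}

#' Split Level-1 categories into the high/low curation-priority partition
#'
#' @param tax A [taxonomy].
#' @return A list with character vectors `high` and `low`, in taxonomy order.
#' @export
priority_partition <- function(tax) {
  l1 <- tax$nodes %>% filter(.data$level == 1L)
  list(high = l1$name[l1$priority == "high"],
       low  = l1$name[l1$priority == "low"])
}

#' Children of a taxonomy node
#'
#' @param tax A [taxonomy].
#' @param parent Name of the parent node, or `NULL` for the Level-1 set.
#' @return A tibble of child nodes (possibly empty).
#' @export
taxonomy_children <- function(tax, parent = NULL) {
  if (is.null(parent)) {
    tax$nodes %>% filter(.data$level == 1L)
  } else {
    tax$nodes %>% filter(!is.na(.data$parent), .data$parent == !!parent)
  }
}

# all root-to-leaf label paths, one row per leaf, as (level1, level2, level3)
#' Enumerate the taxonomy's leaf label paths
#'
#' @param tax A [taxonomy].
#' @return A tibble with columns `level1`, `level2`, `level3` (`NA` where a
#'   level is skipped or the branch ends early).
#' @export
leaf_paths <- function(tax) {
  nodes <- tax$nodes
  out <- list()
  for (i in which(nodes$level == 1L)) {
    l1 <- nodes$name[i]
    kids <- taxonomy_children(tax, l1)
    if (nrow(kids) == 0) {
      out[[length(out) + 1L]] <- tibble(level1 = l1, level2 = NA_character_,
                                        level3 = NA_character_)
      next
    }
    for (j in seq_len(nrow(kids))) {
      kid <- kids[j, ]
      if (kid$level == 3L) { # skip-level-2 branch
        out[[length(out) + 1L]] <- tibble(level1 = l1, level2 = NA_character_,
                                          level3 = kid$name)
      } else {
        gkids <- taxonomy_children(tax, kid$name)
        if (nrow(gkids) == 0) {
          out[[length(out) + 1L]] <- tibble(level1 = l1, level2 = kid$name,
                                            level3 = NA_character_)
        } else {
          out[[length(out) + 1L]] <- tibble(level1 = l1, level2 = kid$name,
                                            level3 = gkids$name)
        }
      }
    }
  }
  bind_rows(out)
}

#' Validate a label table against a taxonomy
#'
#' Checks every record's label path: uncuratable records must have `NA` at
#' Levels 1-3; each non-`NA` deeper label must be a child of the preceding
#' one (honouring skip-Level-2 branches and early-terminating branches);
#' `NA` at a level forces `NA` below it unless the branch skips that level.
#'
#' @param labels A label tibble as returned by [read_label_table()].
#' @param tax A [taxonomy].
#' @return `labels`, invisibly; errors name the offending PMID and level.
#' @export
validate_labels <- function(labels, tax) {
  nodes <- tax$nodes
  l1 <- nodes %>% filter(.data$level == 1L)
  bad <- function(pmid, level, msg) {
    abort(paste0("invalid label for PMID ", pmid, " at Level ", level, ": ", msg))
  }
  for (i in seq_len(nrow(labels))) {
    r <- labels[i, ]
    if (r$level0 == "uncuratable") {
      if (!all(is.na(c(r$level1, r$level2, r$level3)))) {
        bad(r$pmid, "1-3", "uncuratable records must have NA category labels")
      }
      next
    }
    if (is.na(r$level1)) {
      if (!all(is.na(c(r$level2, r$level3)))) {
        bad(r$pmid, 2, "Level 2/3 label without a Level 1 label")
      }
      next
    }
    b <- l1 %>% filter(.data$name == r$level1)
    if (nrow(b) == 0) bad(r$pmid, 1, paste0("unknown Level-1 category '", r$level1, "'"))
    if (b$max_level == 1L && !all(is.na(c(r$level2, r$level3)))) {
      bad(r$pmid, 2, paste0("branch '", r$level1, "' takes no assignments below Level 1"))
    }
    if (b$skip_level2) {
      if (!is.na(r$level2)) {
        bad(r$pmid, 2, paste0("branch '", r$level1, "' skips Level 2"))
      }
      if (!is.na(r$level3)) {
        kid <- nodes %>% filter(.data$level == 3L, .data$parent == r$level1,
                                .data$name == r$level3)
        if (nrow(kid) == 0) {
          bad(r$pmid, 3, paste0("'", r$level3, "' is not a Level-3 child of '",
                                r$level1, "'"))
        }
      }
      next
    }
    if (is.na(r$level2)) {
      if (!is.na(r$level3)) bad(r$pmid, 3, "Level-3 label without a Level-2 label")
      next
    }
    kid <- nodes %>% filter(.data$level == 2L, .data$parent == r$level1,
                            .data$name == r$level2)
    if (nrow(kid) == 0) {
      bad(r$pmid, 2, paste0("'", r$level2, "' is not a Level-2 child of '",
                            r$level1, "'"))
    }
    if (!is.na(r$level3)) {
      gkid <- nodes %>% filter(.data$level == 3L, .data$parent == r$level2,
                               .data$name == r$level3)
      if (nrow(gkid) == 0) {
        bad(r$pmid, 3, paste0("'", r$level3, "' is not a Level-3 child of '",
                              r$level2, "'"))
      }
    }
  }
  invisible(labels)
}

#' @export
print.taxonomy <- function(x, ...) {
  l1 <- x$nodes %>% filter(.data$level == 1L)
  cat("<taxonomy> ", nrow(l1), " Level-1 categories, ",
      nrow(x$nodes), " nodes total\n", sep = "")
  for (i in seq_len(nrow(l1))) {
    flags <- c(l1$priority[i],
               if (l1$skip_level2[i]) "skips L2",
               if (l1$max_level[i] == 1L) "terminal")
    n_desc <- sum(!is.na(x$nodes$parent) & x$nodes$parent == l1$name[i])
    cat("  ", l1$name[i], " [", paste(flags, collapse = ", "), "]",
        if (n_desc) paste0(" (", n_desc, " children)"), "\n", sep = "")
  }
  invisible(x)
}
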