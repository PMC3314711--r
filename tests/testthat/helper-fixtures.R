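# fixture builders shared across test files; everything is generated in code

# a tiny two-branch taxonomy for fast hierarchy tests
toy_taxonomy <- function() {
  taxonomy(dplyr::bind_rows(
    tibble::tibble(name = c("Alpha", "Beta"), level = 1L, parent = NA_character_,
                   priority = c("high", "low")),
    tibble::tibble(name = c("A1", "A2"), level = 2L, parent = "Alpha",
                   priority = NA_character_)
  ))
}

# deterministic toy corpus with obvious vocabulary signal per category
toy_corpus <- function(n_per = 15, seed = 42) {
  tax <- toy_taxonomy()
  vocab <- list(
    "Alpha/A1" = c("antigen", "epitope", "peptide"),
    "Alpha/A2" = c("receptor", "binding", "affinity"),
    "Beta" = c("tumor", "carcinoma", "oncogene"),
    "uncur" = c("survey", "questionnaire", "interview")
  )
  paths <- list(
    list(level0 = "curatable", level1 = "Alpha", level2 = "A1", key = "Alpha/A1"),
    list(level0 = "curatable", level1 = "Alpha", level2 = "A2", key = "Alpha/A2"),
    list(level0 = "curatable", level1 = "Beta", level2 = NA, key = "Beta"),
    list(level0 = "uncuratable", level1 = NA, level2 = NA, key = "uncur")
  )
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_along(paths), function(p) {
      info <- paths[[p]]
      purrr::map_dfr(seq_len(n_per), function(i) {
        words <- c(sample(vocab[[info$key]], 12, replace = TRUE),
                   sample(c("study", "results", "analysis", "patients",
                            "cells", "protein"), 8, replace = TRUE))
        words <- sample(words)
        tibble::tibble(pmid = sprintf("T%d%03d", p, i),
                       title = paste(words[1:4], collapse = " "),
                       abstract = paste(words[-(1:4)], collapse = " "),
                       level0 = info$level0,
                       level1 = as.character(info$level1),
                       level2 = as.character(info$level2),
                       level3 = NA_character_)
      })
    })
    rows
  })
}

# brute-force AUC by enumerating all positive/negative pairs
pair_count_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# binary entropy in bits, for hand IG arithmetic
h2 <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}
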