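test_that("tokenization lowercases, strips stopwords and digits, keeps order", {
  expect_equal(tokenize("The epitope binds HLA", stopwords = "the")[[1]],
               c("epitope", "binds", "hla"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("x 42 1988 T-cell")[[1]], "cell")
  # idempotence on its own joined output, over random strings
  withr::with_seed(1, {
    for (i in 1:20) {
      txt <- paste(sample(c("Epitope", "HLA-DR", "the", "12", "(x)", "cells",
                            "IgE", "mapping", "of"), 15, replace = TRUE),
                   collapse = " ")
      once <- tokenize(txt)[[1]]
      twice <- tokenize(paste(once, collapse = " "))[[1]]
      expect_identical(twice, once)
    }
  })
})

test_that("document frequencies honour the rare-word floor", {
  tokens <- c(rep(list(c("common", "rare2")), 2),
              rep(list(c("common", "rare3")), 1),
              rep(list("common"), 3))
  # rare2 is in exactly 2 documents, below the default floor of 3
  vocab <- build_vocabulary(tokens, min_df = 3)
  expect_false("rare2" %in% vocab$term)
  expect_true("common" %in% vocab$term)
  # boundary: a term in exactly 3 documents is retained
  tokens3 <- c(tokens, list(c("rare3", "common")), list(c("rare3")))
  vocab3 <- build_vocabulary(tokens3, min_df = 3)
  expect_true("rare3" %in% vocab3$term)
  expect_error(build_vocabulary(tokens, min_df = 0), "min_df")
  # df against brute-force set-membership counting on a 6-doc toy corpus
  toy <- list(c("a", "b", "a"), c("b", "c"), c("a"), c("c", "c"), c("a", "c"),
              c("b"))
  v <- build_vocabulary(toy, min_df = 1)
  for (t in c("a", "b", "c")) {
    brute <- sum(vapply(toy, function(d) t %in% d, logical(1)))
    expect_equal(v$df[v$term == t], brute)
  }
})

test_that("idf is ln(N/df) and monotone in df", {
  tokens <- purrr::map(1:100, ~ if (.x <= 10) c("ten", "all") else "all")
  v <- build_vocabulary(tokens, min_df = 1)
  expect_equal(idf("all", v), 0)
  expect_equal(idf("ten", v), log(10), tolerance = 1e-12)
  expect_error(idf("absent", v), "not in vocabulary")
  dfs <- sort(unique(v$df))
  expect_true(all(diff(log(attr(v, "N") / dfs)) < 0))
})

test_that("information gain matches direct entropy arithmetic", {
  # no split information: a term in every document
  tokens <- rep(list("ubiq"), 6)
  labels <- rep(c("p", "n"), 3)
  ig <- information_gain(tokens, labels,
                         vocabulary = build_vocabulary(tokens, min_df = 1))
  expect_equal(ig$ig[ig$term == "ubiq"], 0)
  # perfect indicator on a balanced corpus: 1 bit
  tokens <- c(rep(list(c("marker", "bg")), 5), rep(list("bg"), 5))
  labels <- rep(c("p", "n"), each = 5)
  ig <- information_gain(tokens, labels,
                         vocabulary = build_vocabulary(tokens, min_df = 1))
  expect_equal(ig$ig[ig$term == "marker"], 1)
  # N = 10 (5 pos / 5 neg), term in 4 pos + 1 neg: hand entropy oracle
  tokens <- c(rep(list(c("tt", "bg")), 4), list("bg"),
              list(c("tt", "bg")), rep(list("bg"), 4))
  labels <- c(rep("p", 5), rep("n", 5))
  hand <- h2(0.5) - (0.5 * h2(4 / 5) + 0.5 * h2(1 / 5))
  ig <- information_gain(tokens, labels,
                         vocabulary = build_vocabulary(tokens, min_df = 1))
  expect_equal(ig$ig[ig$term == "tt"], hand, tolerance = 1e-12)
  expect_equal(hand, 0.2780719, tolerance = 1e-6)
  # label-name invariance
  ig_swapped <- information_gain(tokens, ifelse(labels == "p", "n", "p"),
                                 vocabulary = build_vocabulary(tokens, min_df = 1))
  expect_equal(ig$ig, ig_swapped$ig)
  expect_error(information_gain(tokens, rep("p", 10)), "two classes")
})

test_that("top-k selection truncates, floors, and breaks ties lexicographically", {
  withr::with_seed(7, {
    n <- 40
    labels <- rep(c("p", "n"), each = n / 2)
    tokens <- purrr::map(seq_len(n), function(i) {
      c(sample(paste0("w", 1:300), 30, replace = TRUE),
        if (labels[i] == "p") "signal")
    })
  })
  vocab <- build_vocabulary(tokens, min_df = 1)
  ig <- information_gain(tokens, labels, vocab)
  expect_gte(nrow(ig), 250)
  fs <- select_top_k(ig, vocab, k = 100)
  expect_equal(nrow(fs), 100)
  expect_equal(fs$term[1], "signal")
  expect_true(all(diff(fs$ig) <= 1e-12))
  small <- select_top_k(ig[1:40, ], vocab, k = 100)
  expect_equal(nrow(small), 40)
  # constructed tie set: equal-IG terms ordered by name, stable across runs
  tie_tokens <- c(rep(list(c("zeta", "echo", "mike", "bg")), 3),
                  rep(list("bg"), 3))
  tie_labels <- rep(c("p", "n"), each = 3)
  tie_v <- build_vocabulary(tie_tokens, min_df = 1)
  tie_ig <- information_gain(tie_tokens, tie_labels, tie_v)
  sel1 <- select_top_k(tie_ig, tie_v, k = 2)
  sel2 <- select_top_k(information_gain(tie_tokens, tie_labels, tie_v), tie_v, 2)
  expect_equal(sel1$term, c("echo", "mike"))
  expect_identical(sel1$term, sel2$term)
})

test_that("vectorization is TF x IDF with optional unit-length scaling", {
  toy <- list(c("aa", "bb", "aa"), c("bb", "cc"), c("aa"), c("dd", "dd"))
  v <- build_vocabulary(toy, min_df = 1)
  ig <- tibble::tibble(term = v$term, ig = 0)
  fs <- select_top_k(ig, v, k = 4)
  x <- vectorize(toy, fs, normalize = FALSE)
  # hand arithmetic: weight = count * ln(N/df)
  expect_equal(unname(x[1, "aa"]), 2 * log(4 / 2), tolerance = 1e-12)
  expect_equal(unname(x[1, "bb"]), 1 * log(4 / 2), tolerance = 1e-12)
  expect_equal(unname(x[4, "dd"]), 2 * log(4 / 1), tolerance = 1e-12)
  expect_equal(unname(x[3, "bb"]), 0)
  xn <- vectorize(toy, fs, normalize = TRUE)
  expect_equal(unname(sqrt(rowSums(xn^2))), rep(1, 4), tolerance = 1e-12)
  # a document sharing no terms with the feature set stays all-zero
  z <- vectorize(list(c("zz", "qq")), fs)
  expect_equal(sum(abs(z)), 0)
  # single shared feature, normalized: weight 1
  one <- vectorize(list(c("aa", "unknown")), fs, normalize = TRUE)
  expect_equal(unname(one[1, "aa"]), 1)
  # feature sets serialize to TSV and back
  f <- withr::local_tempfile(fileext = ".tsv")
  fs_ig <- build_feature_set(toy, c(TRUE, TRUE, FALSE, FALSE), k = 3, min_df = 1)
  write_feature_set(fs_ig, f)
  back <- read_feature_set(f)
  expect_equal(back$term, fs_ig$term)
  expect_equal(back$idf, fs_ig$idf)
  expect_equal(attr(back, "N"), attr(fs_ig, "N"))
})

test_that("feature selection is a pure function of its inputs", {
  corpus <- toy_corpus(n_per = 10)
  tokens <- tokenize(paste(corpus$title, corpus$abstract))
  lab <- corpus$level0 == "curatable"
  a <- build_feature_set(tokens, lab, k = 20, min_df = 2)
  b <- build_feature_set(tokens, lab, k = 20, min_df = 2)
  expect_identical(a$term, b$term)
  expect_identical(a$ig, b$ig)
})
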