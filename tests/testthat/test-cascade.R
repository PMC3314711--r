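test_that("threshold calibration maximizes specificity under the sensitivity floor", {
  # perfectly separated scores: threshold lands between the classes
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c("uncuratable", "curatable"), each = 3)
  th <- calibrate_level0_threshold(scores, labels, positive = "curatable")
  expect_gt(as.numeric(th), 3)
  expect_lte(as.numeric(th), 10)
  expect_equal(attr(th, "sensitivity"), 1)
  expect_equal(attr(th, "specificity"), 1)
  # vacuous target: pure specificity maximization
  th0 <- calibrate_level0_threshold(scores, labels, target_sensitivity = 0,
                                    positive = "curatable")
  expect_equal(attr(th0, "specificity"), 1)
  # 8-point toy list vs exhaustive evaluation of every cutoff
  s8 <- c(0.1, 0.3, 0.35, 0.5, 0.55, 0.7, 0.9, 0.95)
  l8 <- c("u", "u", "c", "u", "c", "c", "u", "c")
  th8 <- calibrate_level0_threshold(s8, l8, target_sensitivity = 0.75,
                                    positive = "c")
  u <- sort(unique(s8))
  cand <- c(-Inf, u[-length(u)] + diff(u) / 2, Inf)
  stats <- vapply(cand, function(t) {
    cp <- s8 >= t
    c(sens = sum(cp & l8 == "c") / sum(l8 == "c"),
      spec = sum(!cp & l8 == "u") / sum(l8 == "u"))
  }, numeric(2))
  feas <- which(stats["sens", ] >= 0.75)
  best <- feas[which.max(stats["spec", feas])]
  expect_equal(as.numeric(th8), cand[best])
  expect_equal(attr(th8, "specificity"), max(stats["spec", feas]))
})

test_that("an unreachable-except-by-accepting-all target warns and returns -Inf", {
  # only the accept-everything cutoff attains sensitivity 1 here
  scores <- c(5, 1, 2, 3, 4) # lowest score is a positive
  labels <- c("u", "c", "u", "u", "u")
  expect_warning(
    th <- calibrate_level0_threshold(scores, labels, target_sensitivity = 1,
                                     positive = "c"),
    "accepting everything")
  expect_identical(as.numeric(th), -Inf)
})

test_that("the trained hierarchy routes documents along valid taxonomy paths", {
  corpus <- toy_corpus(n_per = 15)
  tax <- toy_taxonomy()
  ctl <- triage_control(m = 5, folds_level0 = 3, folds_level1 = 3,
                        folds_deeper = 3, k_features = 40, epochs = 100)
  bundle <- train_triage(corpus, tax, control = ctl, seed = 2)
  expect_s3_class(bundle, "triage_bundle")
  expect_setequal(names(bundle$nodes), c("ROOT", "Alpha"))
  res <- classify_corpus(bundle, toy_corpus(n_per = 8, seed = 77))
  # every emitted path is a valid root-to-node path (checked exhaustively)
  expect_silent(validate_labels(
    dplyr::transmute(res, pmid, level0 = level0_call, level1, level2, level3),
    tax))
  # uncuratable calls carry NA categories
  unc <- res[res$level0_call == "uncuratable", ]
  expect_true(all(is.na(unc$level1)) && all(is.na(unc$level2)))
  # branch without children (Beta) stops at Level 1
  beta <- res[!is.na(res$level1) & res$level1 == "Beta", ]
  expect_true(all(is.na(beta$level2)))
  # determinism: identical rerun
  res2 <- classify_corpus(bundle, toy_corpus(n_per = 8, seed = 77))
  expect_identical(res, res2)
  # summary counts conserve corpus size at every level
  smry <- attr(res, "summary")
  totals <- dplyr::summarise(dplyr::group_by(smry, level), n = sum(n))
  expect_true(all(totals$n == nrow(res)))
  # empty corpus: empty results, no error
  empty <- classify_corpus(bundle, toy_corpus(n_per = 8)[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("raising the Level-0 threshold only shrinks the curatable set", {
  corpus <- toy_corpus(n_per = 15)
  ctl <- triage_control(m = 5, folds_level0 = 3, folds_level1 = 3,
                        k_features = 40, epochs = 50)
  bundle <- train_triage(corpus, toy_taxonomy(), control = ctl, seed = 2)
  hold <- toy_corpus(n_per = 10, seed = 55)
  base <- classify_corpus(bundle, hold)
  cur0 <- base$pmid[base$level0_call == "curatable"]
  for (bump in c(0.05, 0.2, 0.8)) {
    b2 <- bundle
    b2$level0$threshold <- as.numeric(bundle$level0$threshold) + bump
    cur1 <- with(classify_corpus(b2, hold), pmid[level0_call == "curatable"])
    expect_true(all(cur1 %in% cur0))
    cur0 <- cur1
  }
})

test_that("single-child sets pass through and starved sets fall back to majority", {
  tax <- taxonomy(dplyr::bind_rows(
    tibble::tibble(name = c("Solo", "Busy"), level = 1L, parent = NA_character_,
                   priority = c("high", "low")),
    tibble::tibble(name = "OnlyChild", level = 2L, parent = "Solo",
                   priority = NA_character_),
    tibble::tibble(name = c("B1", "B2"), level = 2L, parent = "Busy",
                   priority = NA_character_)
  ))
  cfg <- generator_config(taxonomy = tax, docs_per_leaf = 20, leaf_weights = c(),
                          uncuratable_fraction = 0.3, doc_length = 60,
                          seed = 31)
  corpus <- generate_corpus(cfg)
  # starve B2 down to 3 documents
  b2 <- which(!is.na(corpus$level2) & corpus$level2 == "B2")
  corpus <- corpus[-b2[-(1:3)], ]
  ctl <- triage_control(m = 5, folds_level0 = 3, folds_level1 = 3,
                        folds_deeper = 3, k_features = 40, epochs = 50)
  bundle <- train_triage(corpus, tax, control = ctl, seed = 4)
  expect_equal(bundle$nodes[["Solo"]]$fallback, "OnlyChild")
  expect_equal(bundle$nodes[["Solo"]]$basis, "single")
  expect_equal(bundle$nodes[["Busy"]]$fallback, "B1")
  expect_equal(bundle$nodes[["Busy"]]$basis, "majority")
  expect_true(any(grepl("fallback", bundle$log)))
  res <- classify_corpus(bundle, corpus)
  solo <- res[!is.na(res$level1) & res$level1 == "Solo", ]
  expect_true(all(solo$level2 == "OnlyChild"))
})

test_that("trained sibling-set count matches direct tree traversal", {
  tax <- default_taxonomy()
  keys <- epitriage:::sibling_set_keys(tax)
  # tree walk: root set + every node with children
  n_expected <- 1 +
    sum(vapply(tax$nodes$name,
               function(nm) nrow(taxonomy_children(tax, nm)) > 0, logical(1)))
  expect_length(keys, n_expected)
  expect_setequal(keys, c("ROOT", "Autoimmunity", "Autoimmunity/Diabetes"))
})

test_that("bundles serialize to JSON and reload to identical predictions", {
  corpus <- toy_corpus(n_per = 15)
  ctl <- triage_control(m = 5, folds_level0 = 3, folds_level1 = 3,
                        k_features = 30, epochs = 50)
  bundle <- train_triage(corpus, toy_taxonomy(), control = ctl, seed = 6)
  dir <- withr::local_tempdir()
  save_triage_bundle(bundle, dir)
  expect_error(save_triage_bundle(bundle, dir), "force")
  back <- load_triage_bundle(dir)
  hold <- toy_corpus(n_per = 6, seed = 88)
  r1 <- classify_corpus(bundle, hold)
  r2 <- classify_corpus(back, hold)
  expect_equal(r1$level0_score, r2$level0_score, tolerance = 1e-12)
  expect_identical(r1$level1, r2$level1)
  expect_identical(r1$level2, r2$level2)
  # results table writes cleanly
  f <- withr::local_tempfile(fileext = ".tsv")
  write_triage_results(r1, f)
  expect_equal(nrow(readr::read_tsv(f, show_col_types = FALSE)), nrow(hold))
})
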