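test_that("linear SVM separates, is symmetric under label flip, and rejects one class", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c("neg", "neg", "neg", "pos", "pos", "pos")
  m <- train_linear_svm(x, y, positive = "pos", C = 100)
  expect_equal(roc_auc(decision_score(m, x), y, positive = "pos")$auc, 1)
  m_flip <- train_linear_svm(x, ifelse(y == "pos", "neg", "pos"),
                             positive = "pos", C = 100)
  expect_equal(decision_score(m_flip, x), -decision_score(m, x),
               tolerance = 1e-6)
  expect_error(train_linear_svm(x, rep("pos", 6)), "both classes")
})

test_that("SVM decision scores match a quadratic-programming oracle", {
  skip_if_not_installed("quadprog")
  X <- rbind(c(1, 1), c(2, 2), c(-1, -1), c(-2, -1))
  y <- c(1, 1, -1, -1)
  C <- 1
  # primal soft-margin QP over z = (w1, w2, b, xi_1..4), tiny ridge on b, xi
  eps <- 1e-6
  D <- diag(c(1, 1, eps, rep(eps, 4)))
  dvec <- -c(0, 0, 0, rep(C, 4))
  Amat <- t(rbind(cbind(y * X, y, diag(4)), cbind(matrix(0, 4, 3), diag(4))))
  bvec <- c(rep(1, 4), rep(0, 4))
  z <- quadprog::solve.QP(D, dvec, Amat, bvec)$solution
  oracle <- as.vector(X %*% z[1:2] + z[3])
  m <- train_linear_svm(X, ifelse(y > 0, "pos", "neg"), positive = "pos", C = C)
  expect_equal(decision_score(m, X), oracle, tolerance = 1e-4)
})

test_that("decision scores are linear and match dot-product arithmetic", {
  m <- structure(list(w = c(a = 0.5, b = -1, c = 2), b = 0.25, C = 1,
                      positive = "pos", negative = "neg"),
                 class = "linear_model")
  expect_equal(decision_score(m, c(0, 0, 0)), 0.25)
  x <- c(1, 2, 3); y <- c(-1, 0.5, 2)
  expect_equal(decision_score(m, x), 0.5 * 1 - 1 * 2 + 2 * 3 + 0.25)
  expect_equal(decision_score(m, x + y),
               decision_score(m, x) + decision_score(m, y) - m$b)
  expect_error(decision_score(m, c(1, 2)), "dimension mismatch")
})

test_that("duplicating every document leaves the normalized-objective fit unchanged", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(40, 1), 20), matrix(rnorm(40, -1), 20))
    y <- rep(c("pos", "neg"), each = 20)
  })
  m1 <- train_linear_svm(x, y, positive = "pos", C = 1)
  m2 <- train_linear_svm(rbind(x, x), c(y, y), positive = "pos", C = 0.5)
  # tolerance reflects the solver's own convergence epsilon
  expect_equal(m2$w, m1$w, tolerance = 5e-3)
  expect_equal(m2$b, m1$b, tolerance = 5e-3)
})

test_that("the ensemble partitions data and averages member scores", {
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(60, 1.5), 30), matrix(rnorm(60, -1.5), 30))
    y <- rep(c("pos", "neg"), each = 30)
  })
  ens <- train_ensemble(x, y, positive = "pos", m = 10, seed = 9)
  expect_length(ens$members, 10)
  # subsets disjoint, covering, label-stratified within one document
  expect_setequal(unique(ens$subset_of), 1:10)
  expect_equal(length(ens$subset_of), nrow(x))
  per_fold_pos <- table(ens$subset_of[y == "pos"])
  expect_lte(diff(range(per_fold_pos)), 1)
  # ensemble score equals brute-force mean of member scores
  xs <- x[c(1, 31), ]
  brute <- rowMeans(vapply(ens$members, decision_score, numeric(2), x = xs))
  expect_equal(ensemble_score(ens, xs), brute, tolerance = 1e-12)
  # member-order invariance
  shuffled <- ens
  shuffled$members <- rev(ens$members)
  expect_equal(ensemble_score(shuffled, xs), ensemble_score(ens, xs))
  expect_error(train_ensemble(x[c(1:12, 31:35), ], y[c(1:12, 31:35)],
                              positive = "pos", m = 10, seed = 1),
               "at least m")
  # duplicated data forces near-identical members: ensemble = member score
  xd <- rbind(x, x, x); yd <- rep(y, 3)
  ens_d <- train_ensemble(xd, yd, positive = "pos", m = 3, seed = 2)
  s_members <- vapply(ens_d$members, decision_score, numeric(1), x = x[1, ])
  expect_equal(ensemble_score(ens_d, x[1, ]), mean(s_members), tolerance = 1e-12)
})

test_that("multinomial naive Bayes matches hand-computed posteriors", {
  # 4-document toy corpus, alpha = 1, vocabulary {aa, bb}
  tokens <- list(c("aa", "aa"), c("aa", "bb"), c("bb", "bb"), c("bb"))
  y <- c("pos", "pos", "neg", "neg")
  m <- train_naive_bayes(tokens, y, positive = "pos", alpha = 1)
  # hand arithmetic: pos counts aa=3 bb=1 (total 4), neg aa=0 bb=3 (total 3)
  p_aa_pos <- (3 + 1) / (4 + 2); p_bb_pos <- (1 + 1) / (4 + 2)
  p_aa_neg <- (0 + 1) / (3 + 2); p_bb_neg <- (3 + 1) / (3 + 2)
  hand <- log(0.5 / 0.5) + 2 * log(p_aa_pos / p_aa_neg) + log(p_bb_pos / p_bb_neg)
  expect_equal(nb_score(m, c("aa", "aa", "bb")), hand, tolerance = 1e-9)
  # empty document scores the log prior odds
  m2 <- train_naive_bayes(tokens[c(1, 1, 2, 3)], c("pos", "pos", "pos", "neg"),
                          positive = "pos")
  expect_equal(nb_score(m2, character(0)), log(3) - log(1), tolerance = 1e-12)
  # perfectly symmetric corpus: balanced query scores zero
  sym <- train_naive_bayes(list(c("aa"), c("bb")), c("pos", "neg"),
                           positive = "pos")
  expect_equal(nb_score(sym, c("aa", "bb")), 0, tolerance = 1e-12)
  expect_error(train_naive_bayes(tokens, y, alpha = 0), "alpha")
})

test_that("SVM ensembles outrank naive Bayes on separable synthetic corpora", {
  # directional comparison at the curatability gate, over seeded replicates
  wins <- 0
  n_rep <- 5
  for (s in seq_len(n_rep)) {
    cfg <- generator_config(taxonomy = toy_taxonomy(), docs_per_leaf = 30,
                            leaf_weights = c(), uncuratable_fraction = 0.5,
                            alpha = 0.85, doc_length = 60, seed = 100 + s)
    corpus <- generate_corpus(cfg)
    tokens <- tokenize(paste(corpus$title, corpus$abstract))
    y <- corpus$level0
    plan <- kfold_plan(nrow(corpus), 3, y, seed = s)
    svm_auc <- roc_auc(
      epitriage:::cv_binary_scores(tokens, y, "curatable", plan,
                                   triage_control(m = 5)),
      y, positive = "curatable")$auc
    nb_oof <- rep(NA_real_, nrow(corpus))
    for (f in 1:3) {
      tr <- plan$index[plan$fold != f]; te <- plan$index[plan$fold == f]
      nb <- train_naive_bayes(tokens[tr], y[tr], positive = "curatable")
      nb_oof[te] <- nb_score(nb, tokens[te])
    }
    nb_auc <- roc_auc(nb_oof, y, positive = "curatable")$auc
    wins <- wins + (svm_auc >= nb_auc)
  }
  expect_gte(wins / n_rep, 0.8)
})
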