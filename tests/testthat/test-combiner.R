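test_that("the priority cost matrix encodes the published cost structure", {
  part <- priority_partition(default_taxonomy())
  cm <- build_priority_cost_matrix(part)
  expect_setequal(unique(as.vector(cm)), c(0, 0.2, 1, 5))
  expect_equal(sum(cm == 5), 4 * 3) # every high-to-low cell
  expect_equal(unname(diag(cm)), rep(0, 7))
  # exhaustive case enumeration for 4 high + 3 low
  for (i in rownames(cm)) for (j in colnames(cm)) {
    expected <- if (i == j) 0
      else if (i %in% part$high && j %in% part$high) 1
      else if (!i %in% part$high && !j %in% part$high) 0.2
      else if (i %in% part$high) 5 else 1
    expect_equal(cm[i, j], expected, info = paste(i, "->", j))
  }
  # all-high partition collapses to uniform misclassification
  allhigh <- build_priority_cost_matrix(list(high = c("A", "B"), low = character(0)))
  expect_equal(unclass(allhigh), unclass(uniform_cost_matrix(c("A", "B"))),
               ignore_attr = TRUE)
  expect_error(build_priority_cost_matrix(part, c_hl = -1), "non-negative")
})

test_that("the catch-all cost matrix penalizes dumping into Other/Various", {
  diab <- taxonomy_children(default_taxonomy(), "Diabetes")
  cm <- build_catchall_cost_matrix(diab$name, diab$catch_all)
  expect_equal(cm["GAD", "OTH"], 5)
  expect_equal(cm["OTH", "GAD"], 0.2)
  expect_equal(cm["GAD", "INSULIN"], 1)
  # full 7x7 enumeration
  for (i in diab$name) for (j in diab$name) {
    ca_i <- diab$catch_all[diab$name == i]; ca_j <- diab$catch_all[diab$name == j]
    expected <- if (i == j) 0 else if (ca_i) 0.2 else if (ca_j) 5 else 1
    expect_equal(cm[i, j], expected, info = paste(i, "->", j))
  }
  minimal <- build_catchall_cost_matrix(c("S", "OTH"), c(FALSE, TRUE))
  expect_equal(unclass(minimal), matrix(c(0, 0.2, 5, 0), 2, 2,
               dimnames = list(true = c("S", "OTH"),
                               predicted = c("S", "OTH"))),
               ignore_attr = TRUE)
  expect_error(build_catchall_cost_matrix(c("A", "B"), c(FALSE, FALSE)),
               "uniform_cost_matrix")
})

test_that("cost matrices load from explicit YAML/JSON tables", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("categories: [A, B]", "costs:", "  - [0, 2]", "  - [1, 0]"), f)
  cm <- load_cost_matrix(f)
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["B", "A"], 1)
})

test_that("instance weights follow cost row-sums and scale invariance", {
  part <- priority_partition(default_taxonomy())
  cm <- build_priority_cost_matrix(part)
  labels <- c("Allergy", "Cancer", "HIV", "Autoimmunity")
  w <- instance_weights(labels, cm)
  # row-sum arithmetic oracle: high rows 3*1 + 3*5 = 18; low 2*0.2 + 4*1 = 4.4
  mean_rs <- (4 * 18 + 3 * 4.4) / 7
  expect_equal(w, c(18, 4.4, 4.4, 18) / mean_rs, tolerance = 1e-12)
  expect_true(all(w[c(1, 4)] > w[c(2, 3)]))
  expect_equal(instance_weights(labels, new_cm <- cm * 7), w, tolerance = 1e-12)
  u <- uniform_cost_matrix(rownames(cm))
  expect_equal(instance_weights(labels, u), rep(1, 4))
  zero <- uniform_cost_matrix(c("A", "B")) * 0
  expect_error(instance_weights(c("A"), zero), "all-zero")
})

test_that("the combiner's analytic gradient matches finite differences", {
  withr::with_seed(11, {
    X <- matrix(rnorm(12), 4, 3)
    Y <- diag(3)[c(1, 2, 3, 1), ]
    w <- c(1, 2, 0.5, 1)
    W1 <- matrix(rnorm(8, sd = 0.3), 4, 2) # 3 inputs + bias, h = 2
    W2 <- matrix(rnorm(9, sd = 0.3), 3, 3) # 2 hidden + bias, K = 3
  })
  g <- epitriage:::mlp_gradients(W1, W2, X, Y, w)
  eps <- 1e-6
  num_grad <- function(M, name) {
    out <- M * 0
    for (i in seq_along(M)) {
      up <- M; up[i] <- up[i] + eps
      dn <- M; dn[i] <- dn[i] - eps
      fu <- if (name == "W1") epitriage:::mlp_gradients(up, W2, X, Y, w)$loss
            else epitriage:::mlp_gradients(W1, up, X, Y, w)$loss
      fd <- if (name == "W1") epitriage:::mlp_gradients(dn, W2, X, Y, w)$loss
            else epitriage:::mlp_gradients(W1, dn, X, Y, w)$loss
      out[i] <- (fu - fd) / (2 * eps)
    }
    out
  }
  expect_equal(g$gW1, num_grad(W1, "W1"), tolerance = 1e-5)
  expect_equal(g$gW2, num_grad(W2, "W2"), tolerance = 1e-5)
})

test_that("the combiner defaults, converges on separable profiles, and is deterministic", {
  withr::with_seed(12, {
    classes <- paste0("C", 1:7)
    lab <- rep(classes, each = 30)
    X <- matrix(rnorm(210 * 7, -1, 0.2), 210, 7, dimnames = list(NULL, classes))
    X[cbind(seq_len(210), match(lab, classes))] <- rnorm(210, 1, 0.2)
  })
  m <- train_mlp(X, lab, seed = 3, epochs = 150)
  expect_equal(m$h, 3) # 7 categories -> floor(7/2)
  pred <- colnames(X)[max.col(predict_probs(m, X))]
  expect_gte(mean(pred == lab), 0.99)
  m2 <- train_mlp(X, lab, seed = 3, epochs = 150)
  expect_identical(m$W1, m2$W1)
  expect_identical(predict_probs(m, X[1, ]), predict_probs(m2, X[1, ]))
  expect_error(train_mlp(X, lab, seed = 1, epochs = 0), "epochs")
  expect_error(train_mlp(X, lab, seed = 1, h = 0), "h must be")
})

test_that("combiner probabilities normalize; symmetric zero network is uniform", {
  withr::with_seed(13, {
    X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("C", 1:4)))
    lab <- sample(paste0("C", 1:4), 10, replace = TRUE)
  })
  m <- train_mlp(X, lab, seed = 5, epochs = 20)
  P <- predict_probs(m, X)
  expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(P >= 0))
  expect_error(predict_probs(m, c(1, 2)), "input width")
  zero <- structure(list(W1 = matrix(0, 5, 2), W2 = matrix(0, 3, 4),
                         classes = paste0("C", 1:4), center = rep(0, 4),
                         scale = rep(1, 4)), class = "mlp_model")
  expect_equal(unname(predict_probs(zero, rep(0, 4))), rep(0.25, 4))
})

test_that("minimum-expected-cost decisions reduce to argmax under uniform costs", {
  part <- priority_partition(default_taxonomy())
  cm <- build_priority_cost_matrix(part)
  u <- uniform_cost_matrix(rownames(cm))
  withr::with_seed(14, {
    for (i in 1:25) {
      p <- runif(7); p <- p / sum(p)
      expect_equal(min_expected_cost_decision(p, u), which.max(p))
      # brute-force column-sum enumeration oracle
      expected_cost <- as.vector(p %*% unclass(cm))
      expect_equal(min_expected_cost_decision(p, cm), which.min(expected_cost))
      # positive-scaling invariance
      expect_equal(min_expected_cost_decision(p, cm * 3.7),
                   min_expected_cost_decision(p, cm))
    }
  })
  # certainty on class i returns i (zero diagonal)
  for (i in 1:7) {
    p <- rep(0, 7); p[i] <- 1
    expect_equal(min_expected_cost_decision(p, cm), i)
  }
  # uniform probabilities with the default Level-1 matrix: a high-priority
  # category wins (columns ordered high first)
  p <- rep(1 / 7, 7)
  win <- rownames(cm)[min_expected_cost_decision(p, cm)]
  expect_true(win %in% part$high)
  # ties break to the smallest canonical index
  expect_equal(min_expected_cost_decision(rep(1 / 7, 7), u), 1)
})
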