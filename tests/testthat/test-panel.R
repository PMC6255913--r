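test_that("AUC rank statistic equals exhaustive pair counting", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  set.seed(20)
  for (i in 1:500) {
    n <- sample(4:10, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, TRUE)  # forces ties
    expect_identical(auc_rank(scores, labels),
                     auc_pair_oracle(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  scores <- rnorm(200); labels <- rbinom(200, 1, 0.4)
  a <- auc_rank(scores, labels)
  expect_equal(auc_rank(exp(scores), labels), a)
  expect_equal(auc_rank(5 * scores - 3, labels), a)
  expect_equal(auc_rank(atan(scores), labels), a)
})

test_that("AUPR of random scores approaches class prevalence", {
  set.seed(22)
  n <- 2000
  labels <- rbinom(n, 1, 0.3)
  scores <- runif(n)
  expect_equal(aupr_step(scores, labels), mean(labels), tolerance = 0.17)
  expect_lt(abs(aupr_step(scores, labels) - mean(labels)), 0.05)
  # perfect ranking gives AUPR 1
  expect_equal(aupr_step(labels + runif(n, 0, 0.5), labels), 1)
})

test_that("optimal cutoff separates and matches the exhaustive scan", {
  cut <- optimal_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(cut), 0.5)
  expect_equal(attr(cut, "accuracy"), 1.0)

  # anti-ordered pair: best achievable accuracy is 0.5 (all-one-class
  # rules); the accuracy -> Youden -> smaller-cutoff tie-break applies
  cut2 <- optimal_cutoff(c(0.4, 0.6), c(1, 0))
  expect_equal(attr(cut2, "accuracy"), 0.5)
  expect_lt(as.numeric(cut2), 0.5)

  set.seed(23)
  for (i in 1:100) {
    scores <- round(runif(20), 2)
    labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2) next
    cut <- optimal_cutoff(scores, labels)
    expect_equal(attr(cut, "accuracy"),
                 cutoff_accuracy_oracle(scores, labels))
  }

  const <- optimal_cutoff(rep(0.5, 4), c(0, 1, 0, 1))
  expect_true(attr(const, "degenerate"))
  expect_equal(as.numeric(const), 0.5)
})

test_that("repeated LASSO recovers planted features and is deterministic", {
  set.seed(24)
  n <- 150; p <- 200
  recovered <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%03d", 1:p)))
    y <- rep(0:1, length.out = n)
    X[, 1:3] <- X[, 1:3] + 1.5 * y
    cand <- cv_lasso_select(X, y, folds = 5, repeats = 8, seed = s)
    top <- cand[order(-cand$frequency), ]
    sum(sprintf("f%03d", 1:3) %in% top$features[[1]])
  }, numeric(1))
  expect_gte(mean(recovered >= 2), 0.9)

  # determinism: same seed, same candidate list
  X <- matrix(rnorm(100 * 50), 100, 50,
              dimnames = list(NULL, sprintf("f%02d", 1:50)))
  y <- rep(0:1, each = 50)
  X[, 1] <- X[, 1] + 2 * y
  c1 <- cv_lasso_select(X, y, repeats = 5, seed = 99)
  c2 <- cv_lasso_select(X, y, repeats = 5, seed = 99)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$cv_auc, c2$cv_auc)

  expect_error(cv_lasso_select(X, rep(1, 100), seed = 1), "both classes")
})

test_that("pure-noise selection yields chance-level CV AUC", {
  meds <- vapply(1:8, function(s) {
    set.seed(s)
    X <- matrix(rnorm(80 * 60), 80, 60,
                dimnames = list(NULL, sprintf("f%02d", 1:60)))
    y <- rep(0:1, each = 40)
    cand <- cv_lasso_select(X, y, repeats = 5, seed = s)
    stats::median(cand$cv_auc)
  }, numeric(1))
  expect_true(all(meds > 0.3 & meds < 0.7))
})

test_that("panel selection rules and the size-two fallback work", {
  cand <- data.frame(size = c(1L, 4L, 3L),
                     cv_auc = c(0.88, 0.86, 0.86),
                     frequency = c(50L, 10L, 40L),
                     lambda = c(0.1, 0.05, 0.07))
  cand$features <- list("a", c("b", "c", "d", "e"), c("f", "g", "h"))
  class(cand) <- c("candidate_panels", "data.frame")

  # best single-feature candidate is skipped for the sub-optimal set
  best <- select_panel(cand, "best_auc")
  expect_equal(best$size, 3L)          # AUC tie at 0.86 -> higher freq
  expect_equal(best$features, c("f", "g", "h"))

  freq <- select_panel(cand, "most_frequent")
  expect_equal(freq$features, c("f", "g", "h"))

  single <- cand[1, , drop = FALSE]
  expect_error(select_panel(single, "best_auc"), "at least two")

  only <- cand[2, , drop = FALSE]
  expect_equal(select_panel(only, "best_auc")$features,
               c("b", "c", "d", "e"))
  expect_equal(select_panel(only, "most_frequent")$features,
               c("b", "c", "d", "e"))
})

test_that("ensemble fits a separable toy exactly and is seed-stable", {
  X <- matrix(c(-2, -1, 1, 2), 4, 1, dimnames = list(NULL, "f1"))
  y <- c(0, 0, 1, 1)
  m <- suppressWarnings(train_ensemble(X, y, seed = 1))
  pv <- predict_vote(m, X)
  expect_equal(pv$vote, y)
  expect_true(all(pv$labels == y))     # every model separates the toy

  set.seed(30)
  X2 <- matrix(rnorm(60 * 3), 60, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  y2 <- rep(0:1, each = 30)
  X2[, 1] <- X2[, 1] + 1.5 * y2
  m1 <- train_ensemble(X2, y2, seed = 5)
  m2 <- train_ensemble(X2, y2, seed = 5)
  Xt <- matrix(rnorm(30 * 3), 30, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  expect_identical(predict_vote(m1, Xt)$labels,
                   predict_vote(m2, Xt)$labels)
  expect_identical(predict_vote(m1, Xt)$scores,
                   predict_vote(m2, Xt)$scores)

  expect_error(train_ensemble(X2, rep(0, 60), seed = 1), "both classes")
  expect_error(predict_vote(m1, Xt[, 1:2]), "missing panel column")
})

test_that("single planted feature attains near-optimal ranked scores", {
  set.seed(31)
  ytr <- rep(0:1, each = 150); yte <- rep(0:1, each = 250)
  Xtr <- matrix(rnorm(300) + 2 * ytr, ncol = 1,
                dimnames = list(NULL, "f1"))
  Xte <- matrix(rnorm(500) + 2 * yte, ncol = 1,
                dimnames = list(NULL, "f1"))
  m <- train_ensemble(Xtr, ytr, seed = 31)
  pv <- predict_vote(m, Xte)
  target <- planted_bayes_auc(2)
  # ridge scores are monotone in the feature, so they track the Bayes AUC
  expect_lt(abs(auc_rank(pv$scores[, "ridge"], yte) - target), 0.03)
  # RBF-SVM decision values and forest vote fractions lose a little
  # ranking sharpness on a single feature but stay close
  expect_lt(abs(auc_rank(pv$scores[, "svm"], yte) - target), 0.07)
  expect_lt(abs(auc_rank(pv$scores[, "rf"], yte) - target), 0.07)
})

test_that("majority vote follows the three model labels", {
  maj <- function(l) as.integer(sum(l) >= 2)
  expect_equal(maj(c(1, 1, 0)), 1L)
  expect_equal(maj(c(0, 0, 0)), 0L)
  set.seed(32)
  for (i in 1:50) {
    l <- rbinom(3, 1, 0.5)
    if (length(unique(l)) == 1L) expect_equal(maj(l), l[1])
  }
})

test_that("evaluation reproduces printed-precision aggregates", {
  expect_equal(vote_auc(c(0.875, 0.874, 0.849)), 0.866)
  expect_equal(vote_auc(c(0.86, 0.86, 0.857)), 0.859)
  expect_equal(vote_auc(c(1, 1, 1)), 1.0)
  expect_error(vote_auc(c(0.8, 0.9)), "three")
  expect_error(vote_auc(c(0.8, 0.9, 1.1)), "\\[0, 1\\]")

  # 141 correct of 180: accuracy 0.783 with exact binomial CI
  labels <- c(rep(1, 102), rep(0, 78))
  vote <- labels
  wrong <- c(1:20, 103:121)            # 39 errors
  vote[wrong] <- 1 - vote[wrong]
  scores <- cbind(svm = labels + 0.1, rf = labels + 0.2,
                  ridge = labels + 0.3)
  rep <- evaluate(scores, labels, vote)
  expect_equal(round(rep$accuracy, 3), 0.783)
  expect_equal(round(rep$accuracy_ci, 3), c(0.716, 0.841))
  expect_equal(unname(rep$confusion["TP"] + rep$confusion["TN"]), 141)
  expect_equal(rep$vote_auc, 1)        # scores separate perfectly
})
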