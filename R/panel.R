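#' Stratified fold assignment
#'
#' Assigns each sample to one of `folds` cross-validation folds so that
#' both classes are spread as evenly as possible across folds.
#'
#' @param y binary labels (0/1).
#' @param folds number of folds.
#' @return integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(y, folds = 5) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

.check_binary <- function(y) {
  u <- sort(unique(y))
  if (!all(u %in% c(0, 1)) || length(u) < 2L)
    stop("labels must contain both classes coded 0/1")
}

#' Repeated cross-validated LASSO feature selection
#'
#' Repeats, `repeats` times with fresh stratified folds: fit the
#' L1-penalized logistic path (geometric grid of 100 lambdas spanning 4
#' decades below lambda_max), pick the lambda maximizing mean out-of-fold
#' AUC, and record the nonzero-coefficient feature set of the full-data
#' fit at that lambda. Identical sets (order-insensitive) are aggregated
#' into candidates with a selection frequency and mean CV AUC.
#'
#' @param X sample x feature matrix (typically centred/scaled residuals)
#'   with column names.
#' @param y binary labels (1 = disease class).
#' @param folds CV folds (default 5).
#' @param repeats number of repetitions (default 100).
#' @param seed integer seed; repeat r uses seed + r.
#' @return data.frame of class `candidate_panels`, one row per distinct
#'   feature set: `features` (list column), `size`, `cv_auc` (mean),
#'   `frequency`, `lambda`.
#' @export
cv_lasso_select <- function(X, y, folds = 5, repeats = 100, seed = 1) {
  .check_binary(y)
  if (nrow(X) < 2 * folds)
    stop("need at least 2 samples per fold")
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant feature column(s) dropped")
    X <- X[, !const, drop = FALSE]
  }
  if (is.null(colnames(X))) stop("X must have feature names as colnames")
  key <- character(0)
  feats <- list(); aucs <- list(); lambdas <- numeric(0)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    foldid <- stratified_folds(y, folds)
    cvfit <- glmnet::cv.glmnet(X, y, family = "binomial",
                               type.measure = "auc", foldid = foldid,
                               nlambda = 100, lambda.min.ratio = 1e-4)
    lam <- cvfit$lambda.min
    cvauc <- cvfit$cvm[cvfit$lambda == lam][1L]
    cf <- as.matrix(stats::coef(cvfit, s = lam))
    sel <- rownames(cf)[-1L][cf[-1L, 1L] != 0]
    k <- paste(sort(sel), collapse = "\r")
    i <- match(k, key)
    if (is.na(i)) {
      key <- c(key, k)
      feats[[length(key)]] <- sel
      aucs[[length(key)]] <- cvauc
      lambdas <- c(lambdas, lam)
    } else {
      aucs[[i]] <- c(aucs[[i]], cvauc)
    }
  }
  out <- data.frame(size = lengths(feats),
                    cv_auc = vapply(aucs, mean, numeric(1)),
                    frequency = lengths(aucs),
                    lambda = lambdas)
  out$features <- feats
  class(out) <- c("candidate_panels", "data.frame")
  out
}

#' Select the biomarker panel from LASSO candidates
#'
#' `best_auc`: highest mean CV AUC, ties broken by higher frequency then
#' smaller panel. `most_frequent`: highest frequency, ties by AUC.
#' Under either rule, candidates with fewer than two features are skipped
#' in favour of the next-ranked candidate of size >= 2 (a one-feature
#' panel is never accepted).
#'
#' @param candidates a `candidate_panels` data.frame.
#' @param rule `"best_auc"` or `"most_frequent"`.
#' @return list of class `biomarker_panel`: `features`, `rule`,
#'   `cv_auc`, `frequency`, `size`.
#' @export
select_panel <- function(candidates, rule = c("best_auc", "most_frequent")) {
  rule <- match.arg(rule)
  if (!nrow(candidates)) stop("empty candidate list")
  ord <- if (rule == "best_auc")
    order(-candidates$cv_auc, -candidates$frequency, candidates$size)
  else
    order(-candidates$frequency, -candidates$cv_auc, candidates$size)
  ranked <- candidates[ord, , drop = FALSE]
  ranked <- ranked[ranked$size >= 2L, , drop = FALSE]
  if (!nrow(ranked))
    stop("no candidate panel with at least two features")
  structure(list(features = ranked$features[[1L]], rule = rule,
                 cv_auc = ranked$cv_auc[1L],
                 frequency = ranked$frequency[1L],
                 size = ranked$size[1L]),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> %d features (rule %s, CV AUC %.3f, freq %d)\n  %s\n",
              x$size, x$rule, x$cv_auc, x$frequency,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Optimal score cutoff by training accuracy
#'
#' Candidate cutoffs are the midpoints between adjacent sorted unique
#' scores, plus two sentinels (one below the minimum, one above the
#' maximum) so that the all-positive and all-negative rules are also in
#' play. The cutoff maximizing accuracy of the rule `score >= cutoff`
#' wins; ties are broken by maximizing Youden's J (sensitivity +
#' specificity - 1), then by the smaller cutoff.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels binary labels (0/1).
#' @return the chosen cutoff; attributes `accuracy` and `degenerate`.
#' @export
optimal_cutoff <- function(scores, labels) {
  .check_binary(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    out <- u
    attr(out, "degenerate") <- TRUE
    attr(out, "accuracy") <- max(mean(labels == 1), mean(labels == 0))
    return(out)
  }
  mids <- (u[-length(u)] + u[-1L]) / 2
  cand <- c(u[1L] - 1, mids, u[length(u)] + 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stat <- vapply(cand, function(cut) {
    pred <- as.integer(scores >= cut)
    tp <- sum(pred == 1 & labels == 1)
    tn <- sum(pred == 0 & labels == 0)
    c(acc = (tp + tn) / length(labels), j = tp / n1 + tn / n0 - 1)
  }, numeric(2))
  best <- which(stat["acc", ] == max(stat["acc", ]))
  best <- best[stat["j", best] == max(stat["j", best])]
  cut <- min(cand[best])
  out <- cut
  attr(out, "degenerate") <- FALSE
  attr(out, "accuracy") <- max(stat["acc", ])
  out
}

# Orient SVM decision values so that larger means class "1": e1071 labels
# the decision column "first/second" with positive values favouring the
# first-named class.
.svm_scores <- function(fit, X) {
  pred <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  flip <- identical(colnames(dv)[1L], "0/1")
  list(labels = as.integer(as.character(pred)),
       scores = if (flip) -dv[, 1L] else dv[, 1L])
}

#' Train the three-classifier ensemble on a panel
#'
#' Trains, on identical feature columns: a radial-basis SVM (cost 1,
#' kernel width `1/(p * Var(X))`), a 500-tree random forest (sqrt(p)
#' candidate features per split), and a ridge-penalized logistic
#' regression whose penalty is chosen by 5-fold CV AUC on the training
#' data. The ridge decision cutoff is then fixed from the training scores
#' by [optimal_cutoff()]. For a single-feature panel the ridge member is
#' an unpenalized logistic fit (the penalty is immaterial at p = 1).
#'
#' @param X sample x feature training matrix (panel columns only).
#' @param y binary labels (1 = disease class).
#' @param seed integer seed (forest and CV folds).
#' @param class_weights if `TRUE`, weight classes inversely to frequency
#'   in the SVM and forest (for imbalanced cohorts; default off).
#' @return list of class `ensemble_model`.
#' @export
train_ensemble <- function(X, y, seed = 1, class_weights = FALSE) {
  .check_binary(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have feature names as colnames")
  yf <- factor(y, levels = c(0, 1))
  p <- ncol(X)
  gamma <- 1 / (p * stats::var(as.vector(X)))
  cw <- if (class_weights)
    stats::setNames(length(y) / (2 * table(yf)), levels(yf)) else NULL
  set.seed(seed)
  svm_fit <- e1071::svm(X, yf, kernel = "radial", cost = 1, gamma = gamma,
                        scale = FALSE, class.weights = cw)
  set.seed(seed + 1L)
  rf_fit <- randomForest::randomForest(
    X, yf, ntree = 500,
    classwt = if (class_weights) unname(cw) else NULL)
  set.seed(seed + 2L)
  if (p >= 2L) {
    foldid <- stratified_folds(y, 5)
    rr_cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                               type.measure = "auc", foldid = foldid)
    rr <- list(type = "glmnet", fit = rr_cv, lambda = rr_cv$lambda.min)
    rr_train <- as.numeric(stats::predict(rr_cv, X, s = rr_cv$lambda.min,
                                          type = "response"))
  } else {
    df <- data.frame(y = y, x = X[, 1L])
    glm_fit <- suppressWarnings(stats::glm(y ~ x, data = df,
                                           family = stats::binomial()))
    rr <- list(type = "glm", fit = glm_fit)
    rr_train <- as.numeric(stats::predict(glm_fit, df, type = "response"))
  }
  cutoff <- optimal_cutoff(rr_train, y)
  structure(list(svm = svm_fit, rf = rf_fit, ridge = rr,
                 cutoff = as.numeric(cutoff), panel = colnames(X),
                 seed = seed, gamma = gamma,
                 class_weights = class_weights),
            class = "ensemble_model")
}

#' Predict with the ensemble and take the majority vote
#'
#' Returns each model's binary label and score plus the majority vote
#' (three voters, so no ties). The ridge label applies the cutoff fixed
#' at training; SVM and forest use their native decision rules.
#'
#' @param model an `ensemble_model`.
#' @param X sample x feature matrix containing the training panel columns.
#' @return list with `labels` (n x 3 matrix), `vote` (integer vector),
#'   `scores` (n x 3 matrix, columns svm/rf/ridge).
#' @export
predict_vote <- function(model, X) {
  stopifnot(inherits(model, "ensemble_model"))
  X <- as.matrix(X)
  missing <- setdiff(model$panel, colnames(X))
  if (length(missing))
    stop("missing panel column(s): ", paste(missing, collapse = ", "))
  X <- X[, model$panel, drop = FALSE]
  sv <- .svm_scores(model$svm, X)
  rf_prob <- stats::predict(model$rf, X, type = "prob")[, "1"]
  rf_lab <- as.integer(as.character(stats::predict(model$rf, X,
                                                   type = "response")))
  rr_score <- if (model$ridge$type == "glmnet")
    as.numeric(stats::predict(model$ridge$fit, X, s = model$ridge$lambda,
                              type = "response"))
  else
    as.numeric(stats::predict(model$ridge$fit,
                              data.frame(x = X[, 1L]), type = "response"))
  rr_lab <- as.integer(rr_score >= model$cutoff)
  labels <- cbind(svm = sv$labels, rf = rf_lab, ridge = rr_lab)
  vote <- as.integer(rowSums(labels) >= 2)
  scores <- cbind(svm = as.numeric(sv$scores), rf = as.numeric(rf_prob),
                  ridge = rr_score)
  rownames(labels) <- rownames(scores) <- rownames(X)
  list(labels = labels, vote = vote, scores = scores)
}

#' AUC by the rank statistic (Mann-Whitney, ties counted half)
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`, or `NA` with a warning if one class is absent.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step-wise integration)
#'
#' Thresholds sweep the unique scores from high to low (ties grouped);
#' the area is the sum over threshold steps of (recall increment) times
#' the precision at that step.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1).
#' @return AUPR, or `NA` if no positive labels exist.
#' @export
aupr_step <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0L) {
    warning("AUPR undefined: no positive labels")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  last <- cumsum(rle(s)$lengths)  # tie groups collapse to one threshold
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate per-model scores and the vote outcome
#'
#' Per-model AUC (rank statistic) and AUPR; the vote AUC is the
#' arithmetic mean of the three per-model AUCs. Accuracy, sensitivity,
#' specificity and the confusion counts are computed from the vote
#' labels, with an exact Clopper-Pearson 95% binomial CI on accuracy.
#'
#' @param scores_per_model n x 3 matrix (or data.frame) of model scores.
#' @param labels true binary labels.
#' @param vote_labels majority-vote predicted labels.
#' @return list of class `evaluation_report`.
#' @export
evaluate <- function(scores_per_model, labels, vote_labels) {
  scores_per_model <- as.matrix(scores_per_model)
  n <- length(labels)
  stopifnot(nrow(scores_per_model) == n, length(vote_labels) == n)
  aucs <- apply(scores_per_model, 2, auc_rank, labels = labels)
  auprs <- apply(scores_per_model, 2, aupr_step, labels = labels)
  tp <- sum(vote_labels == 1 & labels == 1)
  tn <- sum(vote_labels == 0 & labels == 0)
  fp <- sum(vote_labels == 1 & labels == 0)
  fn <- sum(vote_labels == 0 & labels == 1)
  correct <- tp + tn
  ci <- stats::binom.test(correct, n)$conf.int
  structure(list(
    auc = aucs,
    vote_auc = if (anyNA(aucs)) NA_real_ else vote_auc(aucs),
    aupr = auprs,
    accuracy = correct / n,
    accuracy_ci = as.numeric(ci),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> vote AUC %.3f | ACC %.3f (95%%CI %.3f-%.3f) | Sens %.3f | Spec %.3f\n",
              x$vote_auc, x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2],
              x$sensitivity, x$specificity))
  cat(sprintf("  per-model AUC: svm %.3f, rf %.3f, ridge %.3f\n",
              x$auc[1], x$auc[2], x$auc[3]))
  invisible(x)
}

#' Voted AUC: the mean of the three per-model AUCs
#'
#' @param aucs numeric vector of exactly three AUCs in `[0, 1]`.
#' @return their arithmetic mean, rounded to 3 decimals.
#' @export
vote_auc <- function(aucs) {
  if (length(aucs) != 3L) stop("exactly three AUCs are required")
  if (any(aucs < 0 | aucs > 1)) stop("AUCs must lie in [0, 1]")
  round(mean(aucs), 3)
}
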