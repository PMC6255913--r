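#' Cross-dataset panel discovery and evaluation protocol
#'
#' The full biomarker procedure in both directions: each dataset is
#' residualized independently on the covariates, the panel is selected by
#' repeated cross-validated LASSO on the AD/CTL samples of the training
#' dataset, the three-classifier ensemble is trained on the panel columns,
#' and performance is measured on the AD/CTL samples of the other
#' dataset. When MCI samples are present in the test dataset, the
#' fraction of MCI predicted as the disease class by the vote is also
#' reported (prodromal samples carrying the AD signature should be
#' captured by an AD-vs-CTL classifier).
#'
#' @param dsA,dsB [expression_dataset()]s sharing features.
#' @param infoA,infoB sample info data.frames.
#' @param covariates residualization covariates (default age, gender).
#' @param folds,repeats,rule LASSO selection settings (see
#'   [cv_lasso_select()] and [select_panel()]).
#' @param seed integer seed; the reverse direction uses `seed + 10000`.
#' @param class_weights passed to [train_ensemble()].
#' @return list of class `cross_dataset_result` with elements `A_to_B`
#'   and `B_to_A`, each holding `panel`, `report` (an
#'   `evaluation_report`), `mci_ad_rate` and the prediction objects.
#' @export
cross_dataset_protocol <- function(dsA, infoA, dsB, infoB,
                                   covariates = c("age", "gender"),
                                   folds = 5, repeats = 100,
                                   rule = "best_auc", seed = 1,
                                   class_weights = FALSE) {
  common <- intersect(dsA$feature_ids, dsB$feature_ids)
  if (!length(common)) stop("no common features between datasets")
  dsA <- subset_dataset(dsA, features = common)
  dsB <- subset_dataset(dsB, features = common)
  resA <- huber_residualize(dsA, infoA, covariates)
  resB <- huber_residualize(dsB, infoB, covariates)
  usable <- !resA$constant & !resB$constant
  one_direction <- function(res_tr, info_tr, res_te, info_te, seed) {
    Xtr <- t(res_tr$matrix[usable, , drop = FALSE])
    Xte <- t(res_te$matrix[usable, , drop = FALSE])
    tr_idx <- info_tr$group %in% c("AD", "CTL")
    y_tr <- as.integer(info_tr$group[tr_idx] == "AD")
    cand <- cv_lasso_select(Xtr[tr_idx, , drop = FALSE], y_tr,
                            folds = folds, repeats = repeats, seed = seed)
    panel <- select_panel(cand, rule = rule)
    model <- train_ensemble(Xtr[tr_idx, panel$features, drop = FALSE],
                            y_tr, seed = seed + 1L,
                            class_weights = class_weights)
    te_idx <- info_te$group %in% c("AD", "CTL")
    y_te <- as.integer(info_te$group[te_idx] == "AD")
    pred <- predict_vote(model, Xte[te_idx, , drop = FALSE])
    report <- evaluate(pred$scores, y_te, pred$vote)
    mci_idx <- info_te$group == "MCI"
    mci_rate <- if (any(mci_idx)) {
      mci_pred <- predict_vote(model, Xte[mci_idx, , drop = FALSE])
      mean(mci_pred$vote == 1)
    } else NA_real_
    list(panel = panel, model = model, report = report,
         mci_ad_rate = mci_rate, candidates = cand,
         predictions = pred, test_labels = y_te)
  }
  # sample ids are column names of the residual matrices in dataset order
  infoA <- infoA[match(dsA$sample_ids, infoA$sample_id), , drop = FALSE]
  infoB <- infoB[match(dsB$sample_ids, infoB$sample_id), , drop = FALSE]
  list(A_to_B = one_direction(resA, infoA, resB, infoB, seed),
       B_to_A = one_direction(resB, infoB, resA, infoA, seed + 10000L))
}
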