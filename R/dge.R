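#' Build a two-group design matrix with covariates
#'
#' Retains only samples belonging to the two contrast groups and builds
#' `intercept + group indicator + covariates`, with the indicator equal to
#' 1 for the first-named group. Covariate columns that are constant in the
#' retained samples (e.g. gender in an all-female subset) are dropped with
#' a warning rather than producing a rank-deficient fit.
#'
#' @param info sample info data.frame.
#' @param contrast character pair, e.g. `c("AD", "CTL")`; the coefficient
#'   reported downstream is first group minus second.
#' @param covariates covariate names; `"gender"` maps to a female
#'   indicator.
#' @return list with `design` (matrix), `sample_ids`, `contrast`, and
#'   `coef` (name of the contrast column).
#' @export
build_design <- function(info, contrast = c("AD", "CTL"),
                         covariates = c("age", "gender")) {
  if (length(contrast) != 2L || contrast[1] == contrast[2])
    stop("contrast must name two distinct groups")
  keep <- info$group %in% contrast
  if (!any(info$group == contrast[1]) || !any(info$group == contrast[2]))
    stop("both contrast groups must be present in the sample info")
  info <- info[keep, , drop = FALSE]
  design <- cbind(`(Intercept)` = rep(1, nrow(info)),
                  group = as.numeric(info$group == contrast[1]))
  if (length(covariates)) {
    cf <- .covariate_frame(info, covariates)
    design <- cbind(design, as.matrix(cf))
  }
  keep_col <- rep(TRUE, ncol(design))
  for (j in seq_len(ncol(design))[-1L]) {
    if (stats::sd(design[, j]) == 0) {
      keep_col[j] <- FALSE
      warning("design column '", colnames(design)[j],
              "' is constant and was dropped")
    }
  }
  design <- design[, keep_col, drop = FALSE]
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient after dropping constant columns")
  list(design = design, sample_ids = info$sample_id, contrast = contrast,
       coef = "group")
}

#' Fit per-feature linear models and extract the contrast coefficient
#'
#' Ordinary least squares per feature against a shared design matrix
#' (single QR decomposition for all features). Returns the contrast
#' coefficient (log2 units), residual variance, residual degrees of
#' freedom and the unscaled coefficient variance needed for moderated
#' t-statistics.
#'
#' @param ds an [expression_dataset()] whose samples cover the design.
#' @param design output of [build_design()].
#' @return list of class `gene_model_fit` with vectors `coefficients`,
#'   `sigma2`, `v` and scalars `df`, plus `feature_ids`.
#' @export
fit_gene_models <- function(ds, design) {
  stopifnot(inherits(ds, "expression_dataset"))
  X <- design$design
  missing <- setdiff(design$sample_ids, ds$sample_ids)
  if (length(missing))
    stop("dataset lacks design sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  Y <- ds$matrix[, design$sample_ids, drop = FALSE]
  n <- ncol(Y)
  qrX <- qr(X)
  d <- n - qrX$rank
  if (d <= 0) stop("no residual degrees of freedom (n <= rank of design)")
  B <- qr.coef(qrX, t(Y))              # terms x features
  fitted <- X %*% B
  rss <- colSums((t(Y) - fitted)^2)
  sigma2 <- rss / d
  xtx_inv <- chol2inv(qr.R(qrX))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  v <- xtx_inv[design$coef, design$coef]
  structure(list(coefficients = unname(B[design$coef, ]),
                 sigma2 = unname(sigma2), df = d, v = v,
                 feature_ids = rownames(Y), contrast = design$contrast),
            class = "gene_model_fit")
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# following the standard monotone transformation trick.
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Assumes the hierarchical model in which per-feature variances follow a
#' scaled inverse-chi-square prior with df `d0` and scale `s0^2`, so that
#' observed variances are distributed as `s0^2 F(d, d0)`. Hyperparameters
#' are estimated by matching the mean and variance of `log(sigma2)` to the
#' log scaled-F distribution; `d0` solves a trigamma equation by Newton
#' root finding (relative tolerance 1e-8). Posterior variances are the
#' df-weighted mix `(d0 s0^2 + d sigma2) / (d0 + d)`; moderated t uses
#' `d0 + d` degrees of freedom. If the spread of log variances is at or
#' below the sampling-only value, `d0` is infinite and every posterior
#' variance equals `s0^2`.
#'
#' @param fits a `gene_model_fit` (at least 2 features; fewer than 10
#'   gives a warning).
#' @param d0_override optional fixed prior df (0 disables moderation and
#'   reproduces ordinary t-tests; `Inf` forces complete pooling).
#' @return list of class `moderation_params` with `d0`, `s02`, vectors
#'   `s2_post`, `t`, `p`, `df_total`, plus the fit quantities.
#' @export
eb_moderate <- function(fits, d0_override = NULL) {
  stopifnot(inherits(fits, "gene_model_fit"))
  G <- length(fits$sigma2)
  if (G < 2L) stop("need at least 2 features to moderate variances")
  if (G < 10L) warning("fewer than 10 features: hyperparameter estimates ",
                       "will be unstable")
  d <- fits$df
  ok <- fits$sigma2 > 0 & d > 0
  if (!any(ok)) stop("no usable residual variances")
  if (is.null(d0_override)) {
    z <- log(fits$sigma2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(d / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # complete pooling: the prior scale is the geometric mean of the
      # observed variances, so identical variances return themselves
      d0 <- Inf
      s02 <- exp(mean(z))
    }
  } else {
    d0 <- d0_override
    if (d0 < 0) stop("d0 must be nonnegative")
    z <- log(fits$sigma2[ok])
    s02 <- if (is.finite(d0) && d0 > 0)
      exp(mean(z) - digamma(d / 2) + log(d / 2) + digamma(d0 / 2) -
            log(d0 / 2))
    else exp(mean(z))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, G)
  else (d0 * s02 + d * fits$sigma2) / (d0 + d)
  df_total <- d0 + d
  tstat <- fits$coefficients / (sqrt(s2_post) * sqrt(fits$v))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  structure(list(d0 = d0, s02 = s02, s2_post = s2_post, t = tstat, p = p,
                 df_total = df_total, coefficients = fits$coefficients,
                 sigma2 = fits$sigma2, df = fits$df, v = fits$v,
                 feature_ids = fits$feature_ids, contrast = fits$contrast),
            class = "moderation_params")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validating wrapper around `stats::p.adjust(method = "BH")`:
#' sort ascending, multiply by `m/i`, enforce monotonicity from the
#' largest rank, cap at 1, return in input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("pvals must be numeric")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("all p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed features
#'
#' Builds the DEG table: log2 coefficient, natural-scale fold change
#' `FC = 2^logFC` (values below 1 are down-regulated), moderated t,
#' unadjusted and BH-adjusted p-values, direction and significance flag.
#' `mode = "bh"` flags `BH.pval < alpha`; `mode = "nominal"` flags
#' `p < alpha` (the fallback used when no feature survives multiple
#' testing, as in small validation cohorts).
#'
#' @param mod a `moderation_params` object.
#' @param mode `"bh"` or `"nominal"`.
#' @param alpha significance level (default 0.01).
#' @param ann optional annotation data.frame supplying `gene_id`.
#' @return data.frame with columns `feature_id`, `gene_id`, `logFC`,
#'   `FC`, `t`, `p`, `BH.pval`, `direction`, `significant`.
#' @export
call_degs <- function(mod, mode = c("bh", "nominal"), alpha = 0.01,
                      ann = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(mod, "moderation_params"))
  bh <- bh_adjust(mod$p)
  gene_id <- if (is.null(ann)) NA_character_
  else unname(stats::setNames(ann$gene_id, ann$feature_id)[mod$feature_ids])
  out <- data.frame(
    feature_id = mod$feature_ids,
    gene_id = gene_id,
    logFC = mod$coefficients,
    FC = 2^mod$coefficients,
    t = mod$t,
    p = mod$p,
    BH.pval = bh,
    direction = ifelse(mod$coefficients > 0, "up", "down"),
    significant = if (mode == "bh") bh < alpha else mod$p < alpha,
    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "alpha") <- alpha
  attr(out, "contrast") <- mod$contrast
  out
}

#' Run the full differential-expression stage on one dataset
#'
#' Convenience wrapper: design, per-feature fits, empirical-Bayes
#' moderation, DEG calling.
#'
#' @inheritParams build_design
#' @inheritParams call_degs
#' @param ds an [expression_dataset()].
#' @return A DEG table (see [call_degs()]).
#' @export
run_dge <- function(ds, info, contrast = c("AD", "CTL"),
                    covariates = c("age", "gender"),
                    mode = "bh", alpha = 0.01, ann = NULL) {
  design <- build_design(info, contrast, covariates)
  fits <- fit_gene_models(ds, design)
  mod <- eb_moderate(fits)
  call_degs(mod, mode = mode, alpha = alpha, ann = ann)
}

#' Write a DEG table as TSV
#'
#' @param table DEG table from [call_degs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
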