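#' Drop features without a gene annotation
#'
#' Microarray probesets lacking an Entrez-style gene id carry no
#' cross-cohort meaning and are removed before any comparison between
#' studies. Features missing from the annotation table are treated as
#' unannotated.
#'
#' @param ds an [expression_dataset()].
#' @param ann annotation data.frame from [read_annotation()].
#' @return An `expression_dataset` restricted (in original order) to
#'   features with a non-empty `gene_id`.
#' @export
filter_annotated <- function(ds, ann) {
  stopifnot(inherits(ds, "expression_dataset"))
  gene <- stats::setNames(ann$gene_id, ann$feature_id)
  keep <- ds$feature_ids[!is.na(gene[ds$feature_ids]) &
                           nzchar(gene[ds$feature_ids])]
  if (!length(keep)) {
    warning("no annotated features remain")
    m <- ds$matrix[integer(0), , drop = FALSE]
    rownames(m) <- character(0)
    return(structure(list(matrix = m, feature_ids = character(0),
                          sample_ids = ds$sample_ids,
                          dataset_label = ds$dataset_label),
                     class = "expression_dataset"))
  }
  subset_dataset(ds, features = keep)
}

#' Merge two cohorts on their common features with batch adjustment
#'
#' Restricts both datasets to the intersection of their feature sets and
#' removes additive between-cohort (batch) differences. Two adjustments
#' are offered: `batch_mean_center` subtracts each feature's per-batch
#' mean (the default: the simplest transformation that removes additive
#' offsets), and `eb_location_scale` applies a ComBat-style parametric
#' empirical-Bayes location-scale adjustment that additionally shrinks
#' per-batch feature variances toward a pooled prior.
#'
#' @param dsA,dsB [expression_dataset()]s with disjoint sample ids.
#' @param method `"batch_mean_center"` or `"eb_location_scale"`.
#' @return An `expression_dataset` whose label records the method, with
#'   attributes `batch` (per-sample batch labels) and `merge_method`.
#' @export
merge_datasets <- function(dsA, dsB,
                           method = c("batch_mean_center",
                                      "eb_location_scale")) {
  method <- match.arg(method)
  stopifnot(inherits(dsA, "expression_dataset"),
            inherits(dsB, "expression_dataset"))
  common <- intersect(dsA$feature_ids, dsB$feature_ids)
  if (!length(common)) stop("no common features between the two datasets")
  if (length(common) < 2L) stop("need at least 2 common features to merge")
  dup <- intersect(dsA$sample_ids, dsB$sample_ids)
  if (length(dup))
    stop("sample id(s) present in both datasets: ",
         paste(utils::head(dup, 5), collapse = ", "))
  x <- cbind(dsA$matrix[common, , drop = FALSE],
             dsB$matrix[common, , drop = FALSE])
  batch <- c(rep(dsA$dataset_label, ncol(dsA$matrix)),
             rep(dsB$dataset_label, ncol(dsB$matrix)))
  if (method == "batch_mean_center") {
    for (b in unique(batch)) {
      idx <- batch == b
      x[, idx] <- x[, idx, drop = FALSE] -
        rowMeans(x[, idx, drop = FALSE])
    }
  } else {
    if (!requireNamespace("sva", quietly = TRUE))
      stop("method 'eb_location_scale' requires the sva package")
    x <- sva::ComBat(dat = x, batch = batch, par.prior = TRUE,
                     prior.plots = FALSE)
  }
  out <- expression_dataset(x, paste0("merged(", dsA$dataset_label, "+",
                                      dsB$dataset_label, ")"))
  attr(out, "batch") <- batch
  attr(out, "merge_method") <- method
  out
}

.gender_indicator <- function(gender) as.numeric(gender == "F")

.covariate_frame <- function(info, covariates) {
  if (!length(covariates))
    return(as.data.frame(matrix(numeric(0), nrow = nrow(info), ncol = 0)))
  out <- list()
  for (cv in covariates) {
    if (cv == "gender") {
      out$gender <- .gender_indicator(info$gender)
    } else if (!cv %in% names(info)) {
      stop("covariate '", cv, "' not present in sample info")
    } else {
      v <- info[[cv]]
      if (!is.numeric(v)) stop("covariate '", cv, "' is not numeric")
      out[[cv]] <- v
    }
  }
  as.data.frame(out)
}

#' Residualize expression on covariates by Huber robust regression
#'
#' Fits, per feature, a linear model of expression on an intercept plus
#' the named covariates by Huber M-estimation (tuning constant 1.345,
#' MAD residual scale, at most 50 IRLS iterations, coefficient-change
#' convergence tolerance 1e-8 — `MASS::rlm`), then centres the residuals
#' and scales them to unit standard deviation. Non-converging features
#' fall back to least squares with a warning; constant features are
#' returned as all-zero rows and flagged so downstream stages can drop
#' them.
#'
#' @param ds an [expression_dataset()].
#' @param info sample info data.frame covering all samples of `ds`.
#' @param covariates character vector of covariate names (`"gender"` is
#'   mapped to a female indicator).
#' @return A list of class `residual_matrix` with elements `matrix`
#'   (feature x sample, centred/scaled residuals), `converged`,
#'   `constant` (logical flags per feature) and `iterations`.
#' @export
huber_residualize <- function(ds, info, covariates = c("age", "gender")) {
  stopifnot(inherits(ds, "expression_dataset"))
  missing <- setdiff(ds$sample_ids, info$sample_id)
  if (length(missing))
    stop("sample info lacks sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  info <- info[match(ds$sample_ids, info$sample_id), , drop = FALSE]
  cf <- .covariate_frame(info, covariates)
  n <- ncol(ds$matrix)
  if (n <= ncol(cf) + 1L)
    stop("need more samples than covariates + 1")
  X <- cbind(`(Intercept)` = 1, as.matrix(cf))
  G <- nrow(ds$matrix)
  res <- matrix(0, G, n, dimnames = dimnames(ds$matrix))
  converged <- rep(TRUE, G)
  constant <- rep(FALSE, G)
  iterations <- integer(G)
  n_fallback <- 0L
  for (g in seq_len(G)) {
    y <- ds$matrix[g, ]
    if (stats::sd(y) == 0) {
      constant[g] <- TRUE
      next
    }
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                                 scale.est = "MAD", maxit = 50,
                                 acc = 1e-8, test.vec = "coef")),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      converged[g] <- FALSE
      n_fallback <- n_fallback + 1L
      r <- stats::lm.fit(X, y)$residuals
      iterations[g] <- if (is.null(fit)) 0L else length(fit$conv)
    } else {
      r <- stats::residuals(fit)
      iterations[g] <- length(fit$conv)
    }
    r <- r - mean(r)
    s <- stats::sd(r)
    res[g, ] <- if (s > 0) r / s else 0
  }
  if (n_fallback > 0L)
    warning(n_fallback, " feature(s) did not converge in 50 Huber ",
            "iterations; least-squares fallback used")
  structure(list(matrix = res, converged = converged, constant = constant,
                 iterations = iterations, covariates = covariates),
            class = "residual_matrix")
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("<residual_matrix> %d features x %d samples (%d constant, %d non-converged)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$constant),
              sum(!x$converged)))
  invisible(x)
}

#' Write a residual matrix as TSV (features x samples, plus a label row)
#'
#' Mirrors the shape of deposited centred/scaled residual files: the first
#' data row carries the per-sample diagnosis labels when `info` is given.
#'
#' @param rm a `residual_matrix`.
#' @param path output path.
#' @param info optional sample info supplying a `group` label row.
#' @return `path`, invisibly.
#' @export
write_residual_matrix <- function(rm, path, info = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  sids <- colnames(rm$matrix)
  writeLines(paste(c("feature_id", sids), collapse = "\t"), con)
  if (!is.null(info)) {
    lab <- info$group[match(sids, info$sample_id)]
    writeLines(paste(c("diagnosis", lab), collapse = "\t"), con)
  }
  body <- apply(rm$matrix, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(rm$matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Collapse a probeset-level DEG table to unique genes
#'
#' One record per gene: the representative probeset is the one with the
#' smallest unadjusted p-value; the gene is significant if any of its
#' probesets is; direction is taken from the representative. This
#' min-p convention preserves "top DEG" rankings across the collapse.
#'
#' @param table a DEG table (see [call_degs()]).
#' @param ann annotation data.frame covering every feature in `table`.
#' @return A gene-level DEG table whose `feature_id` equals `gene_id`.
#' @export
collapse_to_genes <- function(table, ann) {
  gene <- stats::setNames(ann$gene_id, ann$feature_id)
  g <- gene[table$feature_id]
  if (anyNA(g) || any(!nzchar(g)))
    stop("every feature in the table must be annotated with a gene id")
  table$gene_id <- unname(g)
  ord <- order(table$p, table$BH.pval, table$feature_id)
  sorted <- table[ord, , drop = FALSE]
  rep_rows <- sorted[!duplicated(sorted$gene_id), , drop = FALSE]
  any_sig <- tapply(table$significant, table$gene_id, any)
  rep_rows$significant <- as.logical(any_sig[rep_rows$gene_id])
  rep_rows$probeset_id <- rep_rows$feature_id
  rep_rows$feature_id <- rep_rows$gene_id
  rownames(rep_rows) <- NULL
  rep_rows
}
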