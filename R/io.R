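#' Expression dataset container
#'
#' A validated feature-by-sample matrix of log2-scale expression values,
#' carrying a dataset label used downstream as the batch identity when
#' cohorts are merged.
#'
#' @param matrix numeric matrix, features in rows, samples in columns, with
#'   unique non-empty dimnames; all values must be finite.
#' @param dataset_label single string identifying the cohort/batch.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `feature_ids`, `sample_ids`, `dataset_label`.
#' @export
expression_dataset <- function(matrix, dataset_label) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression data must be a numeric matrix")
  fid <- rownames(matrix)
  sid <- colnames(matrix)
  if (is.null(fid) || is.null(sid))
    stop("expression matrix must carry feature and sample ids as dimnames")
  if (anyDuplicated(fid))
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(matrix)))
    stop("expression matrix contains non-finite values")
  if (!is.character(dataset_label) || length(dataset_label) != 1L)
    stop("dataset_label must be a single string")
  structure(
    list(matrix = matrix, feature_ids = fid, sample_ids = sid,
         dataset_label = dataset_label),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s'> %d features x %d samples\n",
              x$dataset_label, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Subset an expression dataset by feature and/or sample ids
#'
#' @param ds an `expression_dataset`.
#' @param features,samples character vectors of ids to retain (in the given
#'   order); `NULL` keeps everything.
#' @return An `expression_dataset`.
#' @export
subset_dataset <- function(ds, features = NULL, samples = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  m <- ds$matrix
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing))
      stop("unknown feature id(s): ", paste(utils::head(missing, 5), collapse = ", "))
    m <- m[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing))
      stop("unknown sample id(s): ", paste(utils::head(missing, 5), collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  expression_dataset(m, ds$dataset_label)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids; the first column holds feature ids.
#' Validation is strict: ragged rows, duplicated ids and non-numeric cells
#' are errors that name the offending line.
#'
#' @param path path to a TSV file.
#' @param dataset_label cohort/batch label to attach.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, dataset_label) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L)
    stop("expression file ", path, " has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("header of ", path, " has no sample columns")
  sample_ids <- header[-1L]
  ncol_exp <- length(header)
  nf <- lengths(fields[-1L])
  bad <- which(nf != ncol_exp)
  if (length(bad))
    stop("ragged row at line ", bad[1L] + 1L, " of ", path,
         " (expected ", ncol_exp, " fields, found ", nf[bad[1L]], ")")
  body <- fields[-1L]
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(feature_ids)) {
    d <- feature_ids[duplicated(feature_ids)][1L]
    stop("duplicate feature id '", d, "' at line ",
         which(feature_ids == d)[2L] + 1L, " of ", path)
  }
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) {
    i <- which(is.na(vals))[1L]
    row <- (i - 1L) %/% (ncol_exp - 1L) + 1L
    col <- (i - 1L) %% (ncol_exp - 1L) + 1L
    stop("non-numeric cell '", cells[i], "' at line ", row + 1L,
         ", sample column '", sample_ids[col], "' of ", path)
  }
  m <- matrix(vals, nrow = length(feature_ids), ncol = ncol_exp - 1L,
              byrow = TRUE, dimnames = list(feature_ids, sample_ids))
  expression_dataset(m, dataset_label)
}

#' Write an expression dataset as TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the matrix to full double precision.
#'
#' @param ds an `expression_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", ds$sample_ids), collapse = "\t"), con)
  body <- apply(ds$matrix, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(ds$feature_ids, body, sep = "\t"), con)
  invisible(path)
}

.valid_groups <- c("AD", "MCI", "CTL")
.valid_genders <- c("M", "F")

#' Read a sample-information table
#'
#' Requires columns `sample_id`, `group`, `age`, `gender` (tab-delimited).
#' `group` must be one of AD, MCI, CTL (the study design has no other
#' diagnosis classes; e.g. Parkinson's samples must be removed upstream).
#' Any further columns are retained as extra numeric covariates.
#'
#' @param path path to a TSV file with a header.
#' @return A data.frame with one row per sample; extra covariate columns
#'   are carried through and listed in `attr(, "extra_covariates")`.
#' @export
read_sample_info <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  req <- c("sample_id", "group", "age", "gender")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("sample info ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), .valid_groups)
  if (length(bad))
    stop("unknown group label(s) ", paste(bad, collapse = ", "),
         "; allowed labels are ", paste(.valid_groups, collapse = ", "))
  bad_g <- setdiff(unique(df$gender), .valid_genders)
  if (length(bad_g))
    stop("unknown gender code(s) ", paste(bad_g, collapse = ", "),
         "; allowed codes are ", paste(.valid_genders, collapse = ", "))
  age <- suppressWarnings(as.numeric(df$age))
  if (anyNA(age) || any(age <= 0))
    stop("age must be a positive number for every sample in ", path)
  extra <- setdiff(names(df), req)
  out <- data.frame(sample_id = df$sample_id, group = df$group,
                    age = age, gender = df$gender,
                    stringsAsFactors = FALSE)
  for (nm in extra) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v))
      stop("extra covariate column '", nm, "' in ", path, " is non-numeric")
    out[[nm]] <- v
  }
  attr(out, "extra_covariates") <- extra
  out
}

#' Write a sample-information table as TSV
#'
#' @param info data.frame as returned by [read_sample_info()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_info <- function(info, path) {
  utils::write.table(info, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Each line is: set name, description, then member ids, tab-delimited.
#' Members are deduplicated; duplicate set names and empty sets are errors.
#'
#' @param path path to a `.gmt` file.
#' @return A named list of character vectors with class
#'   `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("empty gene set at line ", short[1L], " of ", path)
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene-set name '", nms[duplicated(nms)][1L], "' in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' Members are written sorted so that the file is a canonical form: reading
#' and re-writing any collection is idempotent.
#'
#' @param sets a `gene_set_collection` (or plain named list).
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sort(unique(sets[[i]]))),
          collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a feature annotation table
#'
#' Tab-delimited with columns `feature_id`, `gene_id`, `symbol`. Empty
#' gene ids are preserved here; filtering of unannotated features happens
#' downstream (see [filter_annotated()]).
#'
#' @param path path to a TSV file with a header.
#' @return data.frame with character columns `feature_id`, `gene_id`,
#'   `symbol`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8", na.strings = NULL)
  req <- c("feature_id", "gene_id", "symbol")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("annotation ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature_id '",
         df$feature_id[duplicated(df$feature_id)][1L], "' in ", path)
  df[is.na(df)] <- ""
  df[, req]
}

#' Write run metadata as JSON
#'
#' Records the parameters, seed and package version that produced a result
#' directory, so any run can be reproduced exactly.
#'
#' @param meta named list of run parameters.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  meta$package <- "admarker"
  meta$package_version <- as.character(utils::packageVersion("admarker"))
  meta$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
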