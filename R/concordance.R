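#' Build a 2x2 membership contingency table over a universe
#'
#' Counts `a` (in both lists), `b` (A only), `c` (B only), `d` (neither).
#' Both lists must be contained in the universe.
#'
#' @param listA,listB character vectors of ids.
#' @param universe character vector defining the background.
#' @param labels optional character(3) provenance labels for A, B and the
#'   universe.
#' @return list of class `contingency_table` with counts and labels.
#' @export
build_contingency <- function(listA, listB, universe,
                              labels = c("A", "B", "universe")) {
  listA <- unique(listA); listB <- unique(listB)
  universe <- unique(universe)
  outA <- setdiff(listA, universe)
  if (length(outA))
    stop("listA id(s) outside the universe: ",
         paste(utils::head(outA, 5), collapse = ", "))
  outB <- setdiff(listB, universe)
  if (length(outB))
    stop("listB id(s) outside the universe: ",
         paste(utils::head(outB, 5), collapse = ", "))
  a <- length(intersect(listA, listB))
  b <- length(listA) - a
  c <- length(listB) - a
  d <- length(universe) - a - b - c
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 labels = labels),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%d b=%d c=%d d=%d (N=%d)\n",
              x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Fisher-exact enrichment of a 2x2 table
#'
#' Two-sided exact p by the minimum-likelihood rule (tables no more
#' probable than the observed one) and the conditional maximum-likelihood
#' odds ratio of the noncentral hypergeometric model, i.e. the convention
#' of `stats::fisher.test`. The 95% CI is the exact conditional interval
#' when the smallest margin is at most 200; for larger tables the Woolf
#' log-OR normal approximation is used, with a 0.5 continuity correction
#' only when a zero cell exists. Degenerate margins (an empty row or
#' column) yield a flagged result with undefined OR.
#'
#' @param t a [build_contingency()] table.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `enrichment_stat` with `or`, `ci`, `p`,
#'   `method`, `degenerate`.
#' @export
fisher_enrichment <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  margins <- c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d)
  if (any(margins == 0))
    return(structure(list(or = NA_real_, ci = c(NA_real_, NA_real_),
                          p = 1, method = "degenerate", degenerate = TRUE),
                     class = "enrichment_stat"))
  ft <- stats::fisher.test(m, conf.level = conf_level)
  if (min(margins) <= 200) {
    ci <- unname(ft$conf.int)
    method <- "exact-conditional"
  } else {
    cc <- if (any(m == 0)) 0.5 else 0
    a <- t$a + cc; b <- t$b + cc; c <- t$c + cc; d <- t$d + cc
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    lor <- log(a * d / (b * c))
    ci <- exp(lor + c(-1, 1) * z * se)
    method <- if (cc > 0) "woolf-cc" else "woolf"
  }
  structure(list(or = unname(ft$estimate), ci = ci, p = ft$p.value,
                 method = method, degenerate = FALSE),
            class = "enrichment_stat")
}

#' @export
print.enrichment_stat <- function(x, ...) {
  if (x$degenerate) cat("<enrichment_stat> degenerate margins\n")
  else cat(sprintf("<enrichment_stat> OR=%.3g (95%%CI %.3g-%.3g), p=%.3g [%s]\n",
                   x$or, x$ci[1], x$ci[2], x$p, x$method))
  invisible(x)
}

#' Direction concordance of two DEG tables (sign test)
#'
#' Overlap = features significant in both tables; concordant = same
#' regulation direction. The two-sided exact binomial (sign) test asks
#' whether concordance departs from the chance rate 0.5.
#'
#' @param tableA,tableB DEG tables sharing an id space in `feature_id`.
#' @return list of class `concordance_result` with `n_overlap`,
#'   `n_same_direction`, `proportion`, `p` (NA with `degenerate = TRUE`
#'   when the overlap is empty).
#' @export
direction_concordance <- function(tableA, tableB) {
  sa <- tableA[tableA$significant, c("feature_id", "direction")]
  sb <- tableB[tableB$significant, c("feature_id", "direction")]
  mg <- merge(sa, sb, by = "feature_id", suffixes = c(".A", ".B"))
  n <- nrow(mg)
  if (n == 0L)
    return(structure(list(n_overlap = 0L, n_same_direction = 0L,
                          proportion = NA_real_, p = NA_real_,
                          degenerate = TRUE),
                     class = "concordance_result"))
  same <- sum(mg$direction.A == mg$direction.B)
  bt <- stats::binom.test(same, n, p = 0.5, alternative = "two.sided")
  structure(list(n_overlap = n, n_same_direction = same,
                 proportion = same / n, p = bt$p.value, degenerate = FALSE),
            class = "concordance_result")
}

# Round half away from zero to `digits` decimals (printed-table style;
# base round() would go to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Region-by-region overlap ratio table
#'
#' For each brain-region DEG table: significant counts split by the
#' region's direction, counts of those DEGs that are also significant in
#' the blood table (split by the blood direction), and
#' `ratio = overlap_all / region_all` rounded half-up to 2 decimals.
#' Rows are sorted by decreasing ratio.
#'
#' @param region_tables named list of DEG tables (gene level).
#' @param blood_table DEG table in the same id space.
#' @return data.frame with one row per region.
#' @export
overlap_ratio_table <- function(region_tables, blood_table) {
  blood_sig <- blood_table[blood_table$significant,
                           c("feature_id", "direction")]
  rows <- lapply(names(region_tables), function(nm) {
    rt <- region_tables[[nm]]
    sig <- rt[rt$significant, c("feature_id", "direction")]
    ov <- blood_sig[blood_sig$feature_id %in% sig$feature_id, ]
    data.frame(region = nm,
               region_up = sum(sig$direction == "up"),
               region_down = sum(sig$direction == "down"),
               region_all = nrow(sig),
               overlap_up = sum(ov$direction == "up"),
               overlap_down = sum(ov$direction == "down"),
               overlap_all = nrow(ov),
               ratio = if (nrow(sig) > 0)
                 round_half_up(nrow(ov) / nrow(sig), 2) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$ratio), , drop = FALSE]
}

#' Enrichment of a DEG list among trait-correlated genes
#'
#' Flags genes whose absolute correlation with a neuropathological trait
#' (e.g. Braak stage or frontal atrophy) exceeds `threshold`, then tests
#' the DEG list for enrichment among the flagged genes by Fisher's exact
#' test over the universe.
#'
#' @param gene_corrs named numeric vector of per-gene correlations in
#'   `[-1, 1]`.
#' @param deg_list character vector of DEG ids.
#' @param universe background ids (must cover `deg_list`).
#' @param threshold absolute-correlation cutoff (default 0.5).
#' @return An `enrichment_stat` (see [fisher_enrichment()]).
#' @export
trait_association <- function(gene_corrs, deg_list, universe,
                              threshold = 0.5) {
  if (any(abs(gene_corrs) > 1))
    stop("correlations must lie in [-1, 1]")
  flagged <- names(gene_corrs)[abs(gene_corrs) > threshold]
  flagged <- intersect(flagged, universe)
  ct <- build_contingency(deg_list, flagged, universe,
                          labels = c("DEGs", "trait-correlated", "universe"))
  fisher_enrichment(ct)
}

#' Gene-set overrepresentation analysis (hypergeometric upper tail)
#'
#' For each set, members are first restricted to the universe; the
#' upper-tail hypergeometric p-value `P(X >= k)` tests whether the DEG
#' list hits the set more often than chance. BH adjustment is applied
#' across all sets of the collection and sets with `BH.pval < 0.01` are
#' flagged significant. Sets with no in-universe members are skipped with
#' a warning.
#'
#' @param deg_list character vector of DEG ids (subset of `universe`).
#' @param universe background ids.
#' @param sets a `gene_set_collection`.
#' @param direction_label context label recorded per row
#'   (`"up"`, `"down"` or `"all"`).
#' @param alpha BH significance level (default 0.01).
#' @return data.frame with columns `set`, `set_size`, `hits`, `n_deg`,
#'   `universe_size`, `ratio`, `p`, `BH.pval`, `significant`, `direction`.
#' @export
ora <- function(deg_list, universe, sets, direction_label = "all",
                alpha = 0.01) {
  universe <- unique(universe)
  deg_list <- unique(deg_list)
  out_ids <- setdiff(deg_list, universe)
  if (length(out_ids))
    stop("deg_list id(s) outside the universe: ",
         paste(utils::head(out_ids, 5), collapse = ", "))
  N <- length(universe)
  n <- length(deg_list)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    m <- length(members)
    if (m == 0L) {
      warning("gene set '", nm, "' has no members in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(members, deg_list))
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, hits = k, n_deg = n,
               universe_size = N, ratio = sprintf("%d/%d", k, m),
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$BH.pval <- bh_adjust(out$p)
  out$significant <- out$BH.pval < alpha
  out$direction <- direction_label
  out[order(out$p), , drop = FALSE]
}
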