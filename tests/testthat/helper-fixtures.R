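# Shared fixtures and independent oracles for the test suite.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A tiny valid 3-feature x 2-sample expression file
tiny_expression_lines <- function() {
  c("feature_id\ts1\ts2",
    "p1\t1.5\t2.25",
    "p2\t-0.5\t0.125",
    "p3\t7\t8")
}

make_deg_table <- function(ids, direction, significant,
                           p = rep(0.001, length(ids))) {
  data.frame(feature_id = ids,
             gene_id = ids,
             logFC = ifelse(direction == "up", 0.3, -0.3),
             FC = 2^ifelse(direction == "up", 0.3, -0.3),
             t = 3, p = p, BH.pval = pmin(1, p * 2),
             direction = direction, significant = significant,
             stringsAsFactors = FALSE)
}

# Brute-force BH step-up, written independently of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive two-sided Fisher p by the minimum-likelihood rule
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Pair-counting AUC: fraction of (pos, neg) pairs ranked correctly,
# ties counted half
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  u <- 0
  for (p in pos) for (q in neg)
    u <- u + (p > q) + 0.5 * (p == q)
  u / (length(pos) * length(neg))
}

# Exhaustive accuracy scan over candidate cutoffs (same candidate set as
# the implementation: midpoints plus sentinels), returning best accuracy
cutoff_accuracy_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  max(vapply(cand, function(cut)
    mean(as.integer(scores >= cut) == labels), numeric(1)))
}

# gene_model_fit built directly from simulated variances
fit_from_sigma2 <- function(sigma2, df, coefficients = rep(0, length(sigma2)),
                            v = 1) {
  structure(list(coefficients = coefficients, sigma2 = sigma2, df = df,
                 v = v, feature_ids = sprintf("f%05d", seq_along(sigma2)),
                 contrast = c("AD", "CTL")),
            class = "gene_model_fit")
}
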