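test_that("contingency tables count membership correctly", {
  u <- as.character(1:5)
  ct <- build_contingency(c("1", "2"), c("2", "3"), u)
  expect_equal(unlist(ct[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 2))

  same <- build_contingency(c("1", "2"), c("1", "2"), u)
  expect_equal(same$b, 0); expect_equal(same$c, 0)

  disj <- build_contingency(c("1", "2"), c("3", "4", "5"), u)
  expect_equal(disj$a, 0); expect_equal(disj$d, 0)

  expect_error(build_contingency(c("1", "9"), c("2"), u), "9")
})

test_that("Fisher enrichment matches symmetry and the enumeration oracle", {
  u <- 1:40
  ct <- structure(list(a = 10, b = 10, c = 10, d = 10, n = 40,
                       labels = c("A", "B", "u")),
                  class = "contingency_table")
  st <- fisher_enrichment(ct)
  expect_equal(st$or, 1, tolerance = 1e-6)
  expect_equal(st$p, 1)

  ct2 <- structure(list(a = 8, b = 2, c = 1, d = 9, n = 20,
                        labels = c("A", "B", "u")),
                   class = "contingency_table")
  st2 <- fisher_enrichment(ct2)
  expect_equal(st2$p, fisher_p_oracle(8, 2, 1, 9), tolerance = 1e-8)
  # conditional MLE maximizes the noncentral hypergeometric likelihood:
  # grid scan around the estimate must not find a better psi
  loglik <- function(psi) {
    support <- max(0, 9 - 10):min(10, 9)
    num <- dhyper(8, 9, 11, 10) * psi^8
    den <- sum(dhyper(support, 9, 11, 10) * psi^support)
    log(num / den)
  }
  grid <- st2$or * seq(0.8, 1.2, by = 0.001)
  expect_true(all(loglik(st2$or) >=
                    vapply(grid, loglik, numeric(1)) - 1e-6))

  # zero-cell path uses the continuity-corrected Woolf CI flag only for
  # large margins; small tables keep the exact interval
  ct3 <- structure(list(a = 0, b = 5, c = 5, d = 5, n = 15,
                        labels = c("A", "B", "u")),
                   class = "contingency_table")
  st3 <- fisher_enrichment(ct3)
  expect_equal(st3$method, "exact-conditional")
  big <- structure(list(a = 0, b = 500, c = 500, d = 500, n = 1500,
                        labels = c("A", "B", "u")),
                   class = "contingency_table")
  stb <- fisher_enrichment(big)
  expect_equal(stb$method, "woolf-cc")
  expect_true(stb$ci[1] < 1 && stb$ci[2] > 0)

  degen <- structure(list(a = 0, b = 0, c = 3, d = 7, n = 10,
                          labels = c("A", "B", "u")),
                     class = "contingency_table")
  expect_true(fisher_enrichment(degen)$degenerate)
})

test_that("exact p equals the enumeration oracle on a sweep of tables", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
    d <- n - cuts[3]
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    ct <- structure(list(a = a, b = b, c = c, d = d, n = n,
                         labels = c("A", "B", "u")),
                    class = "contingency_table")
    expect_equal(fisher_enrichment(ct)$p, fisher_p_oracle(a, b, c, d),
                 tolerance = 1e-8)
  }
})

test_that("OR conditional MLE is 1 exactly when the table is balanced", {
  for (k in c(2, 5, 9)) {
    ct <- structure(list(a = k, b = k, c = k, d = k, n = 4 * k,
                         labels = c("A", "B", "u")),
                    class = "contingency_table")
    expect_equal(fisher_enrichment(ct)$or, 1, tolerance = 1e-6)
  }
})

test_that("direction concordance applies the exact sign test", {
  # 615 same-direction of 789 overlapping genes: proportion 77.9%
  tA <- make_deg_table(sprintf("g%03d", 1:789),
                       c(rep("up", 615), rep("down", 174)),
                       rep(TRUE, 789))
  tB <- make_deg_table(sprintf("g%03d", 1:789),
                       rep("up", 789), rep(TRUE, 789))
  cc <- direction_concordance(tA, tB)
  expect_equal(cc$n_overlap, 789L)
  expect_equal(round(cc$proportion, 3), 0.779)
  expect_lt(cc$p, 2.2e-16)

  # 5 of 10 concordant: two-sided p = 1
  tA2 <- make_deg_table(sprintf("g%02d", 1:10),
                        c(rep("up", 5), rep("down", 5)), rep(TRUE, 10))
  tB2 <- make_deg_table(sprintf("g%02d", 1:10), rep("up", 10),
                        rep(TRUE, 10))
  expect_equal(direction_concordance(tA2, tB2)$p, 1.0)

  # all concordant with n = 3: p = 2 * 0.5^3
  tA3 <- make_deg_table(c("a", "b", "c"), rep("up", 3), rep(TRUE, 3))
  expect_equal(direction_concordance(tA3, tA3)$p, 0.25)

  # symmetric in its arguments
  sw <- direction_concordance(tB, tA)
  expect_equal(sw$proportion, cc$proportion)

  # empty overlap is flagged, not an error
  tC <- make_deg_table("zzz", "up", TRUE)
  expect_true(direction_concordance(tA, tC)$degenerate)
})

test_that("region ratio table reports rounded overlap proportions", {
  region <- make_deg_table(sprintf("r%04d", 1:620),
                           rep(c("up", "down"), length.out = 620),
                           rep(TRUE, 620))
  blood211 <- make_deg_table(sprintf("r%04d", 1:211), rep("up", 211),
                             rep(TRUE, 211))
  blood278 <- make_deg_table(sprintf("r%04d", 1:278), rep("down", 278),
                             rep(TRUE, 278))
  out <- overlap_ratio_table(list(PFC = region), blood211)
  expect_equal(out$overlap_all, 211L)
  expect_equal(out$ratio, 0.34)
  out2 <- overlap_ratio_table(list(PFC = region), blood278)
  expect_equal(out2$ratio, 0.45)

  none <- make_deg_table("x1", "up", TRUE)
  out3 <- overlap_ratio_table(list(PFC = region), none)
  expect_equal(out3$ratio, 0)

  # rows ordered by decreasing ratio
  half <- make_deg_table(sprintf("r%04d", 1:310), rep("up", 310),
                         rep(TRUE, 310))
  multi <- overlap_ratio_table(list(low = region, high = region),
                               blood211)
  expect_true(all(diff(multi$ratio) <= 0))
})

test_that("trait association flags high-correlation genes and finds planted signal", {
  u <- sprintf("g%04d", 1:100)
  corrs <- stats::setNames(rep(0.2, 100), u)
  res <- trait_association(corrs, u[1:10], u)
  expect_true(res$degenerate)
  expect_error(trait_association(stats::setNames(1.2, "g1"), "g1", "g1"),
               "\\[-1, 1\\]")

  hits <- vapply(1:20, function(s) {
    set.seed(s)
    u <- sprintf("g%05d", 1:5000)
    deg <- u[1:500]
    pr <- ifelse(u %in% deg, 0.3, 0.1)
    corrs <- stats::setNames(ifelse(runif(5000) < pr, 0.6, 0.1), u)
    st <- trait_association(corrs, deg, u, threshold = 0.5)
    st$or > 1 && st$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("overrepresentation matches the hypergeometric oracle", {
  u <- sprintf("g%03d", 1:100)
  deg <- u[1:20]
  sets <- structure(list(S1 = u[13:22], S2 = u[90:99]),
                    class = "gene_set_collection")
  res <- ora(deg, u, sets)
  # N=100, m=10, n=20: S1 has k=8 hits (g013..g020)
  k <- res$hits[res$set == "S1"]
  expect_equal(k, 8L)
  oracle <- sum(dhyper(8:10, 10, 90, 20))
  expect_equal(res$p[res$set == "S1"], oracle, tolerance = 1e-12)
  expect_equal(res$ratio[res$set == "S1"], "8/10")
  # k = 0 gives p = 1
  expect_equal(res$p[res$set == "S2"], 1)
  expect_equal(sprintf("%d/%d", 21L, 43L), "21/43")

  # BH flags do not depend on set ordering
  res_rev <- ora(deg, u, structure(rev(unclass(sets)),
                                   class = "gene_set_collection"))
  expect_equal(res_rev$BH.pval[res_rev$set == "S1"],
               res$BH.pval[res$set == "S1"])

  empty_set <- structure(list(S1 = u[1:5], S0 = c("zz1", "zz2")),
                         class = "gene_set_collection")
  expect_warning(out <- ora(deg, u, empty_set), "skipped")
  expect_false("S0" %in% out$set)
  expect_error(ora(c(deg, "not_in_u"), u, sets), "outside the universe")
})

test_that("overlap-list generator round-trips through the enrichment stage", {
  ors <- numeric(10); conc <- numeric(10)
  for (s in 1:10) {
    ol <- generate_overlap_lists(20000, 4000, 6000, 3, 0.75, seed = s)
    ct <- build_contingency(ol$listA$feature_id, ol$listB$feature_id,
                            ol$universe)
    ors[s] <- fisher_enrichment(ct)$or
    ov <- merge(ol$listA, ol$listB, by = "feature_id")
    conc[s] <- mean(ov$direction.x == ov$direction.y)
  }
  expect_true(all(abs(ors - 3) / 3 < 0.2))
  expect_true(all(abs(conc - 0.75) < 0.05))
})
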