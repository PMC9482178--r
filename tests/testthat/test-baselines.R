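test_that("traditional filters match an enumeration oracle on a sparse fixture", {
  tab <- random_count_table(12, 8, seed = 1, lambda = 2)
  cnt <- counts(tab)
  ra <- sweep(cnt, 1, rowSums(cnt), "/")

  r1 <- filterByRelAbund(tab, 0.2)
  expect_setequal(r1$retained, colnames(cnt)[apply(ra, 2, max) > 0.2])

  r2 <- filterByCounts(tab, minReads = 3, minSamples = 4)
  expect_setequal(r2$retained, colnames(cnt)[colSums(cnt >= 3) >= 4])

  r3 <- filterByPrevalence(tab, minSamples = 6)
  expect_setequal(r3$retained, colnames(cnt)[colSums(cnt > 0) > 6])

  expect_equal(r1$n_preserved + r1$n_removed, 8)
})

test_that("filters are idempotent and anti-monotone in their thresholds", {
  tab <- simulateCommunity(communitySpec(seed = 2))
  for (fr in list(filterByRelAbund(tab, 0.01), filterByCounts(tab),
                  filterByPrevalence(tab), filterByDepthAndCounts(tab))) {
    sub <- tab[, fr$retained]
    again <- switch(substr(fr$method, 1, 4),
                    "rel_" = filterByRelAbund(sub, 0.01),
                    "read" = filterByCounts(sub),
                    "prev" = filterByPrevalence(sub),
                    filterByDepthAndCounts(sub))
    expect_setequal(again$retained, fr$retained)
  }
  kept_by_th <- vapply(c(0.001, 0.01, 0.05, 0.2),
                       function(t) filterByRelAbund(tab, t)$n_preserved,
                       numeric(1))
  expect_true(all(diff(kept_by_th) <= 0))
  expect_lte(filterByCounts(tab, 10, 5)$n_preserved,
             filterByCounts(tab, 5, 3)$n_preserved)
})

test_that("contamination bookkeeping agrees with generator labels", {
  tab <- simulateCommunity(communitySpec(seed = 3))
  lab <- attr(tab, "labels")
  r <- filterByCounts(tab, labels = lab)
  contam <- names(lab)[lab == "contaminant"]
  expect_equal(r$percent_contamination_preserved,
               100 * sum(r$retained %in% contam) / length(contam))
})

test_that("ROC analysis handles perfect, null and labeled-community cases", {
  sep <- diag(1, 6)
  sep[1, 2] <- sep[2, 1] <- sep[2, 3] <- sep[3, 2] <- 0.8
  dimnames(sep) <- list(letters[1:6], letters[1:6])
  lab <- c(a = "true", b = "true", c = "true", d = "contaminant",
           e = "contaminant", f = "contaminant")
  expect_equal(rocAnalysis(sep, lab)$auc, 1)

  flat <- matrix(0.5, 6, 6); diag(flat) <- 1
  dimnames(flat) <- dimnames(sep)
  expect_equal(rocAnalysis(flat, lab)$auc, 0.5)

  expect_error(rocAnalysis(sep, setNames(rep("true", 6), letters[1:6])),
               "single class")

  # trapezoid AUC equals the pairwise-concordance (Mann-Whitney) oracle
  tab <- simulateCommunity(communitySpec(rho = 0.7, seed = 4))
  labs <- attr(tab, "labels")
  v <- adjacency(adjustedMI(tab))
  roc <- rocAnalysis(v, labs)
  score <- apply(v - diag(diag(v)), 1, max)
  ts <- score[labs == "true"]; cs <- score[labs == "contaminant"]
  conc <- mean(outer(ts, cs, ">") + 0.5 * outer(ts, cs, "=="))
  expect_equal(roc$auc, conc, tolerance = 1e-10)

  # curve endpoints
  expect_equal(unlist(roc$points[roc$points$tau == 0, c("fpf", "tpf")]),
               c(fpf = 1, tpf = 1))
  expect_equal(unname(unlist(roc$points[which.max(roc$points$tau),
                                        c("fpf", "tpf")])), c(0, 0))
})

test_that("comparison report covers requested methods with consistent counts", {
  tab <- simulateCommunity(communitySpec(seed = 5))
  lab <- attr(tab, "labels")
  single <- comparisonReport(tab, lab, methods = "counts")
  expect_equal(nrow(single$report), 1)

  rep <- comparisonReport(tab, lab)
  expect_equal(nrow(rep$report), 7)  # 3 rel-abund + 3 others + MI
  expect_true(all(rep$report$n_preserved + rep$report$n_removed == 46))
  mi_row <- rep$report[rep$report$method == "MI-network", ]
  expect_equal(mi_row$percent_contamination_preserved,
               100 * sum(rep$retained[["MI-network"]] %in%
                           names(lab)[lab == "contaminant"]) / 39)
})
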