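test_that("weighted degrees are off-diagonal row sums with stable ordering", {
  w <- diag(1, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- 0.1
  dimnames(w) <- list(c("a", "b", "c"), c("a", "b", "c"))
  d <- weightedDegrees(w)
  expect_equal(d$d, c(a = 0.7, b = 0.6, c = 0.3))
  expect_identical(d$ordering, c("c", "b", "a"))

  expect_equal(unname(weightedDegrees(diag(1, 4))$d), rep(0, 4))

  v <- random_adjacency(10, seed = 1)
  expect_equal(weightedDegrees(v)$d, rowSums(v) - 1)

  # ties broken lexicographically by taxon ID
  tied <- diag(1, 3)
  tied[upper.tri(tied)] <- tied[lower.tri(tied)] <- 0.2
  dimnames(tied) <- list(c("z", "m", "a"), c("z", "m", "a"))
  expect_identical(weightedDegrees(tied)$ordering, c("a", "m", "z"))
})

test_that("quantile removal follows the documented type-7 convention", {
  v <- random_adjacency(8, seed = 2)
  r0 <- removeBelowQuantile(v, q = 0)
  expect_identical(r0$removed, character(0))
  expect_equal(r0$reduced, v)

  # 10 distinct degrees: the median cut removes exactly the 5 lowest
  w <- diag(1, 10)
  for (j in 2:10) w[1, j] <- w[j, 1] <- (j - 1) / 20
  for (j in 3:10) w[2, j] <- w[j, 2] <- 0.01 * j
  dimnames(w) <- list(paste0("t", 1:10), paste0("t", 1:10))
  d <- weightedDegrees(w)
  expect_length(unique(d$d), 10)
  r <- removeBelowQuantile(w, d, 0.5)
  expect_identical(sort(r$removed), sort(d$ordering[1:5]))

  tied <- matrix(0.3, 4, 4); diag(tied) <- 1
  dimnames(tied) <- list(letters[1:4], letters[1:4])
  for (q in c(0, 0.3, 0.9))
    expect_length(removeBelowQuantile(tied, q = q)$removed, 0)

  expect_error(removeBelowQuantile(v, q = 1), "\\[0, 1\\)")
})

test_that("information loss matches hand computation and endpoints", {
  v <- random_adjacency(5, seed = 3)
  expect_equal(informationLoss(v, v), 0)
  expect_equal(informationLoss(v, v[0, 0]), 1)

  w <- diag(1, 3)
  w[1, 2] <- w[2, 1] <- 0.4
  w[1, 3] <- w[3, 1] <- 0.6
  w[2, 3] <- w[3, 2] <- 0.8
  red <- w[2:3, 2:3]
  expect_equal(informationLoss(w, red),
               1 - (2 + 2 * 0.8^2) / (3 + 2 * (0.4^2 + 0.6^2 + 0.8^2)))
})

test_that("loss profile is monotone and matches closed forms", {
  # identity matrix: only diagonal mass, Lambda = 1 - (m - r)/m
  m <- 12
  v <- diag(1, m)
  dimnames(v) <- list(paste0("t", 1:m), paste0("t", 1:m))
  lp <- lossTable(lossProfile(v))
  expect_equal(lp$lambda, 1 - (m - lp$n_removed) / m)

  # equal off-diagonal weights: closed form in the retained size
  w <- matrix(0.3, 8, 8); diag(w) <- 1
  dimnames(w) <- list(paste0("t", 1:8), paste0("t", 1:8))
  prof <- lossProfile(w, grid = c(0.1, 0.5, 0.9))
  ret <- lengths(retainedSets(prof))
  cf <- function(mp, m, wt) 1 - (mp + mp * (mp - 1) * wt^2) /
    (m + m * (m - 1) * wt^2)
  expect_equal(lossTable(prof)$lambda, cf(ret, 8, 0.3))

  tab <- simulateCommunity(communitySpec(seed = 5))
  lpm <- lossTable(lossProfile(adjustedMI(tab)))
  expect_true(all(diff(lpm$lambda) >= -1e-12))
  expect_true(all(diff(lpm$n_removed) >= 0))
})

test_that("loss depends only on the retained set, not removal order", {
  v <- random_adjacency(9, seed = 4)
  keep <- c("T2", "T5", "T7", "T9")
  l1 <- informationLoss(v, v[keep, keep])
  l2 <- informationLoss(v, v[rev(keep), rev(keep)])
  expect_equal(l1, l2)
})

test_that("one-at-a-time profile spikes when the first true taxon is removed", {
  tab <- simulateCommunity(communitySpec(seed = 3))
  lab <- attr(tab, "labels")
  prof <- lossTable(lossProfile(adjustedMI(tab), oneAtATime = TRUE))
  expect_equal(prof$lambda[nrow(prof)], 1)
  expect_true(all(diff(prof$lambda) >= -1e-12))
  first_true <- which(lab[prof$taxon] == "true")[1]
  expect_gt(prof$delta[first_true], max(prof$delta[seq_len(first_true - 1)]))
})
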