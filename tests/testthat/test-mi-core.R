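test_that("discretization covers the documented cases", {
  b <- discretize(c(5, 5, 5, 5))
  expect_identical(unique(as.integer(b)), 1L)
  expect_equal(attr(b, "p"), 1)

  b2 <- discretize(c(0, 0, 10, 10), discretizationScheme(bins = 2))
  expect_identical(as.integer(b2), c(1L, 1L, 2L, 2L))
  expect_equal(attr(b2, "p"), c(0.5, 0.5))

  set.seed(42)
  x <- sample(0:9, 100, replace = TRUE)
  b3 <- discretize(x, discretizationScheme(bins = 10))
  # equal-width bins over 0..9 put each value in its own bin: tally oracle
  expect_equal(attr(b3, "p") * 100, as.numeric(table(factor(x, 0:9))))

  # equal-frequency collapses a constant vector to one bin, never errors
  b4 <- discretize(rep(3, 10), discretizationScheme("equal_frequency", 4))
  expect_identical(unique(as.integer(b4)), 1L)

  for (sch in list(discretizationScheme(), discretizationScheme("equal_frequency"))) {
    b5 <- discretize(rpois(50, 4), sch)
    expect_true(all(diff(attr(b5, "edges")) > 0))
    expect_equal(sum(attr(b5, "p")), 1)
  }
  expect_error(discretize(numeric(0)), ">= 2")
})

test_that("Sturges and sqrt bin rules follow their formulas", {
  s <- discretizationScheme()
  expect_identical(MIFilter:::.n_bins(s, 240), as.integer(ceiling(log2(240)) + 1))
  expect_identical(MIFilter:::.n_bins(discretizationScheme(bins = "sqrt"), 100), 10L)
})

test_that("entropy, joint entropy and MI match closed forms and oracles", {
  expect_equal(entropy(rep(1, 10)), 0)
  expect_equal(entropy(rep(1:2, 5)), log(2))
  # p = (.5, .25, .25) by direct summation
  x <- c(1, 1, 2, 3)
  expect_equal(entropy(x), -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(entropy(x), oracle_entropy(x))

  y <- c(1, 2, 1, 2)
  expect_equal(jointEntropy(x, x), entropy(x))
  g <- expand.grid(1:2, 1:2)
  expect_equal(jointEntropy(g[[1]], g[[2]]), log(4))
  expect_equal(jointEntropy(x, y), oracle_joint_entropy(x, y))
  expect_error(jointEntropy(x, y[1:3]), "equal length")

  expect_equal(mutualInfo(g[[1]], g[[2]]), 0)
  expect_equal(mutualInfo(x, x), entropy(x))
  expect_equal(mutualInfo(x, y), oracle_mi(x, y))
})

test_that("adjusted MI matches the brute-force oracle on random tables", {
  for (s in 1:30) {
    n <- sample(5:50, 1)
    m <- sample(2:6, 1)
    tab <- random_count_table(n, m, seed = 100 + s)
    scheme <- if (s %% 2) discretizationScheme(bins = sample(2:5, 1)) else
      discretizationScheme("equal_frequency", sample(2:5, 1))
    a <- adjustedMI(tab, scheme)
    expect_equal(adjacency(a), oracle_adjusted_mi(counts(tab), scheme),
                 tolerance = 1e-12)
    # entropy / joint-entropy components agree with the summation oracle
    labs <- lapply(seq_len(m), function(j) discretize(counts(tab)[, j], scheme))
    expect_equal(unname(a@entropies), vapply(labs, oracle_entropy, numeric(1)),
                 tolerance = 1e-12)
    expect_equal(a@jointEntropies[1, m],
                 oracle_joint_entropy(labs[[1]], labs[[m]]), tolerance = 1e-12)
  }
})

test_that("degenerate taxa share no information", {
  cnt <- cbind(A = rep(4, 20), B = rep(7, 20), C = rpois(20, 5))
  a <- adjacency(adjustedMI(MICountTable(cnt)))
  expect_equal(a[1, 2], 0)  # both constant: joint entropy 0
  expect_equal(a[1, 3], 0)  # zero-variance row is 0 off-diagonal
  expect_equal(diag(a), c(A = 1, B = 1, C = 1))
})

test_that("identical columns give adjusted MI 1; independent columns near 0", {
  x <- rpois(100, 10)
  a <- adjacency(adjustedMI(MICountTable(cbind(A = x, B = x))))
  expect_equal(a[1, 2], 1)
  set.seed(7)
  big <- MICountTable(cbind(A = rpois(1000, 10), B = rpois(1000, 10)))
  expect_lte(adjacency(adjustedMI(big))[1, 2], 0.05)
})

test_that("matrix is invariant to sample order and consistent under taxon order", {
  tab <- random_count_table(30, 5, seed = 9)
  a <- adjacency(adjustedMI(tab))
  set.seed(1)
  perm <- sample(nrow(counts(tab)))
  a_s <- adjacency(adjustedMI(MICountTable(counts(tab)[perm, ])))
  expect_equal(a_s, a)
  tperm <- c(3, 1, 5, 2, 4)
  a_t <- adjacency(adjustedMI(MICountTable(counts(tab)[, tperm])))
  expect_equal(a_t, a[tperm, tperm])
})
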