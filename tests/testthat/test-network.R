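test_that("hard thresholding follows the inclusive signum rule", {
  v <- random_adjacency(6, seed = 1)
  net0 <- hardThreshold(v, 0)
  expect_true(all(degrees(net0) == 5L))

  w <- diag(1, 3)
  w[1, 2] <- w[2, 1] <- 0.3
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.45
  dimnames(w) <- list(letters[1:3], letters[1:3])
  net <- hardThreshold(w, 0.45)  # boundary value is kept
  expect_equal(unname(degrees(net)), c(1L, 1L, 2L))
  expect_error(hardThreshold(w, 1.2), "tau")
})

test_that("edges are monotone in tau and degrees exclude the diagonal", {
  v <- random_adjacency(10, seed = 2)
  grid <- seq(0, 1, by = 0.1)
  edges <- sapply(grid, function(t) sum(adjacency(hardThreshold(v, t))) - 10)
  expect_true(all(diff(edges) <= 0))
  kbar <- sapply(grid, function(t) mean(degrees(hardThreshold(v, t))))
  expect_true(all(diff(kbar) <= 0))
  expect_equal(max(degrees(hardThreshold(v, 1.0001 - 1e-4))), 0L)
})

test_that("degree distribution matches hand counts and a tally oracle", {
  cm <- matrix(1, 4, 4); dimnames(cm) <- list(letters[1:4], letters[1:4])
  expect_equal(degreeDistribution(hardThreshold(cm, 0.5)),
               data.frame(k = 3L, p = 1))

  star <- diag(1, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.9
  dimnames(star) <- list(letters[1:5], letters[1:5])
  expect_equal(degreeDistribution(hardThreshold(star, 0.5)),
               data.frame(k = c(1L, 4L), p = c(0.8, 0.2)))

  v <- random_adjacency(12, seed = 3)
  net <- hardThreshold(v, 0.5)
  dd <- degreeDistribution(net)
  expect_equal(sum(dd$p), 1)
  deg <- colSums(adjacency(net)) - 1  # independent tally
  for (i in seq_len(nrow(dd)))
    expect_equal(dd$p[i], mean(deg == dd$k[i]))
})

test_that("power-law fit recovers exact and noisy log-linear data", {
  kk <- c(1, 2, 4, 8)
  pp <- kk^-2 / sum(kk^-2)
  f <- fitPowerLaw(data.frame(k = kk, p = pp))
  expect_equal(f$gamma, 2)
  expect_equal(f$r_squared, 1)

  f2 <- fitPowerLaw(data.frame(k = c(2, 5), p = c(0.6, 0.4)))
  expect_equal(f2$r_squared, 1)  # two points always fit exactly
  expect_identical(f2$n_points, 2L)

  f1 <- fitPowerLaw(data.frame(k = c(0, 3), p = c(0.5, 0.5)))
  expect_false(f1$defined)  # k = 0 excluded leaves a single point

  set.seed(11)
  kk <- 1:8
  pp <- kk^-1.7 * exp(rnorm(8, sd = 0.1))
  pp <- pp / sum(pp)
  f3 <- fitPowerLaw(data.frame(k = kk, p = pp))
  expect_lt(abs(f3$gamma - 1.7), 0.3)
  # independent least-squares computation
  X <- log(kk); Y <- log(pp)
  slope <- sum((X - mean(X)) * (Y - mean(Y))) / sum((X - mean(X))^2)
  expect_equal(f3$slope, slope)
  expect_equal(f3$r_squared, cor(X, Y)^2)
})

test_that("threshold scan selects max R-squared with mean-k tie-break", {
  v <- random_adjacency(8, seed = 4)
  one <- scanThresholds(v, grid = 0.4)
  expect_equal(selectedTau(one), 0.4)

  # star with a weak extra leaf: both thresholds give exact 2-point fits
  # (R^2 = 1); the tie must go to the denser network
  star <- diag(1, 6)
  star[1, 2:5] <- star[2:5, 1] <- 0.9
  star[1, 6] <- star[6, 1] <- 0.4
  dimnames(star) <- list(letters[1:6], letters[1:6])
  sc <- scanThresholds(star, grid = c(0.3, 0.6))
  tab <- scanTable(sc)
  expect_equal(tab$r_squared, c(1, 1))
  expect_gt(tab$mean_k[1], tab$mean_k[2])
  expect_equal(selectedTau(sc), 0.3)

  # selection rule re-derived independently from the scan table
  v2 <- random_adjacency(15, seed = 5)
  sc2 <- scanThresholds(v2, grid = seq(0.05, 0.95, 0.05))
  t2 <- scanTable(sc2)
  ok <- !is.na(t2$r_squared)
  best <- max(t2$r_squared[ok])
  cand <- t2[ok & abs(t2$r_squared - best) < 1e-12, ]
  expect_equal(selectedTau(sc2), cand$tau[which.max(cand$mean_k)])

  expect_error(scanThresholds(diag(1, 3), grid = 0.5), "undefined")
})

test_that("isolated-node partition is exhaustive and disjoint", {
  cm <- matrix(1, 4, 4); dimnames(cm) <- list(letters[1:4], letters[1:4])
  p <- isolatedTaxa(hardThreshold(cm, 0.5))
  expect_identical(p$removed, character(0))

  v <- random_adjacency(6, seed = 6)
  expect_warning(p2 <- isolatedTaxa(hardThreshold(v, 1)), "isolated")
  expect_identical(sort(p2$removed), sort(colnames(v)))

  v3 <- random_adjacency(9, seed = 7)
  p3 <- isolatedTaxa(hardThreshold(v3, 0.6))
  expect_setequal(c(p3$kept, p3$removed), colnames(v3))
  expect_length(intersect(p3$kept, p3$removed), 0)
})

test_that("network export writes edge lists and GraphML", {
  v <- random_adjacency(5, seed = 8)
  a <- hardThreshold(v, 0.5)
  f <- tempfile(fileext = ".tsv")
  writeEdgeList(a, f)
  el <- read.delim(f)
  expect_identical(names(el), c("source", "target", "weight"))
  expect_equal(nrow(el), (sum(adjacency(a)) - 5) / 2)
  g <- tempfile(fileext = ".graphml")
  writeGraphML(a, g)
  expect_true(file.size(g) > 0)
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gorder(gr), 5)
})
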