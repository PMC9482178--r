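# RNG discipline: resampling functions restore the caller's RNG state when
# given an explicit seed, so results are reproducible from (seed, M|B, grid)
# without perturbing the session stream.
.save_rng <- function() {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) set.seed(NULL)
  get(".Random.seed", globalenv(), inherits = FALSE)
}
.restore_rng <- function(old) assign(".Random.seed", old, envir = globalenv())

.step_result <- function(method, qlo, qhi, r_lo, r_hi, statistic, n_resamples,
                         p_value, alpha, degenerate = FALSE) {
  structure(list(method = method, step = c(qlo, qhi), r_lo = r_lo,
                 r_hi = r_hi, statistic = statistic,
                 n_resamples = n_resamples, p_value = p_value, alpha = alpha,
                 reject = p_value < alpha, degenerate = degenerate),
            class = "StepTestResult")
}

#' @export
print.StepTestResult <- function(x, ...) {
  cat(sprintf("%s step test (%.2f, %.2f): removed %d -> %d\n", x$method,
              x$step[1], x$step[2], x$r_lo, x$r_hi))
  cat(sprintf("  statistic = %.4g, p = %.4g (%d resamples)%s\n", x$statistic,
              x$p_value, x$n_resamples,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Shared context: discretized labels, adjusted-MI matrix, weighted degrees.
.mi_ctx <- function(table, scheme) {
  cnt <- counts(table)
  dsc <- .discretize_table(cnt, scheme)
  v <- .adjusted_from_labels(dsc$labels, dsc$nlev, seq_len(ncol(cnt)))
  dimnames(v) <- list(colnames(cnt), colnames(cnt))
  list(cnt = cnt, labels = dsc$labels, nlev = dsc$nlev, v = v,
       d = weightedDegrees(v), total = sum(v^2))
}

# Losses of degree-ordered quantile removal for one adjacency matrix.
.grid_losses <- function(v, deg, grid, total = sum(v^2)) {
  cuts <- quantile(deg, probs = grid, type = 7, names = FALSE)
  vapply(cuts, function(ct) {
    keep <- deg >= ct
    1 - sum(v[keep, keep]^2) / total
  }, numeric(1))
}

# Permutation core. Null model: each taxon's abundance profile is permuted
# independently across samples, which preserves every marginal but destroys
# all inter-taxon association; the adjusted-MI matrix, weighted degrees and
# the entire degree-ordered quantile removal are recomputed on the permuted
# table. Under exchangeable (i.i.d.-taxon) data the permuted tables are
# distributed exactly like the observed one, so the p-values are uniform;
# on structured data the permuted matrices lack the true-taxon block, so a
# step that cuts into strongly connected taxa shows a far larger loss
# increment than any permutation. One permutation set serves every step of
# the grid.
.perm_scan <- function(ctx, grid, M, seed) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  lam_obs <- .grid_losses(ctx$v, ctx$d$d, grid, ctx$total)
  delta_obs <- diff(lam_obs)
  n_removed <- vapply(grid, function(q)
    length(removeBelowQuantile(ctx$v, ctx$d, q)$removed), integer(1))
  exceed <- integer(length(delta_obs))
  m <- ncol(ctx$labels)
  for (b in seq_len(M)) {
    lp <- apply(ctx$labels, 2, sample)
    vp <- .adjusted_from_labels(lp, ctx$nlev, seq_len(m))
    dp <- rowSums(vp) - 1
    lam_p <- .grid_losses(vp, dp, grid)
    exceed <- exceed + (diff(lam_p) >= delta_obs - 1e-15)
  }
  p <- (1 + exceed) / (M + 1)
  degen <- diff(n_removed) == 0L
  p[degen] <- 1
  list(lambda = lam_obs, delta = delta_obs, n_removed = n_removed, p = p,
       degenerate = degen)
}

.cov_norm2 <- function(x) sum(cov(x)^2)

# Bootstrap core (studentized difference-in-loss statistic). Columns are
# resampled with replacement from the pooled retained sets; because each
# resampled column is an exact copy of an original taxon, its bin labels are
# reused and the adjusted-MI matrix of the resample is recomputed from them.
.boot_core <- function(ctx, qlo, qhi, B, alpha, seed) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  ids <- colnames(ctx$v)
  lo <- removeBelowQuantile(ctx$v, ctx$d, qlo)
  hi <- removeBelowQuantile(ctx$v, ctx$d, qhi)
  idx_lo <- match(lo$retained, ids)
  idx_hi <- match(hi$retained, ids)
  m_lo <- length(idx_lo); m_hi <- length(idx_hi)
  if (m_lo < 2L || m_hi < 2L)
    stop("retained sets too small for the bootstrap test (need >= 2 taxa)")
  lam_lo <- 1 - sum(lo$reduced^2) / ctx$total
  lam_hi <- 1 - sum(hi$reduced^2) / ctx$total
  delta <- lam_hi - lam_lo
  n2_lo <- .cov_norm2(ctx$cnt[, idx_lo, drop = FALSE])
  n2_hi <- .cov_norm2(ctx$cnt[, idx_hi, drop = FALSE])
  denom <- sqrt(n2_hi / m_hi + n2_lo / m_lo)
  if (denom == 0)
    stop("both covariance norms are zero for the retained sets at q = ",
         qlo, " and q = ", qhi, "; the test statistic is undefined")
  t_obs <- delta / denom
  pool <- c(idx_lo, idx_hi)
  zi <- seq_len(m_lo); yi <- m_lo + seq_len(m_hi)
  t_star <- vapply(seq_len(B), function(b) {
    draw <- pool[sample.int(length(pool), length(pool), replace = TRUE)]
    a_n <- .adjusted_from_labels(ctx$labels, ctx$nlev, draw)
    norm_n <- sum(a_n^2)
    lam_z <- 1 - sum(a_n[zi, zi]^2) / norm_n
    lam_y <- 1 - sum(a_n[yi, yi]^2) / norm_n
    dz <- .cov_norm2(ctx$cnt[, draw[zi], drop = FALSE])
    dy <- .cov_norm2(ctx$cnt[, draw[yi], drop = FALSE])
    den_b <- sqrt(dy / m_hi + dz / m_lo)
    num <- lam_y - lam_z - delta
    if (den_b == 0) return(if (num == 0) 0 else sign(num) * Inf)
    num / den_b
  }, numeric(1))
  p <- (1 + sum(t_star >= t_obs - 1e-15)) / (B + 1)
  .step_result("bootstrap", qlo, qhi, length(lo$removed), length(hi$removed),
               t_obs, B, p, alpha, degenerate = m_lo == m_hi)
}

#' Permutation test for one quantile step
#'
#' Tests whether stepping the removal level from `qlo` to `qhi` incurs more
#' information loss than expected when taxa share no information. The
#' observed statistic is `Delta = Lambda(qhi) - Lambda(qlo)`. The null
#' distribution is built by independently permuting each taxon's profile
#' across samples (all marginals preserved, every association destroyed) and
#' rerunning the full computation — adjusted MI, weighted degrees,
#' degree-ordered quantile removal — on the permuted table. One-sided
#' p-value with add-one smoothing, `p = (1 + #(Delta* >= Delta)) / (M + 1)`,
#' so p ranges over `[1/(M+1), 1]`. A step with no taxa between the two
#' quantiles is degenerate and returns p = 1.
#'
#' @param table an [MICountTable-class] object.
#' @param qlo,qhi adjacent quantiles, `qlo < qhi`, each in [0, 1).
#' @param M number of permutations (default 500).
#' @param scheme a [discretizationScheme()].
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a `StepTestResult` list: method, step, removal counts, statistic,
#'   p_value, reject, degenerate.
#' @examples
#' tab <- simulateCommunity(communitySpec(nSamples = 80, seed = 1))
#' permStepTest(tab, 0.81, 0.86, M = 99, seed = 1)
#' @export
permStepTest <- function(table, qlo, qhi, M = 500,
                         scheme = discretizationScheme(), alpha = 0.05,
                         seed = NULL) {
  stopifnot(qlo < qhi, M >= 1)
  ctx <- .mi_ctx(table, scheme)
  sc <- .perm_scan(ctx, c(qlo, qhi), M, seed)
  .step_result("permutation", qlo, qhi, sc$n_removed[1L], sc$n_removed[2L],
               sc$delta[1L], M, sc$p[1L], alpha, degenerate = sc$degenerate[1L])
}

#' Bootstrap test for one quantile step
#'
#' Studentized bootstrap of the difference in information loss between two
#' removal levels. The observed statistic scales `Delta` by the Frobenius
#' norms of the covariance matrices of the retained count sub-tables; each
#' bootstrap replicate resamples columns with replacement from the pooled
#' retained sets, splits them into analogues of the two sets, recomputes
#' adjusted-MI matrices on the resampled columns, and centers the resampled
#' difference at the observed one. One-sided p-value with add-one smoothing.
#' The resampling pool is the retained column sets themselves, so the test
#' probes their exchangeability; it is conservative and is reported as a
#' companion to the permutation test.
#'
#' @param table an [MICountTable-class] object.
#' @param qlo,qhi adjacent quantiles, `qlo < qhi`, each in [0, 1).
#' @param B number of bootstrap resamples (default 500).
#' @param scheme a [discretizationScheme()].
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return a `StepTestResult` list (see [permStepTest()]).
#' @examples
#' tab <- simulateCommunity(communitySpec(nSamples = 60, seed = 1))
#' bootStepTest(tab, 0.81, 0.86, B = 49, seed = 1)
#' @export
bootStepTest <- function(table, qlo, qhi, B = 500,
                         scheme = discretizationScheme(), alpha = 0.05,
                         seed = NULL) {
  stopifnot(qlo < qhi, B >= 1)
  .boot_core(.mi_ctx(table, scheme), qlo, qhi, B, alpha, seed)
}

#' Scan all quantile steps and recommend a removal level
#'
#' Runs the permutation and/or bootstrap step test on every adjacent pair of
#' the quantile grid. The recommended removal level is the largest quantile
#' reached before the first significant step — i.e. taxa below it can be
#' removed without significant information loss. When both tests are run,
#' the recommendation follows the permutation test (whose null is exact
#' under exchangeable taxa) and the bootstrap column is reported alongside.
#'
#' @param table an [MICountTable-class] object.
#' @param scheme a [discretizationScheme()].
#' @param grid quantile grid; default 0.01 to 0.96 by 0.05.
#' @param tests `"both"`, `"permutation"`, or `"bootstrap"`.
#' @param M,B resamples per test (defaults 500 each).
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed; the bootstrap derives per-step seeds
#'   from it.
#' @return list with `results` (data.frame: step_lo, step_hi, r_lo, r_hi,
#'   delta, p_perm, p_boot, reject), `recommended` (quantile), plus the
#'   settings. If every step is degenerate the highest grid value is
#'   recommended with a warning.
#' @examples
#' tab <- simulateCommunity(communitySpec(nSamples = 80, seed = 1))
#' scanSteps(tab, tests = "permutation", M = 99, seed = 1)$recommended
#' @export
scanSteps <- function(table, scheme = discretizationScheme(),
                      grid = seq(0.01, 0.96, by = 0.05),
                      tests = c("both", "permutation", "bootstrap"),
                      M = 500, B = 500, alpha = 0.05, seed = NULL) {
  tests <- match.arg(tests)
  ctx <- .mi_ctx(table, scheme)
  nstep <- length(grid) - 1L
  if (nstep < 1L) stop("grid must contain at least two quantiles")
  p_perm <- p_boot <- rep(NA_real_, nstep)
  delta <- numeric(nstep)
  r_lo <- r_hi <- integer(nstep)
  degen <- logical(nstep)
  if (tests %in% c("both", "permutation")) {
    sc <- .perm_scan(ctx, grid, M, seed)
    p_perm <- sc$p
    delta <- sc$delta
    r_lo <- sc$n_removed[-length(grid)]
    r_hi <- sc$n_removed[-1L]
    degen <- sc$degenerate
  }
  if (tests %in% c("both", "bootstrap")) {
    for (k in seq_len(nstep)) {
      sk <- if (is.null(seed)) NULL else seed + k
      br <- .boot_core(ctx, grid[k], grid[k + 1L], B, alpha, sk)
      p_boot[k] <- br$p_value
      if (tests == "bootstrap") {
        r_lo[k] <- br$r_lo; r_hi[k] <- br$r_hi
        degen[k] <- br$r_lo == br$r_hi
        delta[k] <- br$statistic
      }
    }
  }
  p_decide <- if (tests == "bootstrap") p_boot else p_perm
  reject <- !is.na(p_decide) & p_decide < alpha & !degen
  first <- which(reject)[1L]
  if (is.na(first)) {
    recommended <- grid[length(grid)]
    if (all(degen))
      warning("all steps degenerate (uniform degrees); ",
              "recommending the highest grid value")
  } else {
    recommended <- grid[first]
  }
  list(results = data.frame(step_lo = grid[-length(grid)], step_hi = grid[-1L],
                            r_lo = r_lo, r_hi = r_hi, delta = delta,
                            p_perm = p_perm, p_boot = p_boot,
                            reject = reject),
       recommended = recommended, tests = tests, M = M, B = B, alpha = alpha,
       seed = seed)
}
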