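#' Specification of a simulated mock community
#'
#' Defines a mock-community count table: a small set of mutually correlated,
#' high-abundance true taxa plus many sparse, low-abundance, mutually
#' independent contaminant taxa. The defaults emulate a vaginal mock
#' community design: 240 samples, 7 true strains carrying ~99.8% of the
#' reads, 39 sporadic contaminants.
#'
#' True-taxon dependence is generated the way mock communities are actually
#' built: every sample realizes one of `nStates` prescribed mixtures. Each
#' true taxon's prescribed proportion across mixtures runs over a linear
#' dilution grid (including absence), so abundance levels of taxa sharing a
#' guild are co-determined by the sample's mixture identity. `rho` sets how
#' much of the log-abundance variance the design explains versus replicate
#' noise; at `rho = 0` the design vanishes and true taxa become exchangeable
#' with (dense, equal-abundance) contaminants. True taxa are split into
#' `nGuilds` groups driven by independent mixture assignments, so
#' between-guild edges are weak — giving the heterogeneous within-community
#' connectivity real tables show.
#'
#' @param nSamples number of samples (default 240).
#' @param nTrue number of true taxa (default 7).
#' @param nContam number of contaminant taxa (default 39).
#' @param rho fraction of true-taxon log-abundance variance explained by the
#'   mixture design, in [0, 1); default 0.99 (designed proportions span
#'   orders of magnitude while replicate noise is comparatively small).
#' @param gap mean log-abundance gap (nats) between true and contaminant
#'   taxa; default `log(1000)`, i.e. a thousand-fold abundance ratio.
#' @param depth sequencing depth per sample (multinomial size; default 1e4).
#' @param sparsity per-sample presence probability of each contaminant
#'   (default 0.3).
#' @param sigma replicate log-noise scale (default 1; true taxa receive
#'   `sigma * sqrt(1 - rho)`, contaminants `sigma`).
#' @param nStates number of prescribed mixtures per guild (default 8).
#' @param nGuilds number of independent true-taxon guilds (default 2,
#'   reduced automatically so every guild holds at least 2 taxa when
#'   possible).
#' @param seed integer seed; the whole table is reproducible from it.
#' @return a `CommunitySpec` list.
#' @examples
#' communitySpec(nSamples = 60, seed = 7)
#' @export
communitySpec <- function(nSamples = 240, nTrue = 7, nContam = 39, rho = 0.99,
                          gap = log(1000), depth = 1e4, sparsity = 0.3,
                          sigma = 1, nStates = 8, nGuilds = 2, seed = NULL) {
  if (nSamples < 2 || nTrue < 1 || nContam < 0)
    stop("infeasible community dimensions")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (depth < 1) stop("depth must be positive")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must lie in (0, 1]")
  if (nStates < 2) stop("nStates must be >= 2")
  nGuilds <- max(1L, min(as.integer(nGuilds), nTrue %/% 2L, nTrue))
  structure(list(nSamples = nSamples, nTrue = nTrue, nContam = nContam,
                 rho = rho, gap = gap, depth = depth, sparsity = sparsity,
                 sigma = sigma, nStates = nStates, nGuilds = nGuilds,
                 seed = seed),
            class = "CommunitySpec")
}

#' @export
print.CommunitySpec <- function(x, ...) {
  cat(sprintf(paste0("CommunitySpec: %d samples, %d true (%d guilds, ",
                     "%d mixtures) + %d contaminant taxa\n  rho = %g, ",
                     "gap = %.3g nats, depth = %g, sparsity = %g, ",
                     "seed = %s\n"),
              x$nSamples, x$nTrue, x$nGuilds, x$nStates, x$nContam, x$rho,
              x$gap, x$depth, x$sparsity,
              if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' Expected fraction of reads attributed to true taxa under a spec
#'
#' Closed form from the lognormal weights: the per-taxon scale factor
#' `exp(sigma^2 / 2)` is common to both groups and cancels.
#'
#' @param spec a [communitySpec()].
#' @return expected true-read fraction in (0, 1].
#' @export
expectedTrueShare <- function(spec) {
  w_true <- spec$nTrue * exp(spec$gap)
  w_con <- spec$nContam * spec$sparsity * exp(spec$sigma^2 / 2)
  w_true / (w_true + w_con)
}

#' Simulate a mock-community count table with known labels
#'
#' Every sample realizes one prescribed mixture per guild: guild taxa take
#' per-mixture proportions from a shuffled linear dilution grid (including
#' absence), blended toward a flat profile by `1 - rho` and normalized per
#' mixture to a fixed guild mass of `exp(gap)` per taxon; per-sample
#' lognormal replicate noise of scale `sigma * sqrt(1 - rho)` is applied on
#' top, so at `rho = 0` every true taxon is i.i.d. lognormal.
#' Contaminants draw independent lognormal weights gated by a per-sample
#' presence Bernoulli. Per-sample weights are normalized to proportions and
#' counts drawn multinomially at the spec's depth — giving the
#' compositional, overdispersed structure of 16S tables. All randomness
#' flows from the spec seed in a fixed stream order (per guild: mixture
#' grid, sample states, replicate noise; then contaminant presence gates,
#' contaminant noise, counts), so the same spec and seed give an identical
#' table.
#'
#' @param spec a [communitySpec()].
#' @return an [MICountTable-class] with attributes `labels` (named character,
#'   `"true"`/`"contaminant"`) and `spec`.
#' @examples
#' tab <- simulateCommunity(communitySpec(seed = 1))
#' table(attr(tab, "labels"))
#' @export
simulateCommunity <- function(spec = communitySpec()) {
  if (!is.null(spec$seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(spec$seed)
  }
  n <- spec$nSamples; mt <- spec$nTrue; mc <- spec$nContam
  sizes <- diff(round(seq(0, mt, length.out = spec$nGuilds + 1L)))
  dil <- seq(0, 1, length.out = spec$nStates)
  noise_sd <- spec$sigma * sqrt(1 - spec$rho)
  w <- NULL
  for (mb in sizes) {
    mix <- vapply(seq_len(mb), function(j) sample(dil), numeric(spec$nStates))
    mix <- spec$rho * mix + (1 - spec$rho)
    mix <- mix / pmax(rowSums(mix), 1e-12) * mb  # prescribed proportions
    state <- sample.int(spec$nStates, n, replace = TRUE)
    eps <- matrix(rnorm(n * mb, sd = noise_sd), n, mb)
    wb <- mix[state, , drop = FALSE] * exp(spec$gap + eps)
    w <- cbind(w, wb)
  }
  if (mc > 0) {
    present <- matrix(rbinom(n * mc, 1, spec$sparsity), n, mc)
    log_con <- matrix(rnorm(n * mc, sd = spec$sigma), n, mc)
    w <- cbind(w, present * exp(log_con))
  }
  cnt <- t(apply(w, 1, function(wi) {
    if (sum(wi) == 0) wi <- rep(1, length(wi))  # fully absent row guard
    rmultinom(1, size = spec$depth, prob = wi / sum(wi))[, 1]
  }))
  ids <- c(sprintf("TRUE_%02d", seq_len(mt)),
           if (mc > 0) sprintf("CONTAM_%02d", seq_len(mc)))
  tab <- MICountTable(cnt, sampleIDs = sprintf("S%03d", seq_len(n)),
                      taxonIDs = ids)
  labels <- stats::setNames(rep(c("true", "contaminant"), c(mt, mc)), ids)
  attr(tab, "labels") <- labels
  attr(tab, "spec") <- spec
  tab
}

#' Simulate a null table of i.i.d. taxa
#'
#' Every taxon is drawn independently from the same negative-binomial count
#' distribution, so there is no dependence structure: the exchangeable null
#' for type-I-error checks of the step tests.
#'
#' @param n,m numbers of samples and taxa (both >= 2).
#' @param seed optional integer seed.
#' @param mu,size negative-binomial mean and dispersion (defaults 20, 2 —
#'   overdispersed, 16S-like marginals).
#' @return an [MICountTable-class] object.
#' @examples
#' simulateNullTable(100, 10, seed = 1)
#' @export
simulateNullTable <- function(n, m, seed = NULL, mu = 20, size = 2) {
  if (n < 2 || m < 2) stop("n and m must both be >= 2")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  cnt <- matrix(rnbinom(n * m, mu = mu, size = size), n, m)
  MICountTable(cnt, sampleIDs = sprintf("S%03d", seq_len(n)),
               taxonIDs = sprintf("T%03d", seq_len(m)))
}
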