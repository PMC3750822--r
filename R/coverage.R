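## The T1 family: minimum number of reads per amplicon so that every allele
## of a genotype is represented by at least m reads with confidence gamma.
## Exact path: inclusion-exclusion over the alleles that fail to reach m
## reads under a multinomial; stochastic paths: multinomial simulation and
## resampling of observed reads.

#' Coverage-threshold configuration
#'
#' @param m minimum reads per allele (2 by default; the classical dropout
#'   definition).
#' @param gamma confidence level (0.999 by default).
#' @param nSims multinomial draws per candidate read count (10,000 by
#'   default; resampling conventionally uses 1,000).
#' @param nReps replications of the whole estimation; T1 is their median.
#' @param seed integer seed for the simulation paths.
#' @return validated list of class `coverage_config`.
#' @export
coverageConfig <- function(m = 2L, gamma = 0.999, nSims = 10000L,
                           nReps = 100L, seed = 1L) {
  stopifnot(m >= 1, gamma > 0, gamma < 1, nSims >= 1, nReps >= 1)
  structure(list(m = as.integer(m), gamma = gamma, nSims = as.integer(nSims),
                 nReps = as.integer(nReps), seed = as.integer(seed)),
            class = "coverage_config")
}

#' Exact probability that every allele reaches at least m reads
#'
#' Computes \eqn{P(\min_a X_a \ge m)} for
#' \eqn{X \sim Multinomial(n, p)} exactly, by inclusion-exclusion over the
#' subsets of alleles whose count stays below `m`. For a subset S the joint
#' probability that all its counts are below m is accumulated through the
#' coefficients of \eqn{\prod_{i \in S} \sum_{c<m} (p_i x)^c / c!}, which
#' keeps the cost at \eqn{O(2^k)} rather than \eqn{O((m+1)^k)}. Exactness is
#' guaranteed up to `k = 15` alleles; larger genotypes should use the
#' simulation path.
#'
#' @param n number of reads drawn.
#' @param probs positive allele probabilities summing to 1.
#' @param m minimum reads per allele.
#' @return the probability, clamped to [0, 1].
#' @examples
#' probAllAtLeast(4, c(0.5, 0.5), m = 2)   # 0.375
#' @export
probAllAtLeast <- function(n, probs, m = 2L) {
  k <- length(probs)
  if (any(probs <= 0)) stop("probs must be positive")
  if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1")
  if (k > 15L) stop("exact kernel limited to k <= 15 alleles; use t1Simulated")
  if (n < k * m) return(0)
  total <- 0
  lgn <- lgamma(n + 1)
  ## per-allele polynomial sum_{c<m} (p x)^c / c!
  polys <- lapply(probs, function(p) (p^(0:(m - 1L))) / factorial(0:(m - 1L)))
  for (mask in 0:(2^k - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) != 0L)
    sz <- length(members)
    q <- 1 - sum(probs[members])
    coef <- 1
    for (i in members) {
      old <- coef
      coef <- numeric(length(old) + m - 1L)
      for (c in 0:(m - 1L))
        coef[(c + 1):(c + length(old))] <-
          coef[(c + 1):(c + length(old))] + old * polys[[i]][c + 1L]
    }
    s <- seq_along(coef) - 1L
    ## term_s = coef_s * n!/(n-s)! * q^(n-s); log-space for over/underflow
    logq <- if (q > 0) log(q) else -Inf
    lterm <- ifelse(coef > 0, log(coef), -Inf) +
      (lgn - lgamma(n - s + 1)) +
      ifelse(n - s == 0, 0, (n - s) * logq)
    lterm[s > n] <- -Inf
    total <- total + (-1)^sz * sum(exp(lterm))
  }
  min(max(total, 0), 1)
}

.newThreshold <- function(method, k, T1, perRep, config) {
  new("CoverageThreshold", method = method, k = as.integer(k),
      T1 = as.integer(T1), perReplicate = as.integer(perRep),
      config = unclass(config))
}

## smallest n with pred(n) TRUE, assuming monotonicity: doubling then binary.
.monotoneSearch <- function(pred, lo) {
  hi <- max(lo, 1L)
  while (!pred(hi)) {
    lo <- hi + 1L
    hi <- hi * 2L
    if (hi > 1e7) stop("threshold search exceeded 1e7 reads")
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (pred(mid)) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Analytic T1 under equal amplification efficiencies
#'
#' Smallest read count n such that, under a multinomial with k equally likely
#' alleles, every allele receives at least m reads with probability at least
#' gamma; found by monotone (doubling + binary) search on the exact kernel.
#'
#' @param k number of alleles.
#' @param config a [coverageConfig()].
#' @return a [CoverageThreshold-class] with method `analytic_equal`.
#' @examples
#' t1Value(t1Analytic(2))   # 15
#' @export
t1Analytic <- function(k, config = coverageConfig()) {
  stopifnot(k >= 1)
  probs <- rep(1 / k, k)
  T1 <- .monotoneSearch(function(n) probAllAtLeast(n, probs, config$m) >= config$gamma,
                        lo = k * config$m)
  .newThreshold("analytic_equal", k, T1, integer(0), config)
}

## fraction of nSims multinomial draws of size n where all counts reach m
.simFraction <- function(n, probs, m, nSims) {
  draws <- rmultinom(nSims, n, probs)
  mean(colSums(draws >= m) == length(probs))
}

#' Simulation-based T1 (equal or unequal efficiencies)
#'
#' For one replication, finds the smallest n whose success fraction over
#' `nSims` multinomial draws reaches `gamma`; T1 is the median over `nReps`
#' replications. A pilot doubling search brackets the candidate range once so
#' that every replication binary-searches the same interval.
#'
#' @param probs allele probabilities (uniform for the equal-efficiency
#'   variant, normalised genotype efficiencies otherwise).
#' @param config a [coverageConfig()].
#' @param method method tag recorded in the result.
#' @return a [CoverageThreshold-class].
#' @export
t1Simulated <- function(probs, config = coverageConfig(),
                        method = c("simulated_equal", "simulated_var_eff",
                                   "resampled", "min_eff_grid")) {
  method <- match.arg(method)
  if (any(probs <= 0)) stop("degenerate allele probabilities (must be > 0)")
  probs <- probs / sum(probs)
  k <- length(probs)
  m <- config$m
  rng <- .seededRNG(config$seed)
  vals <- rng$run(function() {
    ## pilot bracket, shared by all replications
    lo <- k * m
    hi <- max(lo, 1L)
    while (.simFraction(hi, probs, m, config$nSims) < config$gamma) {
      lo <- hi + 1L
      hi <- hi * 2L
      if (hi > 1e7) stop("threshold search exceeded 1e7 reads")
    }
    pilotLo <- k * m
    pilotHi <- hi
    vapply(seq_len(config$nReps), function(r) {
      lo <- pilotLo
      hi <- pilotHi
      while (.simFraction(hi, probs, m, config$nSims) < config$gamma) hi <- hi * 2L
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (.simFraction(mid, probs, m, config$nSims) >= config$gamma)
          hi <- mid else lo <- mid + 1L
      }
      hi
    }, numeric(1))
  })
  T1 <- as.integer(round(median(vals)))
  .newThreshold(method, k, T1, vals, config)
}

#' Resampling-based T1 for one amplicon
#'
#' Resamples n reads with replacement from the amplicon's allele-labelled
#' reads (equivalently: multinomial draws at the observed allele frequencies)
#' and finds the smallest n at which all alleles of the genotype reach m
#' reads in at least `gamma` of the simulations; median over `nReps`
#' replications. If an allele of the genotype has zero reads in this amplicon
#' the threshold is undefined (dropout evidence) and T1 is NA.
#'
#' @param counts named integer vector: observed reads per called allele in
#'   one amplicon.
#' @param config a [coverageConfig()]; the conventional resampling depth is
#'   `nSims = 1000`.
#' @return a [CoverageThreshold-class] with method `resampled`.
#' @export
t1Resampled <- function(counts, config = coverageConfig(nSims = 1000L)) {
  if (any(counts == 0L)) {
    res <- .newThreshold("resampled", length(counts), NA_integer_, integer(0), config)
    return(res)
  }
  t1Simulated(counts / sum(counts), config, method = "resampled")
}

#' Genotype-level resampled T1 over the two replicates
#'
#' Runs [t1Resampled()] on both amplicon replicates of one individual and
#' retains the maximal value (the conservative, a-posteriori per-genotype
#' requirement). Replicates with an absent allele yield NA and are reported.
#'
#' @param countsRep1,countsRep2 named per-allele read counts in each replicate
#'   (same allele set; zeros mark dropout).
#' @param config a [coverageConfig()].
#' @return list with `T1` (max over replicates, NA if both undefined),
#'   `perReplicate` (the two values) and `dropout` (alleles at zero reads).
#' @export
t1ResampledGenotype <- function(countsRep1, countsRep2,
                                config = coverageConfig(nSims = 1000L)) {
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  r1 <- t1Resampled(countsRep1, config)
  r2 <- t1Resampled(countsRep2, cfg2)
  vals <- c(rep1 = t1Value(r1), rep2 = t1Value(r2))
  T1 <- if (all(is.na(vals))) NA_integer_ else max(vals, na.rm = TRUE)
  dropout <- unique(c(names(countsRep1)[countsRep1 == 0L],
                      names(countsRep2)[countsRep2 == 0L]))
  list(T1 = T1, perReplicate = vals, dropout = dropout)
}

#' T1 grid over allele number and minimum amplification efficiency
#'
#' For each (k, e) with e in (0, 1], all alleles but one amplify at
#' efficiency 1 and the last at e, so the cell probabilities are proportional
#' to (1, ..., 1, e). The e = 1 column reduces to the equal-efficiency T1.
#' Cells use the exact kernel when k is within its bound, otherwise the
#' simulation path.
#'
#' @param kRange integer vector of allele numbers.
#' @param eRange numeric vector of minimum efficiencies in (0, 1].
#' @param config a [coverageConfig()].
#' @return data.frame with columns `k`, `min_efficiency`, `T1`, `method`.
#' @export
t1MinEfficiencyGrid <- function(kRange = 2:10,
                                eRange = seq(0.1, 1, by = 0.1),
                                config = coverageConfig()) {
  stopifnot(all(eRange > 0), all(eRange <= 1), all(kRange >= 1))
  rows <- list()
  for (k in kRange) {
    for (e in eRange) {
      probs <- c(rep(1, k - 1L), e)
      probs <- probs / sum(probs)
      if (k <= 15L) {
        T1 <- .monotoneSearch(function(n) probAllAtLeast(n, probs, config$m) >= config$gamma,
                              lo = k * config$m)
        method <- "exact"
      } else {
        T1 <- t1Value(t1Simulated(probs, config, method = "min_eff_grid"))
        method <- "simulated"
      }
      rows[[length(rows) + 1L]] <- data.frame(k = k, min_efficiency = e,
                                              T1 = T1, method = method)
    }
  }
  do.call(rbind, rows)
}
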