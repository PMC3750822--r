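## Multinomial maximum-likelihood estimation of per-allele relative
## amplification efficiencies. Each amplicon contributes a multinomial term:
## the observed allele read counts given cell probabilities proportional to
## the efficiencies of the alleles in that individual's genotype. The model
## assumes one efficiency per allele, shared across genotypes and PCRs.

#' Log-likelihood of amplicon read counts under given efficiencies
#'
#' For each amplicon with counts \eqn{c_a} over the alleles of its genotype,
#' adds \eqn{\log Multinomial(c \mid n = \sum c, p_a = e_a / \sum_b e_b)}
#' where the sum over \eqn{b} runs over the genotype. The value is invariant
#' to a common rescaling of all efficiencies.
#'
#' @param efficiencies named positive numeric vector.
#' @param observations list of named integer count vectors, one per amplicon
#'   (names are allele identifiers; only alleles of that genotype appear).
#' @return the summed log-likelihood (finite for positive efficiencies).
#' @examples
#' genotypeLogLik(c(a = 1, b = 1), list(c(a = 2, b = 1)))  # log(3/8)
#' @export
genotypeLogLik <- function(efficiencies, observations) {
  if (any(efficiencies <= 0) || any(!is.finite(efficiencies)))
    stop("efficiencies must be positive and finite")
  ll <- 0
  for (obs in observations) {
    e <- efficiencies[names(obs)]
    if (anyNA(e)) stop("observation names allele(s) without an efficiency: ",
                       paste(names(obs)[is.na(e)], collapse = ", "))
    n <- sum(obs)
    p <- e / sum(e)
    ll <- ll + lgamma(n + 1) - sum(lgamma(obs + 1)) + sum(obs * log(p))
  }
  unname(ll)
}

## negative log-likelihood and gradient in log-efficiency space for one
## connected component; theta excludes the pinned (first) allele.
.nllMaker <- function(observations, alleles) {
  q <- length(alleles)
  obsIdx <- lapply(observations, function(o) match(names(o), alleles))
  nll <- function(theta) {
    e <- exp(c(0, theta))
    val <- 0
    for (i in seq_along(observations)) {
      o <- observations[[i]]
      ei <- e[obsIdx[[i]]]
      val <- val - (sum(o * log(ei)) - sum(o) * log(sum(ei)))
    }
    val
  }
  grad <- function(theta) {
    e <- exp(c(0, theta))
    g <- numeric(q)
    for (i in seq_along(observations)) {
      o <- observations[[i]]
      idx <- obsIdx[[i]]
      ei <- e[idx]
      g[idx] <- g[idx] - (o - sum(o) * ei / sum(ei))
    }
    g[-1]
  }
  list(nll = nll, grad = grad)
}

## connected components of the allele co-occurrence graph (alleles linked when
## they appear in the same amplicon); plain BFS over an adjacency list.
.alleleComponents <- function(observations) {
  alleles <- unique(unlist(lapply(observations, names)))
  adj <- setNames(vector("list", length(alleles)), alleles)
  for (obs in observations) {
    nm <- names(obs)
    for (a in nm) adj[[a]] <- unique(c(adj[[a]], setdiff(nm, a)))
  }
  seen <- setNames(rep(FALSE, length(alleles)), alleles)
  comps <- list()
  for (a in alleles) {
    if (seen[a]) next
    queue <- a
    comp <- character(0)
    while (length(queue)) {
      x <- queue[1L]; queue <- queue[-1L]
      if (seen[x]) next
      seen[x] <- TRUE
      comp <- c(comp, x)
      queue <- c(queue, adj[[x]][!seen[adj[[x]]]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Estimate per-allele amplification efficiencies by maximum likelihood
#'
#' Maximises [genotypeLogLik()] over positive efficiencies, parameterised on
#' the log scale. The likelihood only identifies efficiency ratios within a
#' connected component of the genotype-sharing graph, so estimation runs per
#' component with one allele pinned to 1 during optimisation; cross-component
#' ratios are not comparable and the component structure is reported.
#' Optimisation uses BFGS with the analytic gradient and `nStarts` seeded
#' starting points (first start: all efficiencies equal), keeping the best
#' optimum. An allele observed in zero amplicons is dropped with a warning; a
#' single-allele component gets efficiency 1 by convention.
#'
#' @param observations list of named per-amplicon allele read count vectors,
#'   e.g. from [genotypeObservations()].
#' @param nStarts number of optimisation starts.
#' @param seed integer seed for the random restarts.
#' @return an [EfficiencySet-class] (standardised slot empty until
#'   [standardise()] is called).
#' @export
estimateEfficiencies <- function(observations, nStarts = 5L, seed = 1L) {
  observations <- lapply(observations, function(o) {
    o <- o[o > 0]
    if (length(o) == 0L) NULL else o
  })
  observations <- Filter(Negate(is.null), observations)
  if (length(observations) == 0L) stop("no usable observations")
  comps <- .alleleComponents(observations)
  rel <- numeric(0)
  conv <- TRUE
  rng <- .seededRNG(seed)
  for (comp in comps) {
    inComp <- vapply(observations, function(o) all(names(o) %in% comp), logical(1))
    obsC <- observations[inComp]
    if (length(comp) == 1L) {
      rel[comp] <- 1
      next
    }
    fns <- .nllMaker(obsC, comp)
    best <- NULL
    for (s in seq_len(nStarts)) {
      theta0 <- if (s == 1L) rep(0, length(comp) - 1L) else rng$norm(length(comp) - 1L, sd = 0.7)
      fit <- optim(theta0, fns$nll, fns$grad, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    gnorm <- sqrt(sum(fns$grad(best$par)^2))
    conv <- conv && (best$convergence == 0L || gnorm < 1e-6)
    e <- exp(c(0, best$par))
    names(e) <- comp
    rel[comp] <- e
  }
  ll <- genotypeLogLik(rel, observations)
  nAmp <- table(unlist(lapply(observations, names)))
  nAmplicons <- setNames(as.integer(nAmp), names(nAmp))[names(rel)]
  names(nAmplicons) <- names(rel)
  new("EfficiencySet", relative = rel, standardised = numeric(0),
      reference = NA_character_, logLik = ll, converged = conv,
      nAmplicons = nAmplicons, components = comps)
}

#' Standardise efficiencies against a reference allele
#'
#' Divides every relative efficiency by the reference allele's, so the
#' reference gets exactly 1. Alleles with standardised efficiency >= 2 are
#' flagged as candidate duplicated (or homozygous) alleles.
#'
#' @param effSet an [EfficiencySet-class].
#' @param reference name of the reference allele.
#' @return the [EfficiencySet-class] with the `standardised` slot filled; the
#'   duplication candidates are available via `attr(standardisedEfficiency(x),
#'   "duplicated_candidates")`.
#' @export
standardise <- function(effSet, reference) {
  rel <- relativeEfficiency(effSet)
  if (!reference %in% names(rel))
    stop("reference allele '", reference, "' not in the estimated set; available: ",
         paste(names(rel), collapse = ", "))
  std <- rel / rel[[reference]]
  attr(std, "duplicated_candidates") <- names(std)[std >= 2]
  effSet@standardised <- std
  effSet@reference <- reference
  validObject(effSet)
  effSet
}

#' Build per-amplicon allele read-count observations from genotype calls
#'
#' One named count vector per amplicon, over the sequences called
#' `PUTATIVE_ALLELE` for that individual (reads of `LOW_EFFICIENCY_ALLELE`
#' variants are excluded by default: their counts are unreliable by
#' definition). Allele names come from the registry.
#'
#' @param calls a [GenotypeCalls-class].
#' @param includeLowEfficiency include low-efficiency-flagged alleles.
#' @return named list of named integer vectors (amplicon -> allele counts).
#' @export
genotypeObservations <- function(calls, includeLowEfficiency = FALSE) {
  lab <- clusterTable(calls)
  keepLabs <- "PUTATIVE_ALLELE"
  if (includeLowEfficiency) keepLabs <- c(keepLabs, "LOW_EFFICIENCY_ALLELE")
  lab <- lab[lab$finalLabel %in% keepLabs, , drop = FALSE]
  reg <- alleleRegistry(calls)
  lab$allele <- reg$allele[match(lab$sequence, reg$sequence)]
  lab <- lab[!is.na(lab$allele), , drop = FALSE]
  out <- lapply(split(lab, lab$amplicon), function(d)
    setNames(as.integer(d$count), d$allele))
  out[vapply(out, length, integer(1)) > 0L]
}

#' Write an efficiency table
#'
#' @param effSet an [EfficiencySet-class].
#' @param tsv output TSV path.
#' @return invisibly, the table written.
#' @export
writeEfficiencies <- function(effSet, tsv) {
  rel <- relativeEfficiency(effSet)
  std <- standardisedEfficiency(effSet)
  tab <- data.frame(allele = names(rel), relative = unname(rel),
                    standardised = if (length(std)) unname(std[names(rel)]) else NA_real_,
                    n_amplicons = unname(effSet@nAmplicons),
                    duplicated_candidate = if (length(std))
                      unname(std[names(rel)] >= 2) else NA,
                    stringsAsFactors = FALSE)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
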