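#' @import methods
#' @importFrom stats median optim rmultinom runif rnorm setNames cor dmultinom quantile
#' @importFrom utils adist read.delim write.table head
#' @importFrom S4Vectors mcols
NULL

#' Filtered, demultiplexed amplicon read sets
#'
#' Container produced by [filterAmplicons()]: one character vector of filtered
#' target sequences (primers and barcodes removed) per amplicon, the sample
#' sheet that defined the amplicons, and the per-stage attrition report.
#'
#' @slot sequences named list; one character vector of target sequences per
#'   amplicon id (\code{<individual>.<replicate>}).
#' @slot sampleSheet data.frame with columns \code{individual_id},
#'   \code{replicate}, \code{f_mid}, \code{r_mid} and one row per amplicon.
#' @slot report named list of per-stage read counts (see [filterReport()]).
#' @slot config the [filterConfig()] used.
#' @export
setClass("AmpliconSet",
  representation(sequences = "list", sampleSheet = "data.frame",
                 report = "list", config = "list"))

setValidity("AmpliconSet", function(object) {
  ids <- paste(object@sampleSheet$individual_id, object@sampleSheet$replicate, sep = ".")
  if (!all(names(object@sequences) %in% ids))
    return("sequences contain amplicon ids absent from the sample sheet")
  r <- object@report
  need <- c("reads_in", "removed_short", "removed_bad_mid", "removed_bad_primer",
            "removed_low_quality", "removed_bad_length_or_frame", "reads_out")
  if (!all(need %in% names(r))) return("incomplete filter report")
  if (r$reads_in != r$reads_out + r$removed_short + r$removed_bad_mid +
      r$removed_bad_primer + r$removed_low_quality + r$removed_bad_length_or_frame)
    return("filter report does not conserve reads")
  TRUE
})

#' Ranked identical-read clusters with intra-amplicon artefact typology
#'
#' @slot clusters data.frame with one row per (amplicon, variant) cluster:
#'   \code{individual}, \code{replicate}, \code{amplicon}, \code{sequence},
#'   \code{count}, \code{rank}, \code{frequency}, \code{intraLabel},
#'   \code{nearestParentRank}, \code{parentDistance}, \code{chimeraParent1},
#'   \code{chimeraParent2}, \code{breakpoint}.
#' @slot singletons data.frame of sequences seen exactly once per amplicon.
#' @export
setClass("ClusterSet",
  representation(clusters = "data.frame", singletons = "data.frame"))

setValidity("ClusterSet", function(object) {
  cl <- object@clusters
  if (nrow(cl) && any(cl$count < 2L)) return("singletons are never clusters")
  if (nrow(cl)) {
    byAmp <- split(cl, cl$amplicon)
    for (a in byAmp) {
      if (!isTRUE(all.equal(sum(a$frequency), 1)))
        return("cluster frequencies must sum to 1 within an amplicon")
      if (!identical(sort(a$rank), seq_len(nrow(a))))
        return("ranks must be a permutation of 1..n within an amplicon")
    }
  }
  TRUE
})

#' Final allele/artefact calls and genotypes
#'
#' @slot labels cluster table augmented with a \code{finalLabel} column
#'   (\code{PUTATIVE_ALLELE}, \code{PUTATIVE_ARTEFACT}, \code{UNCLASSIFIED},
#'   \code{LOW_EFFICIENCY_ALLELE}).
#' @slot genotypes data.frame: \code{individual}, \code{allele} (registry
#'   name), \code{sequence}, \code{reads_rep1}, \code{reads_rep2}, \code{label}.
#' @slot registry data.frame mapping allele names to sequences.
#' @slot excluded data.frame of excluded individuals with reasons.
#' @slot lowEfficiency character vector of sequences flagged by the census.
#' @slot passes integer; step-III passes needed to reach the fixed point.
#' @export
setClass("GenotypeCalls",
  representation(labels = "data.frame", genotypes = "data.frame",
                 registry = "data.frame", excluded = "data.frame",
                 lowEfficiency = "character", passes = "integer"))

#' Per-allele relative amplification efficiencies
#'
#' @slot relative named numeric; ML estimates, one allele per connected
#'   component pinned to 1 during optimisation.
#' @slot standardised named numeric; \code{relative / relative[reference]}.
#' @slot reference name of the reference allele (standardised value exactly 1).
#' @slot logLik log-likelihood at the optimum.
#' @slot converged logical convergence flag.
#' @slot nAmplicons named integer; amplicons in which each allele was observed.
#' @slot components list of character vectors: connected components of the
#'   genotype-sharing graph (efficiencies are only comparable within one).
#' @export
setClass("EfficiencySet",
  representation(relative = "numeric", standardised = "numeric",
                 reference = "character", logLik = "numeric",
                 converged = "logical", nAmplicons = "integer",
                 components = "list"))

setValidity("EfficiencySet", function(object) {
  if (any(object@relative <= 0)) return("efficiencies must be positive")
  if (length(object@standardised)) {
    ref <- object@reference
    if (!ref %in% names(object@standardised)) return("reference allele missing")
    if (abs(object@standardised[[ref]] - 1) > 1e-12)
      return("standardised efficiency of the reference must be exactly 1")
  }
  TRUE
})

#' A T1 minimum read-depth estimate
#'
#' @slot method one of \code{analytic_equal}, \code{simulated_equal},
#'   \code{simulated_var_eff}, \code{resampled}, \code{min_eff_grid}.
#' @slot k number of alleles in the genotype.
#' @slot T1 the threshold: minimal reads so that every allele is covered by at
#'   least \code{m} reads with confidence \code{gamma}.
#' @slot perReplicate per-replication T1 values (stochastic methods).
#' @slot config snapshot of the [coverageConfig()] used (plus seed).
#' @export
setClass("CoverageThreshold",
  representation(method = "character", k = "integer", T1 = "integer",
                 perReplicate = "integer", config = "list"))

setValidity("CoverageThreshold", function(object) {
  cfg <- object@config
  if (!is.na(object@T1) && length(cfg$m) && object@T1 < object@k * cfg$m)
    return("T1 cannot be below k * m")
  TRUE
})

setMethod("show", "AmpliconSet", function(object) {
  r <- object@report
  cat("AmpliconSet:", length(object@sequences), "amplicons,",
      r$reads_out, "of", r$reads_in, "reads kept\n")
  drop <- unlist(r[grep("^removed_", names(r))])
  cat("  removed:", paste(sprintf("%s=%d", sub("removed_", "", names(drop)), drop),
                          collapse = ", "), "\n")
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", nrow(object@clusters), "clusters across",
      length(unique(object@clusters$amplicon)), "amplicons;",
      nrow(object@singletons), "singletons\n")
  if (nrow(object@clusters))
    print(table(object@clusters$intraLabel))
})

setMethod("show", "GenotypeCalls", function(object) {
  cat("GenotypeCalls:", length(unique(object@genotypes$individual)),
      "individuals genotyped,", nrow(object@registry), "distinct alleles,",
      length(object@lowEfficiency), "low-efficiency flags,",
      nrow(object@excluded), "individuals excluded\n")
})

setMethod("show", "EfficiencySet", function(object) {
  cat("EfficiencySet:", length(object@relative), "alleles in",
      length(object@components), "component(s); logLik =",
      format(object@logLik, digits = 8),
      if (object@converged) "(converged)\n" else "(NOT converged)\n")
  if (length(object@standardised)) {
    cat("  standardised efficiencies (reference ", object@reference, "):\n", sep = "")
    print(round(sort(object@standardised), 3))
  }
})

setMethod("show", "CoverageThreshold", function(object) {
  cat("CoverageThreshold [", object@method, "]: k = ", object@k,
      ", T1 = ", object@T1, " reads (m = ", object@config$m,
      ", confidence = ", object@config$gamma, ")\n", sep = "")
})

## ---- accessors -------------------------------------------------------------

#' @describeIn AmpliconSet-class list of per-amplicon target sequence vectors
#' @param x an object
#' @export
amplicons <- function(x) {
  stopifnot(is(x, "AmpliconSet"))
  x@sequences
}

#' @describeIn AmpliconSet-class the sample sheet
#' @export
sampleSheet <- function(x) {
  stopifnot(is(x, "AmpliconSet"))
  x@sampleSheet
}

#' @describeIn AmpliconSet-class the per-stage attrition report
#' @export
filterReport <- function(x) {
  stopifnot(is(x, "AmpliconSet"))
  x@report
}

#' @describeIn ClusterSet-class the cluster table
#' @param x an object
#' @export
clusterTable <- function(x) {
  if (is(x, "GenotypeCalls")) return(x@labels)
  stopifnot(is(x, "ClusterSet"))
  x@clusters
}

#' @describeIn ClusterSet-class the singleton table
#' @export
singletonTable <- function(x) {
  stopifnot(is(x, "ClusterSet"))
  x@singletons
}

#' @describeIn GenotypeCalls-class the genotype table
#' @param x an object
#' @export
genotypeTable <- function(x) {
  stopifnot(is(x, "GenotypeCalls"))
  x@genotypes
}

#' @describeIn GenotypeCalls-class allele name registry
#' @export
alleleRegistry <- function(x) {
  stopifnot(is(x, "GenotypeCalls"))
  x@registry
}

#' @describeIn GenotypeCalls-class excluded individuals and reasons
#' @export
excludedIndividuals <- function(x) {
  stopifnot(is(x, "GenotypeCalls"))
  x@excluded
}

#' @describeIn EfficiencySet-class named vector of relative efficiencies
#' @param x an object
#' @export
relativeEfficiency <- function(x) {
  stopifnot(is(x, "EfficiencySet"))
  x@relative
}

#' @describeIn EfficiencySet-class named vector of standardised efficiencies
#' @export
standardisedEfficiency <- function(x) {
  stopifnot(is(x, "EfficiencySet"))
  x@standardised
}

#' @describeIn CoverageThreshold-class the T1 value in reads
#' @param x an object
#' @export
t1Value <- function(x) {
  stopifnot(is(x, "CoverageThreshold"))
  x@T1
}
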