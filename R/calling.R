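## Workflow steps II-III: reconcile intra-amplicon typologies across the two
## PCR replicates of each individual and across individuals, iterating the
## frequency-based allele rule to a fixed point, then run the low-efficiency
## census. Labels live per (variant sequence, amplicon): the same sequence may
## legitimately be an artefact in one individual and an allele in another.

.FINAL <- c(ARTEFACT = "PUTATIVE_ARTEFACT", ALLELE = "PUTATIVE_ALLELE",
            UNCLASSIFIED = "UNCLASSIFIED")

#' Call putative alleles from clustered replicate amplicons
#'
#' Implements the replicate-based classification workflow. Step II screens
#' clear artefacts: a `1-2 bp diff` or `chimera` cluster absent (as a
#' non-singleton cluster) from the individual's other replicate, a chimera in
#' both replicates, and a `>2 bp diff` cluster absent from the other replicate
#' and from every other individual. Step III then labels the remaining
#' variants: present in both replicates and strictly more frequent than every
#' annotated artefact in both amplicons gives `PUTATIVE_ALLELE`; present in
#' both but not above the artefact bar gives `UNCLASSIFIED`; a `>2 bp diff`
#' in one replicate only is `UNCLASSIFIED` when the sequence is an allele or
#' unclassified variant in another individual and `PUTATIVE_ARTEFACT`
#' otherwise; a chimera whose replicate partner carries a different category
#' is accepted as a natural recombinant when the sequence occurs in other
#' individuals. Step III is re-run (synchronously over all amplicons, so the
#' result is independent of processing order) until the labelling is stable.
#'
#' A final census re-flags sequences called `PUTATIVE_ALLELE` in at least one
#' individual but `UNCLASSIFIED` in strictly more individuals as
#' `LOW_EFFICIENCY_ALLELE`: candidate true alleles prone to dropout.
#'
#' Individuals are excluded (with a report entry) when they have a number of
#' replicates other than two, when an amplicon has fewer than `floorReads`
#' post-filter reads, or when the replicates share no putative allele
#' (suspected contamination or barcode swap).
#'
#' @param cset a [ClusterSet-class] from [clusterAmplicons()].
#' @param floorReads minimum post-filter reads per amplicon.
#' @param allelePrefix prefix for stable allele names in the registry.
#' @return a [GenotypeCalls-class].
#' @export
callAlleles <- function(cset, floorReads = 100L, allelePrefix = "ALL") {
  cl <- clusterTable(cset)
  sg <- singletonTable(cset)

  ## ---- exclusions ----------------------------------------------------------
  excluded <- data.frame(individual = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  allInd <- unique(c(cl$individual, sg$individual))
  ampReads <- tapply(cl$count, cl$amplicon, sum)
  sgReads <- table(sg$amplicon)
  for (a in names(sgReads))
    ampReads[a] <- (if (a %in% names(ampReads)) ampReads[a] else 0L) + sgReads[[a]]
  for (ind in allInd) {
    reps <- unique(c(cl$replicate[cl$individual == ind],
                     sg$replicate[sg$individual == ind]))
    if (length(reps) != 2L) {
      excluded <- rbind(excluded, data.frame(individual = ind,
                                             reason = "replicate_count",
                                             stringsAsFactors = FALSE))
    } else {
      amps <- unique(c(cl$amplicon[cl$individual == ind],
                       sg$amplicon[sg$individual == ind]))
      if (any(ampReads[amps] < floorReads))
        excluded <- rbind(excluded, data.frame(individual = ind,
                                               reason = "low_coverage",
                                               stringsAsFactors = FALSE))
    }
  }
  cl <- cl[!cl$individual %in% excluded$individual, , drop = FALSE]

  n <- nrow(cl)
  if (n == 0L)
    return(new("GenotypeCalls",
               labels = cbind(cl, finalLabel = character(0)),
               genotypes = data.frame(individual = character(0), allele = character(0),
                                      sequence = character(0), reads_rep1 = integer(0),
                                      reads_rep2 = integer(0), label = character(0),
                                      stringsAsFactors = FALSE),
               registry = data.frame(allele = character(0), sequence = character(0),
                                     stringsAsFactors = FALSE),
               excluded = excluded, lowEfficiency = character(0), passes = 0L))

  ## ---- presence indexes ----------------------------------------------------
  otherRep <- ifelse(cl$replicate == 1L, 2L, 1L)
  rowKey <- paste(cl$individual, cl$replicate, cl$sequence, sep = "\r")
  partnerIdx <- match(paste(cl$individual, otherRep, cl$sequence, sep = "\r"), rowKey)
  inBoth <- !is.na(partnerIdx)
  ## sequence -> individuals carrying it as a non-singleton cluster
  seqInd <- lapply(split(cl$individual, cl$sequence), unique)
  nIndWith <- vapply(seqInd, length, integer(1))
  inOtherInd <- nIndWith[cl$sequence] > 1L

  ## ---- step II -------------------------------------------------------------
  lab <- cl$intraLabel
  partnerLab <- ifelse(inBoth, lab[partnerIdx], NA_character_)
  stepII <- rep(FALSE, n)
  stepII[lab == "DIFF_1_2" & !inBoth] <- TRUE
  stepII[lab == "CHIMERA" & !inBoth] <- TRUE
  stepII[lab == "CHIMERA" & inBoth & partnerLab == "CHIMERA"] <- TRUE
  stepII[lab == "DIFF_GT2" & !inBoth & !inOtherInd] <- TRUE

  ## ---- step III fixed point ------------------------------------------------
  state <- ifelse(stepII, "ARTEFACT", "PENDING")
  amp <- cl$amplicon
  freq <- cl$frequency
  maxPasses <- n + 2L
  passes <- 0L
  repeat {
    passes <- passes + 1L
    if (passes > maxPasses) stop("allele calling did not reach a fixed point")
    ## artefact frequency bar per amplicon, from the current state
    isArt <- state == "ARTEFACT"
    bar <- tapply(ifelse(isArt, freq, -Inf), amp, max)
    barHere <- as.numeric(bar[amp])
    barThere <- ifelse(inBoth, as.numeric(bar[amp[partnerIdx]]), NA_real_)
    ## sequence status in other individuals, from the current state
    indState <- paste(cl$individual, cl$sequence, sep = "\r")
    okElse <- state %in% c("ALLELE", "UNCLASSIFIED")
    seqOkInd <- lapply(split(cl$individual[okElse], cl$sequence[okElse]), unique)
    alleleOrUnclElsewhere <- vapply(seq_len(n), function(i) {
      s <- seqOkInd[[cl$sequence[i]]]
      !is.null(s) && any(s != cl$individual[i])
    }, logical(1))

    newState <- state
    for (i in which(!stepII)) {
      if (inBoth[i]) {
        above <- freq[i] > barHere[i] && freq[partnerIdx[i]] > barThere[i]
        if (lab[i] == "CHIMERA" && partnerLab[i] != "CHIMERA" && inOtherInd[i]) {
          newState[i] <- "ALLELE"        # natural recombinant
        } else {
          newState[i] <- if (above) "ALLELE" else "UNCLASSIFIED"
        }
      } else {
        if (lab[i] == "DIFF_GT2") {
          newState[i] <- if (alleleOrUnclElsewhere[i]) "UNCLASSIFIED" else "ARTEFACT"
        } else {
          ## TOP absent from its replicate: no artefact-typology evidence
          newState[i] <- "UNCLASSIFIED"
        }
      }
    }
    if (identical(newState, state)) break
    state <- newState
  }

  ## ---- incongruent replicate pairs -----------------------------------------
  hasAllele <- tapply(state == "ALLELE", cl$individual, any)
  bad <- names(hasAllele)[!hasAllele]
  if (length(bad)) {
    excluded <- rbind(excluded, data.frame(individual = bad,
                                           reason = "incongruent_replicates",
                                           stringsAsFactors = FALSE))
    keep <- !cl$individual %in% bad
    cl <- cl[keep, , drop = FALSE]
    state <- state[keep]
  }

  final <- unname(.FINAL[state])

  ## ---- low-efficiency census -----------------------------------------------
  lowEff <- character(0)
  if (nrow(cl)) {
    for (s in unique(cl$sequence[final == "PUTATIVE_ALLELE"])) {
      rows <- which(cl$sequence == s)
      stat <- tapply(final[rows], cl$individual[rows], function(f) {
        if (any(f == "PUTATIVE_ALLELE")) "allele"
        else if (any(f == "UNCLASSIFIED")) "unclassified"
        else "artefact"
      })
      if (sum(stat == "unclassified") > sum(stat == "allele"))
        lowEff <- c(lowEff, s)
    }
    if (length(lowEff)) {
      hit <- cl$sequence %in% lowEff &
        final %in% c("PUTATIVE_ALLELE", "UNCLASSIFIED")
      final[hit] <- "LOW_EFFICIENCY_ALLELE"
    }
  }
  cl$finalLabel <- final

  ## ---- genotype table and registry -----------------------------------------
  isCall <- final %in% c("PUTATIVE_ALLELE", "LOW_EFFICIENCY_ALLELE")
  gseq <- unique(cl[isCall, c("individual", "sequence")])
  registrySeqs <- sort(unique(gseq$sequence))
  registry <- data.frame(allele = sprintf("%s*%03d", allelePrefix,
                                          seq_along(registrySeqs)),
                         sequence = registrySeqs, stringsAsFactors = FALSE)
  countOf <- function(ind, s, rep) {
    i <- which(cl$individual == ind & cl$sequence == s & cl$replicate == rep)
    if (length(i)) cl$count[i[1L]] else 0L
  }
  if (nrow(gseq)) {
    genotypes <- do.call(rbind, lapply(seq_len(nrow(gseq)), function(i) {
      ind <- gseq$individual[i]; s <- gseq$sequence[i]
      rows <- which(cl$individual == ind & cl$sequence == s)
      labHere <- if (any(final[rows] == "LOW_EFFICIENCY_ALLELE"))
        "LOW_EFFICIENCY_ALLELE" else "PUTATIVE_ALLELE"
      data.frame(individual = ind,
                 allele = registry$allele[match(s, registry$sequence)],
                 sequence = s,
                 reads_rep1 = countOf(ind, s, 1L),
                 reads_rep2 = countOf(ind, s, 2L),
                 label = labHere, stringsAsFactors = FALSE)
    }))
    genotypes <- genotypes[order(genotypes$individual, genotypes$allele), ,
                           drop = FALSE]
    rownames(genotypes) <- NULL
  } else {
    genotypes <- data.frame(individual = character(0), allele = character(0),
                            sequence = character(0), reads_rep1 = integer(0),
                            reads_rep2 = integer(0), label = character(0),
                            stringsAsFactors = FALSE)
  }

  new("GenotypeCalls", labels = cl, genotypes = genotypes, registry = registry,
      excluded = excluded, lowEfficiency = unique(lowEff), passes = passes)
}

#' Fixed-frequency-threshold classification (comparison baseline)
#'
#' Labels every cluster of an amplicon `PUTATIVE_ALLELE` iff its intra-amplicon
#' frequency is at least `t2`, the fixed-threshold rule used as a benchmark
#' against the replicate-based workflow (the classical choice is
#' t2 = 0.0437, the upper end of the artefact frequency distribution).
#'
#' @param clusters cluster data.frame with a `frequency` column.
#' @param t2 frequency threshold in (0, 1).
#' @return character vector of labels, parallel to `clusters` rows.
#' @export
classifyByFrequencyThreshold <- function(clusters, t2 = 0.0437) {
  if (!is.numeric(t2) || length(t2) != 1L || t2 <= 0 || t2 >= 1)
    stop("t2 must be a fraction in (0, 1)")
  ifelse(clusters$frequency >= t2, "PUTATIVE_ALLELE", "PUTATIVE_ARTEFACT")
}

#' Write genotype outputs
#'
#' @param calls a [GenotypeCalls-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeGenotypes <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             labels = file.path(dir, "classification.tsv"),
             alleles = file.path(dir, "alleles.fasta"),
             excluded = file.path(dir, "excluded.tsv"))
  write.table(genotypeTable(calls), paths["genotypes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(clusterTable(calls), paths["labels"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  reg <- alleleRegistry(calls)
  if (nrow(reg)) {
    fa <- Biostrings::DNAStringSet(setNames(reg$sequence, reg$allele))
    Biostrings::writeXStringSet(fa, paths["alleles"])
  } else file.create(paths["alleles"])
  write.table(excludedIndividuals(calls), paths["excluded"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
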