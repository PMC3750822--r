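# Shared fixture builders and independent oracles.

RC <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

## assemble a raw read: fMID + forward primer + target + rc(reverse primer) + rc(rMID)
mkRead <- function(target, fMid, rMid, fPrimer, rPrimer, qual = NULL) {
  bases <- paste0(fMid, fPrimer, target, RC(rPrimer), RC(rMid))
  if (is.null(qual)) qual <- strrep("I", nchar(bases))  # Q40
  list(bases = bases, quals = qual)
}

mkReadTable <- function(targets, fMid, rMid, fPrimer, rPrimer) {
  rows <- lapply(targets, mkRead, fMid = fMid, rMid = rMid,
                 fPrimer = fPrimer, rPrimer = rPrimer)
  data.frame(read_id = sprintf("t%04d", seq_along(rows)),
             bases = vapply(rows, `[[`, character(1), "bases"),
             quals = vapply(rows, `[[`, character(1), "quals"),
             stringsAsFactors = FALSE)
}

## random codon-clean coding sequence
randCoding <- function(len = 60L) {
  stopifnot(len %% 3 == 0)
  codons <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                          paste0), c("A","C","G","T"), paste0)),
                    c("TAA", "TAG", "TGA"))
  paste(sample(codons, len %/% 3, replace = TRUE), collapse = "")
}

substituteAt <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

otherBase <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

## exhaustive chimera oracle: enumerate all ordered parent pairs and all
## breakpoints, building the template-switch product explicitly
oracleChimera <- function(query, parentSeqs, parentRanks = seq_along(parentSeqs)) {
  ord <- order(parentRanks)
  for (i in ord) for (j in ord) {
    if (i == j) next
    p1 <- parentSeqs[i]; p2 <- parentSeqs[j]
    if (p1 == query || p2 == query) next
    for (b in seq_len(min(nchar(p1), nchar(p2) - 1L))) {
      cand <- paste0(substr(p1, 1L, b), substr(p2, b + 1L, nchar(p2)))
      if (cand == query)
        return(list(parent1 = parentRanks[i], parent2 = parentRanks[j],
                    breakpoint = b))
    }
  }
  NULL
}

## exhaustive multinomial coverage oracle for k <= 3
oracleAllAtLeast <- function(n, probs, m) {
  k <- length(probs)
  if (k == 1L) return(as.numeric(n >= m))
  total <- 0
  if (k == 2L) {
    for (c1 in 0:n) {
      cnt <- c(c1, n - c1)
      if (all(cnt >= m)) total <- total + dmultinom(cnt, prob = probs)
    }
  } else {
    for (c1 in 0:n) for (c2 in 0:(n - c1)) {
      cnt <- c(c1, c2, n - c1 - c2)
      if (all(cnt >= m)) total <- total + dmultinom(cnt, prob = probs)
    }
  }
  total
}

## hand-built cluster-table rows for calling-rule fixtures; counts are given
## per amplicon and ranks/frequencies derived exactly as clusterReads does
mkAmp <- function(individual, replicate, seqs, counts, labels) {
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]; counts <- counts[ord]; labels <- labels[ord]
  data.frame(individual = individual, replicate = replicate,
             amplicon = paste(individual, replicate, sep = "."),
             sequence = seqs, count = counts, rank = seq_along(seqs),
             frequency = counts / sum(counts), intraLabel = labels,
             nearestParentRank = NA_integer_, parentDistance = NA_integer_,
             chimeraParent1 = NA_integer_, chimeraParent2 = NA_integer_,
             breakpoint = NA_integer_, stringsAsFactors = FALSE)
}

mkClusterSet <- function(...) {
  cl <- do.call(rbind, list(...))
  sg <- data.frame(individual = character(0), replicate = integer(0),
                   amplicon = character(0), sequence = character(0),
                   stringsAsFactors = FALSE)
  new("ClusterSet", clusters = cl, singletons = sg)
}

## tiny deterministic sample sheet
mkSheet <- function(nInd = 1L) {
  mids <- c("ACGTACGTAA", "TTGGCCAATT", "GGAATTCCGG", "CCTTAAGGCC",
            "ATATCGCGAT", "GCGCATATGC", "TACGGCATTA", "CGATTAGCCG")
  data.frame(individual_id = rep(sprintf("ind%02d", seq_len(nInd)), each = 2L),
             replicate = rep(1:2, nInd),
             f_mid = mids[seq_len(2L * nInd)],
             r_mid = rev(mids)[seq_len(2L * nInd)],
             stringsAsFactors = FALSE)
}
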