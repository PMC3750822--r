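## Workflow step I: collapse identical reads into ranked clusters per
## amplicon, drop singletons, and give every non-top cluster an intra-amplicon
## artefact typology: chimera of two more-frequent clusters, 1-2 bp variant of
## a more-frequent cluster, or a more divergent (>2 bp) variant.

#' Cluster identical reads within one amplicon
#'
#' Groups identical target sequences, emits size-1 groups as singletons, and
#' ranks the remaining clusters by read count (ties broken lexicographically
#' by sequence, so the ranking is deterministic). Cluster frequencies are
#' computed over non-singleton reads only.
#'
#' @param targets character vector of filtered target sequences.
#' @return list with `clusters` (data.frame: sequence, count, rank, frequency)
#'   and `singletons` (character vector).
#' @examples
#' clusterReads(c("AAA", "AAA", "AAA", "CCC", "CCC", "GGG", "TTT"))$clusters
#' @export
clusterReads <- function(targets) {
  if (length(targets) == 0L)
    return(list(clusters = data.frame(sequence = character(0), count = integer(0),
                                      rank = integer(0), frequency = numeric(0),
                                      stringsAsFactors = FALSE),
                singletons = character(0)))
  tab <- table(targets)
  cnt <- as.integer(tab)
  seqs <- names(tab)
  single <- cnt == 1L
  singletons <- seqs[single]
  seqs <- seqs[!single]
  cnt <- cnt[!single]
  ord <- order(-cnt, seqs)
  seqs <- seqs[ord]
  cnt <- cnt[ord]
  total <- sum(cnt)
  list(clusters = data.frame(sequence = seqs, count = cnt,
                             rank = seq_along(seqs),
                             frequency = if (total > 0) cnt / total else numeric(length(cnt)),
                             stringsAsFactors = FALSE),
       singletons = singletons)
}

#' Test whether a variant is a chimera of two more-frequent variants
#'
#' A query is a chimera if there is a breakpoint `b` (1 <= b < L) and an
#' ordered pair of distinct parents, both with strictly higher read count,
#' such that the query equals the first `b` bases of parent 1 followed by
#' parent 2 from position `b + 1` onward, and the query differs from both
#' parents. This is the mechanistic template-switch model: the product
#' inherits parent 2's coordinates (and therefore its length), so in-frame
#' indel variants are never mistaken for chimeras. Among multiple
#' certificates the one with the lowest (parent-1 rank, parent-2 rank,
#' breakpoint) is returned.
#'
#' @param query query sequence (character scalar).
#' @param parentSeqs sequences of all clusters with strictly higher count,
#'   ordered by rank.
#' @param parentRanks their ranks (defaults to `seq_along(parentSeqs)`).
#' @return NULL if not a chimera, else a list with `parent1`, `parent2`
#'   (ranks), and `breakpoint`.
#' @export
detectChimera <- function(query, parentSeqs, parentRanks = seq_along(parentSeqs)) {
  .chimeraCore(strsplit(query, "")[[1]], parentSeqs != query,
               strsplit(parentSeqs, ""), parentRanks)
}

## core of the chimera test on pre-split character vectors
.chimeraCore <- function(qc, differs, parentChars, parentRanks) {
  np <- length(parentChars)
  if (np < 2L) return(NULL)
  L <- length(qc)
  if (L < 2L) return(NULL)
  lcp <- function(pc) {
    n <- min(L, length(pc))
    d <- which(qc[seq_len(n)] != pc[seq_len(n)])
    if (length(d) == 0L) n else d[1L] - 1L
  }
  lcs <- function(pc) {
    n <- min(L, length(pc))
    d <- which(qc[L - seq_len(n) + 1L] != pc[length(pc) - seq_len(n) + 1L])
    if (length(d) == 0L) n else d[1L] - 1L
  }
  pre <- vapply(parentChars, lcp, integer(1))
  suf <- vapply(parentChars, lcs, integer(1))
  pLen <- lengths(parentChars)
  ord <- order(parentRanks)
  for (i in ord) {
    if (!differs[i]) next
    hi <- min(pre[i], L - 1L, pLen[i])
    if (hi < 1L) next
    for (j in ord) {
      if (j == i || !differs[j] || pLen[j] != L) next
      lo <- max(1L, L - suf[j])
      if (lo <= hi)
        return(list(parent1 = parentRanks[i], parent2 = parentRanks[j],
                    breakpoint = lo))
    }
  }
  NULL
}

#' Assign intra-amplicon categories to ranked clusters
#'
#' Rank-1 clusters get `TOP`. Every other cluster is first tested as a chimera
#' of two strictly-more-frequent clusters (chimera precedence); otherwise its
#' distance to the most similar strictly-more-frequent cluster is computed as
#' the Levenshtein edit distance (mismatches plus gap columns of a global
#' alignment, so one 3 bp indel counts 3), and the cluster is labelled
#' `DIFF_1_2` when that distance is at most 2, else `DIFF_GT2`. Nearest-parent
#' ties at equal distance resolve to the lowest rank.
#'
#' @param clusters data.frame from [clusterReads()] (sequence, count, rank).
#' @return the cluster data.frame with columns `intraLabel`,
#'   `nearestParentRank`, `parentDistance`, `chimeraParent1`,
#'   `chimeraParent2`, `breakpoint` added.
#' @export
classifyIntra <- function(clusters) {
  n <- nrow(clusters)
  lab <- rep(NA_character_, n)
  npr <- rep(NA_integer_, n)
  pdist <- rep(NA_integer_, n)
  cp1 <- rep(NA_integer_, n)
  cp2 <- rep(NA_integer_, n)
  bp <- rep(NA_integer_, n)
  if (n >= 1L) lab[1L] <- "TOP"
  chars <- strsplit(clusters$sequence, "")
  for (r in seq_len(n)[-1]) {
    ## strictly-more-frequent = strictly higher count (ties cannot parent)
    parents <- which(clusters$count > clusters$count[r])
    if (length(parents) == 0L) { lab[r] <- "TOP"; next }
    chi <- .chimeraCore(chars[[r]],
                        clusters$sequence[parents] != clusters$sequence[r],
                        chars[parents], clusters$rank[parents])
    if (!is.null(chi)) {
      lab[r] <- "CHIMERA"
      cp1[r] <- chi$parent1
      cp2[r] <- chi$parent2
      bp[r] <- chi$breakpoint
      next
    }
    ## fast exact path: for equal-length pairs a Hamming distance <= 2 equals
    ## the Levenshtein distance, and a length difference of >= 3 bp (the only
    ## kind the filter admits) bounds the edit distance at >= 3
    qc <- chars[[r]]
    sameLen <- lengths(chars[parents]) == length(qc)
    h <- rep(NA_integer_, length(parents))
    h[sameLen] <- vapply(chars[parents[sameLen]],
                         function(pc) sum(pc != qc), integer(1))
    if (any(!is.na(h) & h <= 2L)) {
      best <- which.min(h)
      npr[r] <- clusters$rank[parents][best]
      pdist[r] <- h[best]
      lab[r] <- "DIFF_1_2"
      next
    }
    d <- as.integer(adist(clusters$sequence[r], clusters$sequence[parents]))
    best <- which.min(d)  # lowest rank wins ties (parents are rank-ordered)
    npr[r] <- clusters$rank[parents][best]
    pdist[r] <- d[best]
    lab[r] <- if (d[best] <= 2L) "DIFF_1_2" else "DIFF_GT2"
  }
  clusters$intraLabel <- lab
  clusters$nearestParentRank <- npr
  clusters$parentDistance <- pdist
  clusters$chimeraParent1 <- cp1
  clusters$chimeraParent2 <- cp2
  clusters$breakpoint <- bp
  clusters
}

#' Cluster and classify all amplicons of a filtered run
#'
#' @param aset an [AmpliconSet-class] from [filterAmplicons()], or a named
#'   list of per-amplicon target sequence vectors.
#' @param sheet sample sheet (only needed when `aset` is a bare list).
#' @return a [ClusterSet-class].
#' @export
clusterAmplicons <- function(aset, sheet = NULL) {
  if (is(aset, "AmpliconSet")) {
    sheet <- sampleSheet(aset)
    seqs <- amplicons(aset)
  } else seqs <- aset
  if (is.null(sheet)) stop("a sample sheet is required")
  rows <- list()
  srows <- list()
  for (amp in names(seqs)) {
    meta <- sheet[sheet$amplicon == amp, , drop = FALSE]
    cl <- clusterReads(seqs[[amp]])
    if (nrow(cl$clusters)) {
      tab <- classifyIntra(cl$clusters)
      tab <- cbind(individual = meta$individual_id[1L],
                   replicate = meta$replicate[1L],
                   amplicon = amp, tab, stringsAsFactors = FALSE)
      rows[[amp]] <- tab
    }
    if (length(cl$singletons))
      srows[[amp]] <- data.frame(individual = meta$individual_id[1L],
                                 replicate = meta$replicate[1L],
                                 amplicon = amp, sequence = cl$singletons,
                                 stringsAsFactors = FALSE)
  }
  emptyCl <- data.frame(individual = character(0), replicate = integer(0),
                        amplicon = character(0), sequence = character(0),
                        count = integer(0), rank = integer(0),
                        frequency = numeric(0), intraLabel = character(0),
                        nearestParentRank = integer(0), parentDistance = integer(0),
                        chimeraParent1 = integer(0), chimeraParent2 = integer(0),
                        breakpoint = integer(0), stringsAsFactors = FALSE)
  emptySg <- data.frame(individual = character(0), replicate = integer(0),
                        amplicon = character(0), sequence = character(0),
                        stringsAsFactors = FALSE)
  clusters <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else emptyCl
  singles <- if (length(srows)) do.call(rbind, c(srows, make.row.names = FALSE)) else emptySg
  new("ClusterSet", clusters = clusters, singletons = singles)
}

#' Write the per-amplicon cluster table
#'
#' @param cset a [ClusterSet-class].
#' @param tsv output TSV path.
#' @return invisibly, the table written.
#' @export
writeClusterTable <- function(cset, tsv) {
  tab <- clusterTable(cset)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
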