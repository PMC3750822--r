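## Synthetic dual-barcoded amplicon runs with full truth tables. The
## generator emulates the error taxonomy of a PCR + pyrosequencing amplicon
## experiment: per-allele amplification efficiencies spanning more than
## 10-fold, single-breakpoint PCR chimeras, early-PCR 1-2 bp polymerase-error
## variants amplified into multi-read clusters, more divergent multi-read
## artefacts, unique singleton sequencing errors, homopolymer-style 1 bp
## frameshift reads, low-quality reads, short reads and corrupted barcodes.

.CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: 36 individuals genotyped
#' in two independent PCR replicates from a shared pool of 20 alleles (2-11
#' per individual), a 228 bp codon-clean target, standardised amplification
#' efficiencies drawn log-uniformly over [0.2, 2.4], and read depths of mean
#' 768 (sd 314) per amplicon. Of the reads surviving filtering, about 47%
#' represent alleles, 34% are unique singleton errors and 19% multi-read
#' artefact clusters, the latter dominated by chimeras; corrupted reads
#' (frameshifts, low quality, short, bad barcodes) are added on top and are
#' what the filter cascade removes.
#'
#' @param nIndividuals individuals (each with two amplicon replicates).
#' @param allelePoolSize size of the shared allele pool.
#' @param allelesPerIndividual integer range of genotype sizes.
#' @param targetLength target length in bp, divisible by 3.
#' @param divergence allowed pairwise Hamming distance range within the pool.
#' @param efficiencyRange range of the log-uniform efficiency draw.
#' @param readsMean,readsSd,readsMin,readsMax per-amplicon depth distribution
#'   (normal draw, rounded and clamped).
#' @param singletonFraction fraction of filtered reads that are singletons.
#' @param multiArtefactFraction fraction of filtered reads in multi-read
#'   artefact clusters.
#' @param chimeraShare,diff12Share,diffGt2Share split of the multi-read
#'   artefact reads by type (chimeras carry about half).
#' @param frameshiftFraction,lowQualityFraction,shortFraction,badMidFraction
#'   corrupted reads added on top of the filtered-read target, as fractions
#'   of it.
#' @param respectAlleleFloor keep every artefact cluster strictly smaller
#'   than the smallest allele cluster of its amplicon (the workflow's
#'   assumption that artefacts are rarer than any true allele holds by
#'   construction); set FALSE for robustness studies.
#' @param fPrimer,rPrimer amplification primers (IUPAC-degenerate positions
#'   are realised per read).
#' @param efficiencies optional numeric vector overriding the efficiency draw
#'   (length `allelePoolSize`).
#' @param genotypes optional list of allele-name vectors overriding the
#'   genotype draw (length `nIndividuals`).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return validated list of class `simulation_config`.
#' @export
simulationConfig <- function(nIndividuals = 36L, allelePoolSize = 20L,
                             allelesPerIndividual = c(2L, 11L),
                             targetLength = 228L, divergence = c(4L, 30L),
                             efficiencyRange = c(0.2, 2.4),
                             readsMean = 768, readsSd = 314,
                             readsMin = 142L, readsMax = 2400L,
                             singletonFraction = 0.34,
                             multiArtefactFraction = 0.19,
                             chimeraShare = 0.5, diff12Share = 0.35,
                             diffGt2Share = 0.15,
                             frameshiftFraction = 0.08,
                             lowQualityFraction = 0.10,
                             shortFraction = 0.05, badMidFraction = 0.03,
                             respectAlleleFloor = TRUE,
                             fPrimer = "TCCTGGAGCAGRTTCTACAA",
                             rPrimer = "GCTGCACAGTGAAWCTCTCC",
                             efficiencies = NULL, genotypes = NULL,
                             seed = 1L) {
  stopifnot(targetLength %% 3L == 0L,
            allelesPerIndividual[1] >= 1,
            allelesPerIndividual[2] <= allelePoolSize,
            singletonFraction >= 0, multiArtefactFraction >= 0,
            singletonFraction + multiArtefactFraction < 1,
            abs(chimeraShare + diff12Share + diffGt2Share - 1) < 1e-9,
            all(c(frameshiftFraction, lowQualityFraction, shortFraction,
                  badMidFraction) >= 0),
            efficiencyRange[1] > 0, readsMin >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

## mutate `nPos` distinct positions of a coding sequence, avoiding stop
## codons and (optionally) a set of forbidden resulting sequences.
.mutateSeq <- function(seq, nPos) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  pos <- sample.int(L, nPos)
  for (p in pos) {
    ci <- (p - 1L) %/% 3L
    alt <- sample(setdiff(c("A", "C", "G", "T"), chars[p]))
    for (b in alt) {
      old <- chars[p]
      chars[p] <- b
      codon <- paste(chars[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      if (!codon %in% .STOP_CODONS) break
      chars[p] <- old
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a pool of mutually distinct alleles
#'
#' Alleles are derived from a random codon-clean ancestor by substitutions at
#' randomly chosen positions (codon-aware, never creating an internal stop),
#' under the constraint that all pairwise Hamming distances fall inside the
#' configured divergence range. Bounded rejection sampling; infeasible
#' constraints raise an error.
#'
#' @param n pool size.
#' @param targetLength sequence length (divisible by 3).
#' @param divergence length-2 integer range of pairwise distances.
#' @param seed optional seed (NULL = use the current RNG stream).
#' @return named character vector of allele sequences (`A001`, `A002`, ...).
#' @export
simulateAllelePool <- function(n, targetLength = 228L, divergence = c(4L, 30L),
                               seed = NULL) {
  gen <- function() {
    base <- paste(sample(.CODONS, targetLength %/% 3L, replace = TRUE),
                  collapse = "")
    dmin <- divergence[1]
    dmax <- divergence[2]
    half <- max(dmin, dmax %/% 2L)
    pool <- character(0)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (attempt in seq_len(500L)) {
        d <- sample(seq(dmin, half), 1L)
        cand <- .mutateSeq(base, d)
        dists <- vapply(pool, .hamming, integer(1), a = cand, USE.NAMES = FALSE)
        db <- .hamming(cand, base)
        if (db >= dmin && db <= dmax &&
            (length(dists) == 0L || (all(dists >= dmin) && all(dists <= dmax)))) {
          pool <- c(pool, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not satisfy divergence constraints for allele ", i)
    }
    setNames(pool, sprintf("A%03d", seq_len(n)))
  }
  if (is.null(seed)) gen() else .seededRNG(seed)$run(gen)
}

## realise IUPAC-degenerate primer positions, one concrete string per read
.realisePrimer <- function(primer, nReads) {
  if (nReads == 0L) return(character(0))
  map <- Biostrings::IUPAC_CODE_MAP
  letters <- strsplit(primer, "")[[1]]
  cols <- lapply(letters, function(l) {
    set <- strsplit(map[[l]], "")[[1]]
    if (length(set) == 1L) rep(set, nReads) else sample(set, nReads, replace = TRUE)
  })
  do.call(paste0, cols)
}

#' Simulate the reads of one amplicon
#'
#' Clean allele reads are multinomial with cell probabilities proportional to
#' the genotype's efficiencies; every artefact cluster's count is strictly
#' below its source(s), and (by default) below the smallest allele cluster.
#' Chimeras splice two genotype alleles at a uniform breakpoint. Corrupted
#' reads (frameshift, low-quality, short, bad-MID) are appended for the
#' filter cascade to remove.
#'
#' @param genotype named character vector of allele target sequences.
#' @param efficiencies positive numeric, parallel to `genotype`.
#' @param nReads intended number of filter-surviving reads.
#' @param config a [simulationConfig()].
#' @return list: `targets` (data.frame sequence/count/type/source1/source2/
#'   breakpoint for clean and multi-read artefact clusters plus singletons)
#'   and `corrupt` (data.frame type/target for reads the filter must drop).
#' @export
simulateAmplicon <- function(genotype, efficiencies, nReads, config) {
  stopifnot(length(genotype) >= 1, all(efficiencies > 0),
            length(efficiencies) == length(genotype))
  L <- config$targetLength
  cleanFrac <- 1 - config$singletonFraction - config$multiArtefactFraction
  nClean <- max(round(nReads * cleanFrac), length(genotype))
  counts <- as.integer(rmultinom(1L, nClean, efficiencies / sum(efficiencies)))
  names(counts) <- names(genotype)

  rows <- data.frame(sequence = unname(genotype), count = counts,
                     type = "allele", source1 = names(genotype),
                     source2 = NA_character_, breakpoint = NA_integer_,
                     stringsAsFactors = FALSE)
  rows <- rows[rows$count > 0L, , drop = FALSE]
  existing <- new.env(parent = emptyenv())
  for (s in genotype) assign(s, TRUE, envir = existing)
  taken <- function(s) exists(s, envir = existing, inherits = FALSE)
  minAllele <- if (any(counts >= 2L)) min(counts[counts >= 2L]) else Inf
  cap <- if (config$respectAlleleFloor) minAllele - 1L else Inf

  artReads <- round(nReads * config$multiArtefactFraction)
  budget <- c(chimera = round(artReads * config$chimeraShare),
              early_error = round(artReads * config$diff12Share),
              distant_error = round(artReads * config$diffGt2Share))

  addCluster <- function(seq, size, type, s1, s2 = NA_character_, bp = NA_integer_) {
    rows[nrow(rows) + 1L, ] <<- list(seq, size, type, s1, s2, bp)
    assign(seq, TRUE, envir = existing)
  }

  ## chimeras: spliced from two genotype alleles, count below both parents
  if (length(genotype) >= 2L) {
    guard <- 0L
    while (budget["chimera"] >= 2L && guard < 200L) {
      guard <- guard + 1L
      eligible <- names(counts)[counts >= 3L]
      if (length(eligible) < 2L) break
      pair <- sample(eligible, 2L)
      b <- sample.int(L - 1L, 1L)
      p1 <- genotype[[pair[1]]]; p2 <- genotype[[pair[2]]]
      chim <- paste0(substr(p1, 1L, b), substr(p2, b + 1L, nchar(p2)))
      if (taken(chim)) next
      upper <- min(6, cap, counts[pair[1]] - 1L, counts[pair[2]] - 1L,
                   budget["chimera"])
      if (upper < 2) next
      size <- sample(2:upper, 1L)
      addCluster(chim, size, "chimera", pair[1], pair[2], b)
      budget["chimera"] <- budget["chimera"] - size
    }
  }

  ## early-PCR polymerase errors amplified into multi-read clusters
  for (type in c("early_error", "distant_error")) {
    nmutRange <- if (type == "early_error") 1:2 else 3:6
    guard <- 0L
    while (budget[type] >= 2L && guard < 200L) {
      guard <- guard + 1L
      eligible <- names(counts)[counts >= 3L]
      if (length(eligible) == 0L) break
      src <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      mut <- .mutateSeq(genotype[[src]], sample(nmutRange, 1L))
      if (taken(mut)) next
      upper <- min(6, cap, counts[src] - 1L, budget[type])
      if (upper < 2) next
      size <- sample(2:upper, 1L)
      addCluster(mut, size, type, src)
      budget[type] <- budget[type] - size
    }
  }

  ## unique singleton errors (1-2 bp, unique within the amplicon)
  nSingle <- round(nReads * config$singletonFraction)
  singles <- character(0)
  srcs <- character(0)
  if (nSingle > 0L && sum(counts) > 0L) {
    pick <- sample(names(counts), nSingle, replace = TRUE,
                   prob = pmax(counts, 1e-9))
    for (src in pick) {
      for (attempt in 1:30) {
        mut <- .mutateSeq(genotype[[src]], sample(1:2, 1L, prob = c(0.7, 0.3)))
        if (!taken(mut)) {
          assign(mut, TRUE, envir = existing)
          singles <- c(singles, mut)
          srcs <- c(srcs, src)
          break
        }
      }
    }
  }
  if (length(singles))
    rows <- rbind(rows, data.frame(sequence = singles, count = 1L,
                                   type = "singleton_error", source1 = srcs,
                                   source2 = NA_character_,
                                   breakpoint = NA_integer_,
                                   stringsAsFactors = FALSE))

  ## corrupted reads for the filter cascade
  corrupt <- data.frame(type = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  addCorrupt <- function(type, n) {
    if (n <= 0L) return()
    src <- sample(names(genotype), n, replace = TRUE)
    tg <- unname(genotype[src])
    if (type == "frameshift") {
      tg <- vapply(tg, function(s) {
        p <- sample.int(nchar(s), 1L)
        if (runif(1) < 0.5) paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
        else paste0(substr(s, 1L, p), sample(c("A", "C", "G", "T"), 1L),
                    substr(s, p + 1L, nchar(s)))
      }, character(1), USE.NAMES = FALSE)
    }
    corrupt <<- rbind(corrupt, data.frame(type = type, target = tg,
                                          stringsAsFactors = FALSE))
  }
  addCorrupt("frameshift", round(nReads * config$frameshiftFraction))
  addCorrupt("low_quality", round(nReads * config$lowQualityFraction))
  addCorrupt("short", round(nReads * config$shortFraction))
  addCorrupt("bad_mid", round(nReads * config$badMidFraction))

  rownames(rows) <- NULL
  list(targets = rows, corrupt = corrupt)
}

## expand a cluster truth table + corrupt reads into full barcoded reads
.assembleReads <- function(sim, fMid, rMid, config) {
  tg <- rep(sim$targets$sequence, sim$targets$count)
  type <- rep(sim$targets$type, sim$targets$count)
  tgAll <- c(tg, sim$corrupt$target)
  typeAll <- c(type, sim$corrupt$type)
  n <- length(tgAll)
  if (n == 0L)
    return(data.frame(bases = character(0), quals = character(0),
                      type = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  fReal <- .realisePrimer(config$fPrimer, n)
  rReal <- .realisePrimer(config$rPrimer, n)
  bases <- paste0(fMid, fReal, tgAll, .revcomp(rReal), .revcomp(rMid))
  lens <- nchar(bases)
  quals <- strrep("G", lens)  # Q38

  isLq <- typeAll == "low_quality"
  if (any(isLq)) {
    quals[isLq] <- vapply(which(isLq), function(i) {
      l <- lens[i]
      nBad <- ceiling(l * 0.08)
      q <- rep(38L, l)
      q[sample.int(l, nBad)] <- 10L
      .qualString(q)
    }, character(1))
  }
  isShort <- typeAll == "short"
  if (any(isShort)) {
    keepTo <- pmin(200L, lens[isShort])
    bases[isShort] <- substr(bases[isShort], 1L, keepTo)
    quals[isShort] <- substr(quals[isShort], 1L, keepTo)
  }
  isBadMid <- typeAll == "bad_mid"
  if (any(isBadMid)) {
    first <- substr(bases[isBadMid], 1L, 1L)
    repl <- vapply(first, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                   character(1), USE.NAMES = FALSE)
    bases[isBadMid] <- paste0(repl, substring(bases[isBadMid], 2L))
  }
  ## half the reads arrive in reverse-complement orientation
  flip <- sample.int(n, n %/% 2L)
  bases[flip] <- .revcomp(bases[flip])
  quals[flip] <- .revQuals(quals[flip])
  data.frame(bases = bases, quals = quals, type = typeAll, target = tgAll,
             stringsAsFactors = FALSE)
}

## pairwise-distinct 10 bp barcodes (Hamming >= 3)
.makeMids <- function(n) {
  mids <- character(0)
  guard <- 0L
  while (length(mids) < n && guard < 5000L) {
    guard <- guard + 1L
    cand <- paste(sample(c("A", "C", "G", "T"), 10L, replace = TRUE),
                  collapse = "")
    if (all(vapply(mids, .hamming, integer(1), a = cand, USE.NAMES = FALSE) >= 3L))
      mids <- c(mids, cand)
  }
  if (length(mids) < n) stop("could not generate enough distinct MIDs")
  mids
}

#' Simulate a full dual-barcoded amplicon run
#'
#' Draws an allele pool, per-allele efficiencies, per-individual genotypes
#' and two independently noisy amplicon replicates per individual, and
#' returns the read table together with complete truth tables.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `reads` (read table: `read_id`, `bases`,
#'   `quals`), `sampleSheet`, `truth` (list: `reads` per-read provenance,
#'   `clusters` planted cluster table, `genotypes`, `efficiencies`), `pool`,
#'   and `config`.
#' @examples
#' sim <- simulateDataset(simulationConfig(nIndividuals = 2, readsMean = 120,
#'                                         readsSd = 0, readsMin = 120, seed = 7))
#' nrow(sim$reads)
#' @export
simulateDataset <- function(config = simulationConfig()) {
  .seededRNG(config$seed)$run(function() {
    pool <- simulateAllelePool(config$allelePoolSize, config$targetLength,
                               config$divergence)
    eff <- if (!is.null(config$efficiencies)) {
      stopifnot(length(config$efficiencies) == config$allelePoolSize)
      setNames(as.numeric(config$efficiencies), names(pool))
    } else {
      lo <- log(config$efficiencyRange[1])
      hi <- log(config$efficiencyRange[2])
      setNames(exp(runif(config$allelePoolSize, lo, hi)), names(pool))
    }
    genotypes <- if (!is.null(config$genotypes)) {
      stopifnot(length(config$genotypes) == config$nIndividuals)
      config$genotypes
    } else {
      lapply(seq_len(config$nIndividuals), function(i) {
        k <- sample(seq(config$allelesPerIndividual[1],
                        config$allelesPerIndividual[2]), 1L)
        sort(sample(names(pool), k))
      })
    }
    indIds <- sprintf("I%03d", seq_len(config$nIndividuals))
    names(genotypes) <- indIds

    nMid <- ceiling(sqrt(2 * config$nIndividuals)) + 1L
    fMids <- .makeMids(nMid)
    rMids <- .makeMids(nMid)
    combos <- expand.grid(f = seq_len(nMid), r = seq_len(nMid))
    combos <- combos[sample.int(nrow(combos), 2L * config$nIndividuals), ]
    sheet <- data.frame(individual_id = rep(indIds, each = 2L),
                        replicate = rep(1:2, config$nIndividuals),
                        f_mid = fMids[combos$f], r_mid = rMids[combos$r],
                        stringsAsFactors = FALSE)
    sheet <- validateSampleSheet(sheet)

    readRows <- list()
    clusterRows <- list()
    for (i in seq_len(nrow(sheet))) {
      ind <- sheet$individual_id[i]
      rep_ <- sheet$replicate[i]
      amp <- sheet$amplicon[i]
      geno <- pool[genotypes[[ind]]]
      nReads <- round(rnorm(1, config$readsMean, config$readsSd))
      nReads <- min(max(nReads, config$readsMin), config$readsMax)
      sim <- simulateAmplicon(geno, eff[names(geno)], nReads, config)
      reads <- .assembleReads(sim, sheet$f_mid[i], sheet$r_mid[i], config)
      if (nrow(reads)) {
        reads$individual <- ind
        reads$replicate <- rep_
        reads$amplicon <- amp
        readRows[[amp]] <- reads
      }
      ct <- sim$targets
      ct$individual <- ind
      ct$replicate <- rep_
      ct$amplicon <- amp
      clusterRows[[amp]] <- ct
    }
    reads <- do.call(rbind, c(readRows, make.row.names = FALSE))
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    reads$read_id <- sprintf("r%07d", seq_len(nrow(reads)))
    rownames(reads) <- NULL
    clusters <- do.call(rbind, c(clusterRows, make.row.names = FALSE))
    genoTab <- do.call(rbind, lapply(indIds, function(ind)
      data.frame(individual = ind, allele = genotypes[[ind]],
                 sequence = unname(pool[genotypes[[ind]]]),
                 efficiency = unname(eff[genotypes[[ind]]]),
                 stringsAsFactors = FALSE)))
    list(reads = reads[, c("read_id", "bases", "quals", "individual",
                           "replicate", "amplicon", "type", "target")],
         sampleSheet = sheet,
         truth = list(reads = reads[, c("read_id", "amplicon", "type", "target")],
                      clusters = clusters, genotypes = genoTab,
                      efficiencies = eff),
         pool = pool, config = config)
  })
}

#' Write a simulated run to disk
#'
#' Emits FASTQ (Phred+33), the sample sheet, truth tables and a JSON echo of
#' the configuration. Round-trip property: running [filterAmplicons()] and
#' [clusterAmplicons()] on the output reproduces the planted cluster table
#' exactly when all corruption fractions are zero.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeRun <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fastq = file.path(dir, "reads.fastq"),
             sheet = file.path(dir, "sample_sheet.tsv"),
             truth_reads = file.path(dir, "truth_reads.tsv"),
             truth_clusters = file.path(dir, "truth_clusters.tsv"),
             truth_genotypes = file.path(dir, "truth_genotypes.tsv"),
             config = file.path(dir, "config.json"))
  fq <- character(4L * nrow(sim$reads))
  fq[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", sim$reads$read_id)
  fq[c(FALSE, TRUE, FALSE, FALSE)] <- sim$reads$bases
  fq[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  fq[c(FALSE, FALSE, FALSE, TRUE)] <- sim$reads$quals
  writeLines(fq, paths["fastq"])
  sheet <- sim$sampleSheet
  write.table(sheet[, c("individual_id", "replicate", "f_mid", "r_mid")],
              paths["sheet"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$reads, paths["truth_reads"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$clusters, paths["truth_clusters"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genotypes, paths["truth_genotypes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$genotypes <- NULL
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
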