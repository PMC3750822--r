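# Steps II-III: replicate reconciliation, fixed point, census, exclusions.

A <- "AAAAAAAA"; B <- "CCCCCCCC"; C <- "GGGGGGGG"; D <- "TTTTTTTT"
E <- "AACCGGTT"; X <- "ACACACAC"; Z <- "GTGTGTGT"

lblOf <- function(calls, ind, rep, seq) {
  lab <- clusterTable(calls)
  lab$finalLabel[lab$individual == ind & lab$replicate == rep &
                   lab$sequence == seq]
}

test_that("step II: single-replicate 1-2bp and chimera variants are artefacts,
           chimera in both replicates is an artefact", {
  cs <- mkClusterSet(
    mkAmp("i1", 1, c(A, B, C, D), c(50, 30, 4, 3),
          c("TOP", "DIFF_GT2", "DIFF_1_2", "CHIMERA")),
    mkAmp("i1", 2, c(A, B, E), c(55, 25, 5),
          c("TOP", "DIFF_GT2", "CHIMERA")),
    mkAmp("i2", 1, c(A, B, E), c(40, 30, 6),
          c("TOP", "DIFF_GT2", "CHIMERA")),
    mkAmp("i2", 2, c(A, B, E), c(45, 28, 4),
          c("TOP", "DIFF_GT2", "CHIMERA")))
  calls <- callAlleles(cs, floorReads = 10)
  expect_equal(lblOf(calls, "i1", 1, C), "PUTATIVE_ARTEFACT")  # IIa
  expect_equal(lblOf(calls, "i1", 1, D), "PUTATIVE_ARTEFACT")  # IIc single
  expect_equal(lblOf(calls, "i2", 1, E), "PUTATIVE_ARTEFACT")  # IIc both
  expect_equal(lblOf(calls, "i2", 2, E), "PUTATIVE_ARTEFACT")
  ## top clusters present in both replicates, above all artefacts
  expect_equal(lblOf(calls, "i1", 1, A), "PUTATIVE_ALLELE")
  expect_equal(lblOf(calls, "i1", 2, B), "PUTATIVE_ALLELE")
})

test_that("step II/III: >2bp single-replicate variants depend on other
           individuals; below-bar variants are unclassified", {
  cs <- mkClusterSet(
    ## i1: Z is DIFF_GT2 in rep1 only and occurs nowhere else -> artefact
    mkAmp("i1", 1, c(A, B, Z, D), c(50, 30, 3, 5),
          c("TOP", "DIFF_GT2", "DIFF_GT2", "CHIMERA")),
    mkAmp("i1", 2, c(A, B), c(55, 25), c("TOP", "DIFF_GT2")),
    ## i2: X in rep1 only but also clustered in i3 -> not a step II artefact;
    ## in i3, X is an allele, so X becomes UNCLASSIFIED in i2
    mkAmp("i2", 1, c(A, X, D), c(40, 6, 8),
          c("TOP", "DIFF_GT2", "CHIMERA")),
    mkAmp("i2", 2, c(A, E), c(45, 3), c("TOP", "DIFF_1_2")),
    mkAmp("i3", 1, c(X, C), c(30, 2), c("TOP", "DIFF_GT2")),
    mkAmp("i3", 2, c(X, C), c(28, 3), c("TOP", "DIFF_GT2")))
  calls <- callAlleles(cs, floorReads = 10)
  expect_equal(lblOf(calls, "i1", 1, Z), "PUTATIVE_ARTEFACT")
  expect_equal(lblOf(calls, "i2", 1, X), "UNCLASSIFIED")
  expect_equal(lblOf(calls, "i3", 1, X), "PUTATIVE_ALLELE")
  ## i3: C present in both replicates but its frequency (2/30) is below the
  ## bar set by... no artefacts in i3, so C is an allele
  expect_equal(lblOf(calls, "i3", 2, C), "PUTATIVE_ALLELE")
})

test_that("variants below an annotated artefact frequency are UNCLASSIFIED", {
  cs <- mkClusterSet(
    ## D (chimera, single-replicate) is an artefact at 10%; B sits below it
    mkAmp("i1", 1, c(A, D, B), c(80, 10, 5),
          c("TOP", "CHIMERA", "DIFF_GT2")),
    mkAmp("i1", 2, c(A, B), c(90, 4), c("TOP", "DIFF_GT2")),
    ## second individual so B's sequence exists elsewhere (keeps i1 congruent)
    mkAmp("i2", 1, c(B, C), c(50, 40), c("TOP", "DIFF_GT2")),
    mkAmp("i2", 2, c(B, C), c(45, 42), c("TOP", "DIFF_GT2")))
  calls <- callAlleles(cs, floorReads = 10)
  expect_equal(lblOf(calls, "i1", 1, B), "UNCLASSIFIED")
  expect_equal(lblOf(calls, "i1", 2, B), "UNCLASSIFIED")
  expect_equal(lblOf(calls, "i1", 1, A), "PUTATIVE_ALLELE")
})

test_that("natural recombinants: chimera in one replicate, different category
           in the other, present in other individuals -> allele", {
  cs <- mkClusterSet(
    mkAmp("i1", 1, c(A, B, E), c(50, 30, 10),
          c("TOP", "DIFF_GT2", "CHIMERA")),
    mkAmp("i1", 2, c(A, B, E), c(55, 25, 8),
          c("TOP", "DIFF_GT2", "DIFF_GT2")),
    mkAmp("i2", 1, c(E, C), c(40, 30), c("TOP", "DIFF_GT2")),
    mkAmp("i2", 2, c(E, C), c(38, 33), c("TOP", "DIFF_GT2")))
  calls <- callAlleles(cs, floorReads = 10)
  expect_equal(lblOf(calls, "i1", 1, E), "PUTATIVE_ALLELE")
  expect_equal(lblOf(calls, "i2", 1, E), "PUTATIVE_ALLELE")
})

demotionFixture <- function(order = 1:2) {
  amps <- list(
    ## i1: X is DIFF_GT2 in both replicates, initially above all artefacts;
    ## Z (DIFF_GT2, rep1 only, also clustered in i2 where it is an artefact)
    ## becomes a step-III artefact whose frequency tops X -> X demoted
    mkAmp("i1", 1, c(A, Z, X, D), c(60, 10, 6, 4),
          c("TOP", "DIFF_GT2", "DIFF_GT2", "CHIMERA")),
    mkAmp("i1", 2, c(A, X), c(70, 5), c("TOP", "DIFF_GT2")))
  amps2 <- list(
    mkAmp("i2", 1, c(B, Z), c(50, 8), c("TOP", "CHIMERA")),
    mkAmp("i2", 2, c(B, C), c(55, 3), c("TOP", "DIFF_1_2")))
  mkClusterSet(do.call(rbind, list(amps, amps2)[order][[1]]),
               do.call(rbind, list(amps, amps2)[order][[2]]))
}

test_that("a late-classified artefact demotes an allele call at the next pass
           and the fixed point is order-independent", {
  calls <- callAlleles(demotionFixture(), floorReads = 10)
  expect_gt(calls@passes, 1L)
  expect_equal(lblOf(calls, "i1", 1, Z), "PUTATIVE_ARTEFACT")
  expect_equal(lblOf(calls, "i1", 1, X), "UNCLASSIFIED")
  expect_equal(lblOf(calls, "i1", 2, X), "UNCLASSIFIED")
  ## amplicon processing order does not change the outcome
  calls2 <- callAlleles(demotionFixture(order = 2:1), floorReads = 10)
  l1 <- clusterTable(calls)[, c("amplicon", "sequence", "finalLabel")]
  l2 <- clusterTable(calls2)[, c("amplicon", "sequence", "finalLabel")]
  expect_identical(l1[order(l1$amplicon, l1$sequence), ],
                   l2[order(l2$amplicon, l2$sequence), ],
                   ignore_attr = TRUE)
})

test_that("datasets without cross-amplicon interactions settle in one pass", {
  cs <- mkClusterSet(mkAmp("i1", 1, c(A, B), c(50, 30), c("TOP", "DIFF_GT2")),
                     mkAmp("i1", 2, c(A, B), c(45, 35), c("TOP", "DIFF_GT2")))
  calls <- callAlleles(cs, floorReads = 10)
  ## second pass only confirms stability
  expect_lte(calls@passes, 2L)
  expect_equal(lblOf(calls, "i1", 1, A), "PUTATIVE_ALLELE")
})

test_that("low-efficiency census follows the strict-majority rule", {
  mk <- function(ind, seqs1, cnt1, lab1, seqs2, cnt2, lab2)
    list(mkAmp(ind, 1, seqs1, cnt1, lab1), mkAmp(ind, 2, seqs2, cnt2, lab2))
  ## E is an allele in i1 but unclassified (below the artefact bar) in i2-i4
  amps <- c(
    mk("i1", c(A, E), c(50, 20), c("TOP", "DIFF_GT2"),
            c(A, E), c(55, 18), c("TOP", "DIFF_GT2")),
    mk("i2", c(A, D, E), c(80, 10, 3), c("TOP", "CHIMERA", "DIFF_GT2"),
            c(A, E), c(90, 2), c("TOP", "DIFF_GT2")),
    mk("i3", c(A, D, E), c(70, 12, 4), c("TOP", "CHIMERA", "DIFF_GT2"),
            c(A, E), c(85, 3), c("TOP", "DIFF_GT2")),
    mk("i4", c(A, D, E), c(75, 11, 2), c("TOP", "CHIMERA", "DIFF_GT2"),
            c(A, E), c(88, 2), c("TOP", "DIFF_GT2")))
  calls <- callAlleles(do.call(mkClusterSet, amps), floorReads = 10)
  expect_equal(calls@lowEfficiency, E)
  expect_equal(lblOf(calls, "i1", 1, E), "LOW_EFFICIENCY_ALLELE")
  expect_equal(lblOf(calls, "i2", 1, E), "LOW_EFFICIENCY_ALLELE")
  g <- genotypeTable(calls)
  expect_equal(sort(unique(g$label[g$sequence == E])), "LOW_EFFICIENCY_ALLELE")

  ## allele-in-2, unclassified-in-1: stays a plain putative allele
  amps2 <- c(
    mk("i1", c(A, E), c(50, 20), c("TOP", "DIFF_GT2"),
            c(A, E), c(55, 18), c("TOP", "DIFF_GT2")),
    mk("i2", c(A, E), c(60, 25), c("TOP", "DIFF_GT2"),
            c(A, E), c(58, 22), c("TOP", "DIFF_GT2")),
    mk("i3", c(A, D, E), c(75, 11, 2), c("TOP", "CHIMERA", "DIFF_GT2"),
            c(A, E), c(88, 2), c("TOP", "DIFF_GT2")))
  calls2 <- callAlleles(do.call(mkClusterSet, amps2), floorReads = 10)
  expect_length(calls2@lowEfficiency, 0L)
  expect_equal(lblOf(calls2, "i1", 1, E), "PUTATIVE_ALLELE")
})

test_that("final labels are exhaustive and replicate-symmetric", {
  cs <- demotionFixture()
  calls <- callAlleles(cs, floorReads = 10)
  expect_true(all(clusterTable(calls)$finalLabel %in%
                    c("PUTATIVE_ALLELE", "PUTATIVE_ARTEFACT", "UNCLASSIFIED",
                      "LOW_EFFICIENCY_ALLELE")))
  ## swap replicate indices 1 <-> 2
  swapped <- clusterTable(cs)
  swapped$replicate <- ifelse(swapped$replicate == 1L, 2L, 1L)
  swapped$amplicon <- paste(swapped$individual, swapped$replicate, sep = ".")
  callsSw <- callAlleles(new("ClusterSet", clusters = swapped,
                             singletons = singletonTable(cs)), floorReads = 10)
  a <- clusterTable(calls); b <- clusterTable(callsSw)
  a <- a[order(a$individual, a$sequence, a$replicate), ]
  b <- b[order(b$individual, b$sequence, -b$replicate), ]
  expect_equal(a$finalLabel, b$finalLabel)
})

test_that("exclusions: replicate count, read floor, incongruent pairs", {
  ## one replicate only
  cs <- mkClusterSet(mkAmp("solo", 1, c(A, B), c(50, 30), c("TOP", "DIFF_GT2")),
                     mkAmp("ok", 1, c(A, B), c(60, 30), c("TOP", "DIFF_GT2")),
                     mkAmp("ok", 2, c(A, B), c(55, 35), c("TOP", "DIFF_GT2")))
  calls <- callAlleles(cs, floorReads = 10)
  ex <- excludedIndividuals(calls)
  expect_equal(ex$reason[ex$individual == "solo"], "replicate_count")
  expect_false("solo" %in% genotypeTable(calls)$individual)

  ## a 20-read amplicon under the default 100-read floor
  cs2 <- mkClusterSet(mkAmp("thin", 1, c(A, B), c(12, 8), c("TOP", "DIFF_GT2")),
                      mkAmp("thin", 2, c(A, B), c(300, 200), c("TOP", "DIFF_GT2")))
  ex2 <- excludedIndividuals(callAlleles(cs2, floorReads = 100))
  expect_equal(ex2$reason, "low_coverage")

  ## replicates sharing no allele candidate (suspected swap): excluded
  cs3 <- mkClusterSet(mkAmp("mix", 1, c(A, B), c(50, 30), c("TOP", "DIFF_GT2")),
                      mkAmp("mix", 2, c(C, D), c(45, 35), c("TOP", "DIFF_GT2")))
  calls3 <- callAlleles(cs3, floorReads = 10)
  ex3 <- excludedIndividuals(calls3)
  expect_equal(ex3$reason, "incongruent_replicates")
  expect_equal(nrow(genotypeTable(calls3)), 0L)
})

test_that("identical inputs give byte-identical outputs (determinism)", {
  c1 <- callAlleles(demotionFixture(), floorReads = 10)
  c2 <- callAlleles(demotionFixture(), floorReads = 10)
  expect_identical(clusterTable(c1), clusterTable(c2))
  expect_identical(genotypeTable(c1), genotypeTable(c2))
})

test_that("fixed-threshold baseline classifies by frequency and validates t2", {
  cl <- data.frame(frequency = c(0.05, 0.04, 0.30))
  expect_equal(classifyByFrequencyThreshold(cl, 0.0437),
               c("PUTATIVE_ALLELE", "PUTATIVE_ARTEFACT", "PUTATIVE_ALLELE"))
  expect_error(classifyByFrequencyThreshold(cl, 0), "t2")
  expect_error(classifyByFrequencyThreshold(cl, 1.2), "t2")
})
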