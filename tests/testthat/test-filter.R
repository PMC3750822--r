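# Filter cascade: length, demultiplexing, primers, quality, length/frame.

FP <- "TGGACGAGCAAGACGTTCCT"          # plain test primer
RP <- "CGAYCCCGTAGTTGTGTCTG"          # degenerate Y at position 4

test_that("length pre-filter keeps the boundary and counts removals", {
  reads <- data.frame(read_id = c("a", "b"),
                      bases = c(strrep("A", 240), strrep("A", 250)),
                      quals = c(strrep("I", 240), strrep("I", 250)),
                      stringsAsFactors = FALSE)
  out <- filterByLength(reads, filterConfig())
  expect_equal(out$kept$read_id, "b")
  expect_equal(out$removed, 1L)
  empty <- filterByLength(reads[0, ], filterConfig())
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(empty$removed, 0L)
})

test_that("length filter on a constructed 30/70 mixture keeps exactly 70", {
  set.seed(5)
  reads <- data.frame(read_id = sprintf("r%03d", 1:100),
                      bases = c(replicate(30, paste(sample(c("A","C","G","T"), 200,
                                                           TRUE), collapse = "")),
                                replicate(70, paste(sample(c("A","C","G","T"), 290,
                                                           TRUE), collapse = ""))),
                      quals = strrep("I", c(rep(200, 30), rep(290, 70))),
                      stringsAsFactors = FALSE)
  out <- filterByLength(reads[sample.int(100), ], filterConfig())
  expect_equal(nrow(out$kept), 70L)
  expect_equal(out$removed, 30L)
})

test_that("demultiplexing is exact-match on both MIDs and orientation-aware", {
  sheet <- validateSampleSheet(mkSheet(3))
  set.seed(7)
  targets <- replicate(20, randCoding(60))
  tabs <- lapply(seq_len(3), function(i) {
    spec <- sheet[sheet$replicate == 1 & sheet$individual_id ==
                    sprintf("ind%02d", i), ]
    mkReadTable(targets, spec$f_mid, spec$r_mid, FP, RP)
  })
  reads <- do.call(rbind, tabs)
  ## five corrupt-MID reads: one mismatch in the forward MID
  corrupt <- reads[1:5, ]
  substr(corrupt$bases, 1, 1) <- vapply(substr(corrupt$bases, 1, 1),
                                        otherBase, character(1))
  corrupt$read_id <- paste0("bad", 1:5)
  out <- demultiplex(rbind(reads, corrupt), sheet)
  expect_equal(nrow(out$assigned), 60L)
  expect_equal(out$unassigned, 5L)
  expect_equal(unname(table(out$assigned$amplicon)[paste0("ind01", ".1")]), 20L)

  ## a reverse-complemented read is flipped and assigned
  one <- reads[1, ]
  one$bases <- RC(one$bases)
  flip <- demultiplex(one, sheet)
  expect_equal(nrow(flip$assigned), 1L)
  expect_equal(flip$assigned$bases, reads$bases[1])
})

test_that("duplicate MID pairs are a configuration error", {
  sheet <- mkSheet(1)
  sheet$f_mid <- sheet$f_mid[1]
  sheet$r_mid <- sheet$r_mid[1]
  expect_error(validateSampleSheet(sheet), "duplicate MID")
})

test_that("primer matching uses IUPAC semantics with zero mismatches", {
  target <- randCoding(60)
  ## RP has Y (C/T) at position 4; realise it as C
  rpC <- sub("Y", "C", RP, fixed = TRUE)
  seqs <- paste0(FP, target, RC(rpC))
  ok <- stripPrimers(seqs, FP, RP)
  expect_true(ok$ok)
  expect_equal(ok$target, target)
  ## realise Y as T: still accepted
  rpT <- sub("Y", "T", RP, fixed = TRUE)
  expect_true(stripPrimers(paste0(FP, target, RC(rpT)), FP, RP)$ok)
  ## one mismatch at a non-degenerate forward-primer position: rejected
  badF <- paste0(substituteAt(FP, 2, otherBase(substr(FP, 2, 2))), target, RC(rpC))
  expect_false(stripPrimers(badF, FP, RP)$ok)
  ## an N in the primer region never matches
  withN <- paste0(substituteAt(FP, 3, "N"), target, RC(rpC))
  expect_false(stripPrimers(withN, FP, RP)$ok)
})

test_that("a planted 10% corrupted-primer fraction is rejected exactly", {
  set.seed(11)
  targets <- replicate(50, randCoding(60))
  rpC <- sub("Y", "C", RP, fixed = TRUE)
  seqs <- paste0(FP, targets, RC(rpC))
  bad <- 1:5
  seqs[bad] <- paste0(substituteAt(FP, 1, otherBase(substr(FP, 1, 1))),
                      targets[bad], RC(rpC))
  out <- stripPrimers(seqs, FP, RP)
  expect_equal(sum(!out$ok), 5L)
  expect_equal(which(!out$ok), bad)
})

test_that("quality predicate: >= 95% of bases strictly above Q20", {
  q96 <- paste0(strrep("?", 96), strrep("+", 4))    # 96 x Q30, 4 x Q10
  q94 <- paste0(strrep("?", 94), strrep("+", 6))
  q20 <- strrep("5", 100)                           # all exactly Q20
  expect_equal(qualityKeep(c(q96, q94, q20), filterConfig()),
               c(TRUE, FALSE, FALSE))
  ## missing qualities: strict mode rejects, permissive keeps with warning
  expect_false(qualityKeep(NA_character_, filterConfig()))
  expect_warning(keep <- qualityKeep(NA_character_,
                                     filterConfig(strictQuality = FALSE)))
  expect_true(keep)
})

test_that("length/frame check accepts codon indels and rejects frameshifts", {
  base <- randCoding(228)
  del3 <- paste0(substr(base, 1, 100), substr(base, 104, 228))  # in-frame 3bp del
  fs <- paste0(substr(base, 1, 100), substr(base, 102, 228))    # 1 bp frameshift
  expect_true(checkLengthFrame(base, 228, filterConfig()))
  expect_false(checkLengthFrame(fs, 228, filterConfig()))
  ## one-codon deletion is allowed when it stays stop-free
  expect_equal(checkLengthFrame(del3, 228, filterConfig()),
               !grepl("TAA|TAG|TGA",
                      paste(substring(del3, seq(1, 223, 3), seq(3, 225, 3)),
                            collapse = " ")))
  ## an internal stop codon in frame is rejected
  withStop <- paste0(substr(base, 1, 99), "TAA", substr(base, 103, 228))
  expect_false(checkLengthFrame(withStop, 228, filterConfig()))
  ## beyond maxIndelUnits: rejected even if in frame
  del9 <- paste0(substr(base, 1, 100), substr(base, 110, 228))
  expect_false(checkLengthFrame(del9, 228, filterConfig()))
})

test_that("cascade conserves reads, is order-independent, and each simulator
           corruption is removed at its own stage", {
  cfg <- simulationConfig(nIndividuals = 3, allelePoolSize = 6,
                          allelesPerIndividual = c(2, 4),
                          readsMean = 150, readsSd = 0, readsMin = 150,
                          seed = 19)
  sim <- simulateDataset(cfg)
  aset <- filterAmplicons(sim$reads, sim$sampleSheet, cfg$fPrimer, cfg$rPrimer,
                          cfg$targetLength)
  r <- filterReport(aset)
  expect_equal(r$reads_in,
               r$reads_out + r$removed_short + r$removed_bad_mid +
                 r$removed_bad_primer + r$removed_low_quality +
                 r$removed_bad_length_or_frame)
  truthN <- table(sim$reads$type)
  expect_equal(r$removed_short, unname(truthN["short"]))
  expect_equal(r$removed_bad_mid, unname(truthN["bad_mid"]))
  expect_equal(r$removed_low_quality, unname(truthN["low_quality"]))
  expect_equal(r$removed_bad_length_or_frame, unname(truthN["frameshift"]))
  expect_equal(r$reads_out,
               sum(truthN[c("allele", "chimera", "early_error",
                            "distant_error", "singleton_error")]))
  ## order-independence of the kept per-amplicon multisets
  perm <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  aset2 <- filterAmplicons(perm, sim$sampleSheet, cfg$fPrimer, cfg$rPrimer,
                           cfg$targetLength)
  expect_identical(lapply(amplicons(aset), sort), lapply(amplicons(aset2), sort))
})

test_that("re-filtering clean surviving reads changes nothing (idempotence)", {
  cfg <- simulationConfig(nIndividuals = 2, allelePoolSize = 5,
                          allelesPerIndividual = c(2, 3),
                          readsMean = 120, readsSd = 0, readsMin = 120, seed = 23)
  sim <- simulateDataset(cfg)
  aset <- filterAmplicons(sim$reads, sim$sampleSheet, cfg$fPrimer, cfg$rPrimer,
                          cfg$targetLength)
  ## rebuild full reads from the kept targets and run the cascade again
  sheet <- sampleSheet(aset)
  rebuilt <- do.call(rbind, lapply(names(amplicons(aset)), function(a) {
    spec <- sheet[sheet$amplicon == a, ]
    tg <- amplicons(aset)[[a]]
    if (length(tg) == 0) return(NULL)
    mkReadTable(tg, spec$f_mid, spec$r_mid,
                gsub("R", "G", cfg$fPrimer), gsub("W", "A", cfg$rPrimer))
  }))
  aset2 <- filterAmplicons(rebuilt, sheet, cfg$fPrimer, cfg$rPrimer,
                           cfg$targetLength)
  r2 <- filterReport(aset2)
  expect_equal(r2$reads_out, r2$reads_in)
  expect_identical(lapply(amplicons(aset), sort), lapply(amplicons(aset2), sort))
})
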