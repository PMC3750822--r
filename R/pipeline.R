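## End-to-end orchestration: filter -> cluster -> call -> efficiency -> T1,
## with every stage's outputs written before the next starts and a JSON run
## manifest recording seeds, counts and per-individual coverage verdicts.

#' Run the full genotyping pipeline
#'
#' Executes the filter cascade, identical-read clustering, the replicate
#' allele-calling workflow, amplification-efficiency estimation and the
#' per-genotype T1 analysis (resampled on both replicates plus the
#' variable-efficiency simulation), writing stage outputs and a manifest to
#' `outDir`. A genotype is marked `reliable` when both replicates carry at
#' least as many allele-labelled reads as the genotype's resampled T1 (the
#' a-posteriori coverage check); otherwise it is flagged.
#'
#' @param reads read table or FASTQ path.
#' @param sheet sample sheet data.frame or TSV path.
#' @param fPrimer,rPrimer amplification primers.
#' @param expectedLength expected target length (bp).
#' @param outDir output directory.
#' @param filterCfg a [filterConfig()].
#' @param coverageCfg a [coverageConfig()] for the T1 stage (resampling depth
#'   `nSims = 1000` by convention).
#' @param floorReads minimum post-filter reads per amplicon.
#' @param seed global seed (propagated to efficiency restarts and T1).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(reads, sheet, fPrimer, rPrimer, expectedLength,
                        outDir, filterCfg = filterConfig(),
                        coverageCfg = coverageConfig(nSims = 1000L),
                        floorReads = 100L, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ampliTyper",
                   version = as.character(utils::packageVersion("ampliTyper")),
                   seed = seed)

  aset <- filterAmplicons(reads, sheet, fPrimer, rPrimer, expectedLength, filterCfg)
  writeFilterReport(aset, tsv = file.path(outDir, "filter_report.tsv"),
                    json = file.path(outDir, "filter_report.json"))
  manifest$filter <- filterReport(aset)[c("reads_in", "reads_out")]

  cset <- clusterAmplicons(aset)
  writeClusterTable(cset, file.path(outDir, "clusters.tsv"))
  manifest$clusters <- nrow(clusterTable(cset))
  manifest$singletons <- nrow(singletonTable(cset))

  calls <- callAlleles(cset, floorReads = floorReads)
  writeGenotypes(calls, outDir)
  geno <- genotypeTable(calls)
  manifest$individuals_genotyped <- length(unique(geno$individual))
  manifest$alleles <- nrow(alleleRegistry(calls))
  manifest$low_efficiency_alleles <- length(calls@lowEfficiency)
  manifest$excluded <- excludedIndividuals(calls)

  obs <- genotypeObservations(calls)
  eff <- NULL
  if (length(obs) && nrow(geno)) {
    eff <- estimateEfficiencies(obs, seed = seed)
    ref <- intersect(names(relativeEfficiency(eff)), geno$allele)[1L]
    eff <- standardise(eff, ref)
    writeEfficiencies(eff, file.path(outDir, "efficiencies.tsv"))
    manifest$efficiency <- list(reference = ref,
                                logLik = eff@logLik, converged = eff@converged)
  }

  t1rows <- list()
  if (nrow(geno)) {
    cfg <- coverageCfg
    cfg$seed <- seed
    relEff <- if (!is.null(eff)) relativeEfficiency(eff) else NULL
    for (ind in unique(geno$individual)) {
      g <- geno[geno$individual == ind, , drop = FALSE]
      c1 <- setNames(g$reads_rep1, g$allele)
      c2 <- setNames(g$reads_rep2, g$allele)
      res <- t1ResampledGenotype(c1, c2, cfg)
      t1var <- NA_integer_
      if (!is.null(relEff) && all(g$allele %in% names(relEff))) {
        e <- relEff[g$allele]
        t1var <- t1Value(t1Simulated(e / sum(e), cfg, method = "simulated_var_eff"))
      }
      reads12 <- c(sum(g$reads_rep1), sum(g$reads_rep2))
      verdict <- if (!is.na(res$T1) && all(reads12 >= res$T1)) "reliable" else "flagged"
      t1rows[[ind]] <- data.frame(individual = ind, k = nrow(g),
                                  reads_rep1 = reads12[1], reads_rep2 = reads12[2],
                                  T1_resampled_rep1 = res$perReplicate[1],
                                  T1_resampled_rep2 = res$perReplicate[2],
                                  T1_resampled = res$T1,
                                  T1_var_eff = t1var,
                                  dropout_alleles = paste(res$dropout, collapse = ","),
                                  verdict = verdict, stringsAsFactors = FALSE)
    }
    t1tab <- do.call(rbind, c(t1rows, make.row.names = FALSE))
    write.table(t1tab, file.path(outDir, "t1_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$t1 <- list(reliable = sum(t1tab$verdict == "reliable"),
                        flagged = sum(t1tab$verdict == "flagged"))
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(manifest)
}
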