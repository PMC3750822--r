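## Quality-filter cascade: length -> dual-barcode demultiplexing -> primer
## check/strip -> Phred-quality fraction -> target length / reading frame.
## Reads travel as a data.frame with columns read_id, bases, quals so that the
## whole cascade stays vectorised.

#' Filter configuration
#'
#' Parameters of the read-filter cascade. Defaults mirror a 454-style amplicon
#' run targeting a ~290 bp read (barcodes + primers + 228 bp coding target):
#' reads shorter than 250 bp are discarded, a read must have at least 95% of
#' bases with Phred score strictly greater than 20, and only in-frame indels
#' (multiples of 3 bp, at most 2 codons) relative to the expected target
#' length are accepted.
#'
#' @param minReadLength minimum raw read length in bp.
#' @param minQualFraction minimum fraction of bases above `minPhred`.
#' @param minPhred Phred threshold; the predicate is strictly greater-than.
#' @param allowedIndelUnit indel granularity in bp (3 = one codon).
#' @param maxIndelUnits maximal number of indel units either side of the
#'   expected target length.
#' @param strictQuality if TRUE, reads without quality strings are rejected;
#'   otherwise kept with a warning.
#' @return a validated list of class `filter_config`.
#' @export
filterConfig <- function(minReadLength = 250L, minQualFraction = 0.95,
                         minPhred = 20L, allowedIndelUnit = 3L,
                         maxIndelUnits = 2L, strictQuality = TRUE) {
  stopifnot(minQualFraction > 0, minQualFraction <= 1, allowedIndelUnit >= 1,
            minReadLength >= 1, maxIndelUnits >= 0,
            minPhred >= 0, minPhred <= 60)
  structure(list(minReadLength = as.integer(minReadLength),
                 minQualFraction = minQualFraction,
                 minPhred = as.integer(minPhred),
                 allowedIndelUnit = as.integer(allowedIndelUnit),
                 maxIndelUnits = as.integer(maxIndelUnits),
                 strictQuality = strictQuality),
            class = "filter_config")
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Sanger Phred+33 qualities).
#' @return data.frame with columns `read_id`, `bases`, `quals`.
#' @export
readAmpliconFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x),
             bases = as.character(x),
             quals = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Read a sample sheet
#'
#' TSV with columns `individual_id`, `replicate`, `f_mid`, `r_mid`; every
#' individual must appear with exactly two replicates carrying distinct
#' barcode (MID) pairs, and MID pairs must be unique across the sheet.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readSampleSheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  validateSampleSheet(sheet)
}

#' @rdname readSampleSheet
#' @param sheet an in-memory sample sheet data.frame.
#' @export
validateSampleSheet <- function(sheet) {
  need <- c("individual_id", "replicate", "f_mid", "r_mid")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet$replicate <- as.integer(sheet$replicate)
  key <- paste(sheet$f_mid, sheet$r_mid)
  if (anyDuplicated(key))
    stop("duplicate MID pairs in sample sheet: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  reps <- table(sheet$individual_id)
  if (any(nchar(sheet$f_mid) != 10L) || any(nchar(sheet$r_mid) != 10L))
    stop("MIDs must be 10 bp")
  sheet$amplicon <- paste(sheet$individual_id, sheet$replicate, sep = ".")
  attr(sheet, "irregular") <- names(reps)[reps != 2L]
  sheet
}

#' Length pre-filter
#'
#' Removes reads substantially shorter than the expected full read length.
#'
#' @param reads read table (`read_id`, `bases`, `quals`).
#' @param config a [filterConfig()].
#' @return list with `kept` (read table) and `removed` (count).
#' @export
filterByLength <- function(reads, config = filterConfig()) {
  if (nrow(reads) == 0L) return(list(kept = reads, removed = 0L))
  keep <- nchar(reads$bases) >= config$minReadLength
  list(kept = reads[keep, , drop = FALSE], removed = sum(!keep))
}

#' Demultiplex reads by dual barcodes
#'
#' A read is assigned to an amplicon iff its first 10 bases equal that
#' amplicon's forward MID and its last 10 bases equal the reverse complement
#' of the reverse MID, exactly (0 mismatches). Reads are also searched in
#' reverse-complement orientation and flipped to the forward orientation on a
#' match. Unassigned reads are counted, not errors.
#'
#' @param reads read table.
#' @param sheet validated sample sheet (see [validateSampleSheet()]).
#' @return list: `assigned` (read table with `amplicon`, `individual`,
#'   `replicate` columns), `unassigned` (count).
#' @export
demultiplex <- function(reads, sheet) {
  sheet <- if (is.null(sheet$amplicon)) validateSampleSheet(sheet) else sheet
  keyOf <- function(seqs) {
    n <- nchar(seqs)
    paste(substr(seqs, 1L, 10L), substring(seqs, n - 9L, n))
  }
  specKey <- paste(sheet$f_mid, .revcomp(sheet$r_mid))
  if (nrow(reads) == 0L) {
    empty <- cbind(reads, amplicon = character(0), individual = character(0),
                   replicate = integer(0))
    return(list(assigned = empty, unassigned = 0L))
  }
  fwd <- match(keyOf(reads$bases), specKey)
  rcBases <- .revcomp(reads$bases)
  rev <- match(keyOf(rcBases), specKey)
  useRev <- is.na(fwd) & !is.na(rev)
  reads$bases[useRev] <- rcBases[useRev]
  reads$quals[useRev] <- .revQuals(reads$quals[useRev])
  hit <- ifelse(is.na(fwd), rev, fwd)
  ok <- !is.na(hit)
  assigned <- reads[ok, , drop = FALSE]
  assigned$amplicon <- sheet$amplicon[hit[ok]]
  assigned$individual <- sheet$individual_id[hit[ok]]
  assigned$replicate <- sheet$replicate[hit[ok]]
  list(assigned = assigned, unassigned = sum(!ok))
}

#' Check and strip primers
#'
#' After MID removal, both primer regions must match with zero mismatches
#' under IUPAC semantics (a degenerate primer letter matches any base of its
#' set; an N in the read matches nothing). Matching reads are reduced to the
#' bare target insert.
#'
#' @param seqs character vector of MID-stripped read sequences.
#' @param fPrimer,rPrimer primer sequences (IUPAC letters allowed); `rPrimer`
#'   is given in its own 5'->3' orientation and matched as its reverse
#'   complement at the 3' end of the read.
#' @return list: `target` (character, NA where rejected), `ok` (logical).
#' @export
stripPrimers <- function(seqs, fPrimer, rPrimer) {
  fLen <- nchar(fPrimer)
  rLen <- nchar(rPrimer)
  rcR <- .revcomp(rPrimer)
  fRe <- paste0("^", .iupacRegex(fPrimer))
  rRe <- paste0(.iupacRegex(rcR), "$")
  ok <- nchar(seqs) > fLen + rLen & grepl(fRe, seqs) & grepl(rRe, seqs)
  target <- rep(NA_character_, length(seqs))
  target[ok] <- substr(seqs[ok], fLen + 1L, nchar(seqs[ok]) - rLen)
  list(target = target, ok = ok)
}

#' Phred-quality filter predicate
#'
#' Keep iff the fraction of bases with Phred score strictly greater than
#' `config$minPhred` is at least `config$minQualFraction`.
#'
#' @param quals character vector of Phred+33 quality strings (NA = missing).
#' @param config a [filterConfig()].
#' @return logical keep vector.
#' @export
qualityKeep <- function(quals, config = filterConfig()) {
  missing <- is.na(quals) | quals == ""
  keep <- logical(length(quals))
  if (any(!missing))
    keep[!missing] <- .fracAbovePhred(quals[!missing], config$minPhred) >=
      config$minQualFraction
  if (any(missing)) {
    if (config$strictQuality) {
      keep[missing] <- FALSE
    } else {
      warning(sum(missing), " reads without qualities kept (permissive mode)")
      keep[missing] <- TRUE
    }
  }
  keep
}

#' Target length and reading-frame filter predicate
#'
#' Keep iff the target length differs from the expected length by a multiple
#' of `allowedIndelUnit` bp (at most `maxIndelUnits` units, so frameshifts are
#' rejected) and the fixed-frame translation contains no internal stop codon.
#' The stop-codon rule is an automated proxy for visual reading-frame
#' inspection of a coding exon.
#'
#' @param targets character vector of primer-stripped target sequences.
#' @param expectedLength expected target length in bp.
#' @param config a [filterConfig()].
#' @return logical keep vector.
#' @export
checkLengthFrame <- function(targets, expectedLength, config = filterConfig()) {
  d <- nchar(targets) - expectedLength
  unit <- config$allowedIndelUnit
  okLen <- d %% unit == 0L & abs(d) <= config$maxIndelUnits * unit
  keep <- okLen
  if (any(okLen)) keep[okLen] <- !.hasInternalStop(targets[okLen])
  keep
}

#' Run the full filter cascade
#'
#' Applies, in order: length pre-filter, dual-MID demultiplexing, primer
#' check/strip, Phred-quality filter, and target length/reading-frame check,
#' and returns per-amplicon filtered target sequences plus a per-stage
#' attrition report.
#'
#' @param reads read table (see [readAmpliconFastq()]) or a FASTQ path.
#' @param sheet sample sheet data.frame or TSV path.
#' @param fPrimer,rPrimer amplification primers (IUPAC allowed).
#' @param expectedLength expected target (insert) length in bp.
#' @param config a [filterConfig()].
#' @return an [AmpliconSet-class] object.
#' @examples
#' sim <- simulateDataset(simulationConfig(nIndividuals = 2, seed = 1))
#' aset <- filterAmplicons(sim$reads, sim$sampleSheet,
#'                         sim$config$fPrimer, sim$config$rPrimer,
#'                         sim$config$targetLength)
#' filterReport(aset)$reads_out
#' @export
filterAmplicons <- function(reads, sheet, fPrimer, rPrimer, expectedLength,
                            config = filterConfig()) {
  if (is.character(reads) && length(reads) == 1L) reads <- readAmpliconFastq(reads)
  if (is.character(sheet) && length(sheet) == 1L) sheet <- readSampleSheet(sheet)
  sheet <- if (is.null(sheet$amplicon)) validateSampleSheet(sheet) else sheet

  nIn <- nrow(reads)
  st1 <- filterByLength(reads, config)
  st2 <- demultiplex(st1$kept, sheet)
  asn <- st2$assigned
  n <- nchar(asn$bases)
  noMid <- substr(asn$bases, 11L, pmax(n - 10L, 10L))
  st3 <- stripPrimers(noMid, fPrimer, rPrimer)
  badPrimer <- sum(!st3$ok)
  asn <- asn[st3$ok, , drop = FALSE]
  asn$target <- st3$target[st3$ok]
  keepQ <- qualityKeep(asn$quals, config)
  badQual <- sum(!keepQ)
  asn <- asn[keepQ, , drop = FALSE]
  keepL <- checkLengthFrame(asn$target, expectedLength, config)
  badLen <- sum(!keepL)
  asn <- asn[keepL, , drop = FALSE]

  seqs <- lapply(split(asn$target, factor(asn$amplicon, levels = sheet$amplicon)),
                 as.character)
  report <- list(reads_in = nIn,
                 removed_short = st1$removed,
                 removed_bad_mid = st2$unassigned,
                 removed_bad_primer = badPrimer,
                 removed_low_quality = badQual,
                 removed_bad_length_or_frame = badLen,
                 reads_out = nrow(asn),
                 per_amplicon = vapply(seqs, length, integer(1)))
  new("AmpliconSet", sequences = seqs, sampleSheet = sheet,
      report = report, config = unclass(config))
}

#' Write a filter report
#'
#' @param aset an [AmpliconSet-class].
#' @param tsv,json output paths (either may be NULL).
#' @return invisibly, the report list.
#' @export
writeFilterReport <- function(aset, tsv = NULL, json = NULL) {
  r <- filterReport(aset)
  if (!is.null(tsv)) {
    flat <- data.frame(stage = setdiff(names(r), "per_amplicon"),
                       reads = unlist(r[setdiff(names(r), "per_amplicon")]))
    write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(r, json, auto_unbox = TRUE, digits = NA)
  invisible(r)
}
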