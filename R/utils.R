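# Internal string/sequence helpers shared across modules.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

## Reverse complement of a character vector of DNA strings (IUPAC letters allowed).
.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Reverse a vector of quality strings (for reads flipped to the forward
## orientation); constant strings are their own reversal and skipped.
.revQuals <- function(x) {
  if (length(x) == 0L) return(x)
  const <- x == strrep(substr(x, 1L, 1L), nchar(x))
  todo <- which(!const)
  if (length(todo))
    x[todo] <- vapply(strsplit(x[todo], ""),
                      function(ch) paste(rev(ch), collapse = ""), character(1))
  x
}

## Translate an IUPAC-degenerate primer into an anchored-free regular expression.
## Each degenerate letter becomes a character class over its base set; plain
## A/C/G/T stay literal.  Read bases must be concrete (an N in the read never
## matches, because N is not a member of any primer letter's base set).
.iupacRegex <- function(primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  letters <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(letters, names(map))
  if (length(bad))
    stop("primer contains non-IUPAC letters: ", paste(unique(bad), collapse = ", "))
  parts <- vapply(letters, function(l) {
    set <- map[[l]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1))
  paste(parts, collapse = "")
}

## Phred+33 quality strings -> list of integer vectors.
.phredInts <- function(qualStrings) {
  lapply(qualStrings, function(q) utf8ToInt(q) - 33L)
}

## Fraction of bases with Phred strictly greater than `minPhred`, per read.
## Computed on unique strings only (runs share few distinct quality profiles).
.fracAbovePhred <- function(qualStrings, minPhred) {
  uq <- unique(qualStrings)
  fr <- vapply(uq, function(q) {
    ph <- utf8ToInt(q) - 33L
    if (length(ph) == 0L) return(0)
    mean(ph > minPhred)
  }, numeric(1), USE.NAMES = FALSE)
  fr[match(qualStrings, uq)]
}

.qualString <- function(phred) intToUtf8(phred + 33L)

## TRUE where the in-frame translation (frame 1) contains an internal stop codon.
## Codons with N are never counted as stops.  Vectorised by grouping on length.
.hasInternalStop <- function(seqs) {
  out <- logical(length(seqs))
  if (length(seqs) == 0L) return(out)
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    ncod <- L %/% 3L
    if (ncod == 0L) next
    hit <- logical(length(idx))
    sub <- seqs[idx]
    for (j in seq_len(ncod)) {
      codon <- substr(sub, 3L * j - 2L, 3L * j)
      hit <- hit | codon %in% .STOP_CODONS
    }
    out[idx] <- hit
  }
  out
}

## Hamming distance between two equal-length strings.
.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Longest common prefix / suffix length of two strings.
.lcpLen <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

.lcsLen <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

## A self-contained seeded RNG stream that leaves the global RNG untouched.
.seededRNG <- function(seed) {
  state <- NULL
  run <- function(f) {
    glob <- globalenv()
    old <- if (exists(".Random.seed", envir = glob, inherits = FALSE))
      get(".Random.seed", envir = glob) else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = glob)
    on.exit({
      state <<- get(".Random.seed", envir = glob)
      if (is.null(old)) rm(".Random.seed", envir = glob)
      else assign(".Random.seed", old, envir = glob)
    })
    f()
  }
  list(norm = function(n, sd = 1) run(function() rnorm(n, 0, sd)),
       run = run)
}
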