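## Six-frame ORF prediction (stop-to-stop, getorf-default semantics) and
## codon-table translation. Coordinates are 0-based half-open on the
## forward strand; frames 1-3 forward, 4-6 reverse.

.STOPS <- c("TAA", "TAG", "TGA")

#' Translate a nucleotide sequence with the standard or bacterial code
#'
#' Explicit per-codon lookup so ambiguous codons (any non-ACGT base) are
#' emitted as `'X'` with a warning rather than an error. The standard
#' (table 1) and bacterial (table 11) codes share all sense/stop codons
#' and differ only in which codons may initiate (handled by
#' [findOrfs()]'s `require_start` mode); internal stops translate to `*`.
#'
#' @param nt nucleotide string, length a multiple of 3.
#' @param genetic_code `"standard"` or `"bacterial"`.
#' @return amino-acid string.
#' @examples
#' translateSequence("ATGAAA")  # "MK"
#' @export
translateSequence <- function(nt, genetic_code = c("standard", "bacterial")) {
  genetic_code <- match.arg(genetic_code)
  nt <- toupper(as.character(nt))
  if (nchar(nt) %% 3L != 0L)
    stop("sequence length must be a multiple of 3", call. = FALSE)
  code <- Biostrings::getGeneticCode(
    if (genetic_code == "standard") "1" else "11")
  starts <- seq(1L, nchar(nt), by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- code[codons]
  if (anyNA(aa)) {
    warning(sprintf("%d ambiguous codon(s) translated as 'X'",
                    sum(is.na(aa))), call. = FALSE)
    aa[is.na(aa)] <- "X"
  }
  paste(aa, collapse = "")
}

.startCodons <- function(genetic_code) {
  if (genetic_code == "standard") "ATG" else c("ATG", "GTG", "TTG")
}

## ORFs in one reading direction of one plain sequence.
## Returns codon-index intervals [from, to] (1-based, inclusive) per frame.
.orfRunsOneStrand <- function(s, min_codons, require_start, starts_ok) {
  L <- nchar(s)
  out <- list()
  for (off in 0:2) {
    ncod <- (L - off) %/% 3L
    if (ncod < 1L) next
    pos <- off + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(s, pos, pos + 2L)
    is_stop <- codons %in% .STOPS
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i]) next                 # run of stops
      from <- begins[i]; to <- ends[i]
      if (require_start) {
        hit <- which(codons[from:to] %in% starts_ok)
        if (!length(hit)) next
        from <- from + hit[1] - 1L
      }
      if (to - from + 1L < min_codons) next
      out[[length(out) + 1L]] <-
        list(offset = off, from = from, to = to,
             codons = codons[from:to])
    }
  }
  out
}

#' Six-frame open reading frame prediction
#'
#' Reports, in all six frames of each input sequence, every maximal
#' stop-free codon stretch of at least `min_len` nucleotides (the getorf
#' default: stretches bounded by stop codons or by the sequence ends,
#' neither flanking stop counted). With `require_start = TRUE` each
#' stretch is trimmed to its first start codon (ATG under the standard
#' code; ATG/GTG/TTG under the bacterial code) before the length test.
#'
#' @param sequences named character vector or `DNAStringSet` of unigene
#'   sequences over A/C/G/T/N (ambiguous codons are never stops and
#'   translate as `X`).
#' @param min_len minimum ORF length in nucleotides (inclusive; default
#'   600).
#' @param genetic_code `"standard"` or `"bacterial"`.
#' @param require_start report only start-anchored ORFs (default FALSE,
#'   the getorf stop-to-stop mode).
#' @return data.frame with one row per ORF: `unigene_id`, `orf_id`,
#'   `frame` (1-3 forward, 4-6 reverse), `start`, `end` (0-based
#'   half-open, forward strand), `nt_length`, `protein`, `genetic_code`.
#'   Sequences shorter than `min_len` simply contribute no rows.
#' @export
findOrfs <- function(sequences, min_len = 600,
                     genetic_code = c("standard", "bacterial"),
                     require_start = FALSE) {
  genetic_code <- match.arg(genetic_code)
  assertScalarNumeric(min_len, "min_len", lower = 3)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  min_codons <- ceiling(min_len / 3)
  starts_ok <- .startCodons(genetic_code)
  code <- Biostrings::getGeneticCode(
    if (genetic_code == "standard") "1" else "11")

  rows <- list()
  for (id in names(sequences)) {
    s <- toupper(sequences[[id]])
    L <- nchar(s)
    n_orf <- 0L
    collect <- function(runs, reverse) {
      for (r in runs) {
        nt_from <- r$offset + 3L * (r$from - 1L)        # 0-based
        nt_to <- r$offset + 3L * r$to                   # half-open
        if (reverse) { tmp <- nt_from; nt_from <- L - nt_to; nt_to <- L - tmp }
        aa <- unname(code[r$codons])
        aa[is.na(aa)] <- "X"
        n_orf <<- n_orf + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          unigene_id = id,
          orf_id = sprintf("%s_orf%d", id, n_orf),
          frame = r$offset + 1L + if (reverse) 3L else 0L,
          start = nt_from, end = nt_to,
          nt_length = nt_to - nt_from,
          protein = paste(aa, collapse = ""),
          genetic_code = genetic_code,
          stringsAsFactors = FALSE)
      }
    }
    collect(.orfRunsOneStrand(s, min_codons, require_start, starts_ok),
            reverse = FALSE)
    collect(.orfRunsOneStrand(revComp(s), min_codons, require_start,
                              starts_ok), reverse = TRUE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unigene_id = character(), orf_id = character(),
               frame = integer(), start = integer(), end = integer(),
               nt_length = integer(), protein = character(),
               genetic_code = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
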