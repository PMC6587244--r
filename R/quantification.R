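## k-mer pseudo-mapping of reads to unigenes, FPKM computation, and
## base-quality summaries of FASTQ input.

.kmerize <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character(0))
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

#' Assign reads to unigenes by unique k-mer ownership
#'
#' Builds an index of which gene(s) each k-mer occurs in. A read is
#' assigned to a gene iff every one of its k-mers occurs in exactly that
#' one gene; reads with k-mers shared across genes, absent from the
#' index, or resolving differently in the two orientations are
#' unassigned. Each assigned single-end read counts as one fragment.
#'
#' @param reads character vector of read sequences (or the data.frame
#'   from [generateReads()], whose `seq` column is used).
#' @param unigenes `DNAStringSet` or named character vector of gene
#'   sequences.
#' @param k k-mer size (<= read length; default 31).
#' @return integer vector of fragment counts per gene (named as
#'   `unigenes`), with attributes `assigned` (per-read gene or NA) and
#'   `mapping_rate` (percent of reads assigned).
#' @export
pseudoMap <- function(reads, unigenes, k = 31L) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (methods::is(unigenes, "DNAStringSet"))
    unigenes <- stats::setNames(as.character(unigenes), names(unigenes))
  if (!length(unigenes)) stop("empty unigene index", call. = FALSE)
  k <- assertCount(k, "k", min = 4L)
  if (length(reads) && any(nchar(reads) < k))
    stop("'k' exceeds the shortest read length", call. = FALSE)

  ## k-mer -> owning gene; multi-gene k-mers marked ""
  km <- lapply(unigenes, function(s) unique(.kmerize(toupper(s), k)))
  owner <- rep(names(unigenes), lengths(km))
  kmer <- unlist(km, use.names = FALSE)
  dup <- kmer %in% kmer[duplicated(kmer)]
  owner[dup] <- ""
  index <- stats::setNames(owner, kmer)

  resolve <- function(s) {
    ks <- .kmerize(s, k)
    own <- index[ks]
    if (anyNA(own) || any(own == "")) return(NA_character_)
    u <- unique(own)
    if (length(u) == 1L) u else NA_character_
  }
  assigned <- vapply(reads, function(r) {
    r <- toupper(r)
    a <- resolve(r)
    if (is.na(a)) {
      b <- resolve(revComp(r))
      a <- b
    }
    a
  }, character(1), USE.NAMES = FALSE)

  counts <- table(factor(assigned, levels = names(unigenes)))
  out <- stats::setNames(as.integer(counts), names(unigenes))
  attr(out, "assigned") <- assigned
  attr(out, "mapping_rate") <-
    if (length(reads)) 100 * mean(!is.na(assigned)) else NA_real_
  out
}

#' Compute FPKM from fragment counts
#'
#' `FPKM = fragments / ((length / 1000) x (library / 1e6))` -- fragments
#' per kilobase of transcript per million mapped fragments. By the RSEM
#' convention the library size is the total of assigned fragments; pass
#' total input fragments to switch conventions.
#'
#' @param counts named integer vector (or one column of
#'   [generateCounts()] output) of fragments per gene.
#' @param lengths gene lengths in nt, aligned with `counts`.
#' @param library total mapped fragments (> 0); default `sum(counts)`.
#' @return data.frame: `gene_id`, `length`, `fragments`, `FPKM`.
#' @export
computeFpkm <- function(counts, lengths, library = sum(counts)) {
  if (length(counts) != length(lengths))
    stop("'counts' and 'lengths' must align", call. = FALSE)
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (!is.numeric(library) || length(library) != 1L || library <= 0)
    stop("'library' must be > 0", call. = FALSE)
  fpkm <- counts / ((lengths / 1000) * (library / 1e6))
  data.frame(gene_id = if (is.null(names(counts)))
    sprintf("g%d", seq_along(counts)) else names(counts),
    length = lengths, fragments = as.integer(counts), FPKM = fpkm,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Base-quality and GC summary of FASTQ reads
#'
#' Q20/Q30 are the percentages of bases with Phred+33 quality at or
#' above 20/30; GC is the percentage of G or C bases. Q30 can never
#' exceed Q20.
#'
#' @param path FASTQ file path.
#' @return named numeric vector: `Q20`, `Q30`, `GC` (percent), `bases`.
#' @export
readQc <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ: %d lines (not a multiple of 4)",
                 length(lines)), call. = FALSE)
  n <- length(lines) / 4L
  for (i in seq_len(n)) {
    at <- 4L * (i - 1L)
    if (!startsWith(lines[at + 1L], "@"))
      stop(sprintf("malformed FASTQ at line %d: header must start with '@'",
                   at + 1L), call. = FALSE)
    if (!startsWith(lines[at + 3L], "+"))
      stop(sprintf("malformed FASTQ at line %d: separator must start with '+'",
                   at + 3L), call. = FALSE)
    if (nchar(lines[at + 2L]) != nchar(lines[at + 4L]))
      stop(sprintf("malformed FASTQ at line %d: sequence/quality length mismatch",
                   at + 4L), call. = FALSE)
  }
  seqs <- paste(lines[seq(2L, length(lines), by = 4L)], collapse = "")
  quals <- paste(lines[seq(4L, length(lines), by = 4L)], collapse = "")
  q <- as.integer(charToRaw(quals)) - 33L
  bases <- strsplit(seqs, "")[[1]]
  c(Q20 = 100 * mean(q >= 20L),
    Q30 = 100 * mean(q >= 30L),
    GC = 100 * mean(bases %in% c("G", "C", "g", "c")),
    bases = length(q))
}
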