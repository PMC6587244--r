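## Unigene synthesis: embed each planted ORF intact in its requested
## reading frame, bounded by in-frame stop codons (or the sequence ends
## when no flank is requested), with a configurable fraction of genes
## truncated below the 600-nt ORF filter boundary. Also simulates
## single-end reads from the unigenes for the pseudo-mapper.

## inverse codon table (standard code, stops excluded)
.codonChoices <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc1 <- Biostrings::getGeneticCode("1")
      gc1 <- gc1[gc1 != "*"]
      code <<- split(names(gc1), unname(gc1))
    }
    code
  }
})

.randomAa <- function(n) {
  paste(sample(names(.codonChoices()), n, replace = TRUE), collapse = "")
}

.reverseTranslate <- function(protein) {
  ch <- .codonChoices()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- ch[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

.randomNt <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate unigene sequences carrying the planted ORFs
#'
#' For every gene in the truth object, draws a protein of the recorded
#' length with the family's motif consensus planted at the recorded
#' domain interval, reverse-translates it, and embeds the resulting ORF
#' in the requested frame: random flanks of about `flank_len` nt on each
#' side whose three terminal nucleotides are in-frame stop codons (left
#' flank is padded by 0-2 nt to realise the frame). Genes with frames
#' 4-6 are emitted reverse-complemented. With `flank_len = 0` the unigene
#' is the bare ORF (its maximality then comes from the sequence ends) and
#' the realised frame is 1 or 4. A `frag_fraction` share of genes is
#' truncated so that at most 597 nt of ORF remain, to exercise the
#' 600-nt minimum-length filter downstream.
#'
#' @param truth a [CommunityTruth-class].
#' @param flank_len flank length in nt, 0 or >= 3 (the bounding stop
#'   codon occupies the flank's inner 3 nt). Default 60.
#' @param frag_fraction fraction of genes truncated below 600 nt of ORF
#'   (default 0).
#' @param seed integer seed.
#' @return list with `sequences` (a `DNAStringSet`, one unigene per
#'   gene) and `truth` (data.frame: `gene_id`, `unigene_id`, `frame`,
#'   `orf_start`, `orf_end` 0-based half-open on the forward strand,
#'   `orf_nt_length`, `protein`, `truncated`, `cazy_family`,
#'   `lineage`).
#' @export
generateUnigenes <- function(truth, flank_len = 60, frag_fraction = 0,
                             seed = 1L) {
  stopifnot(is(truth, "CommunityTruth"))
  assertScalarNumeric(flank_len, "flank_len", lower = 0)
  if (flank_len > 0 && flank_len < 3)
    stop("'flank_len' must be 0 or >= 3 (it embeds the bounding stop)",
         call. = FALSE)
  assertScalarNumeric(frag_fraction, "frag_fraction", lower = 0, upper = 1)

  genes <- communityGenes(truth)
  taxa <- communityTaxa(truth)
  models <- builtinDomainModels()

  withSeed(seed, {
    n <- nrow(genes)
    trunc_idx <- if (frag_fraction > 0)
      sample.int(n, floor(frag_fraction * n)) else integer(0)

    seqs <- character(n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- genes[i, ]
      aa_len <- g$orf_nt_length / 3L
      prot <- strsplit(.randomAa(aa_len), "")[[1]]
      fam <- g$cazy_family
      if (!is.na(fam) && !is.null(models[[fam]])) {
        cons <- strsplit(models[[fam]]$consensus, "")[[1]]
        at <- if (!is.na(g$cd_start)) g$cd_start else g$cbm_start
        if (!is.na(at))
          prot[at:(at + length(cons) - 1L)] <- cons
      }
      prot <- paste(prot, collapse = "")
      orf_nt <- .reverseTranslate(prot)
      orf_len <- nchar(orf_nt)

      d0 <- (g$frame - 1L) %% 3L                 # frame offset 0..2
      if (flank_len == 0) {
        left <- ""; right <- ""
        d0 <- 0L
      } else {
        left_len <- flank_len + ((d0 - flank_len) %% 3L)
        left <- paste0(.randomNt(left_len - 3L), "TAA")
        right <- paste0("TGA", .randomNt(flank_len - 3L))
      }
      construct <- paste0(left, orf_nt, right)
      orf_from <- nchar(left)                    # 0-based in construct

      truncated <- i %in% trunc_idx
      if (truncated) {
        keep_orf <- min(orf_len, 597L)
        construct <- substr(construct, 1L, orf_from + keep_orf)
        orf_len <- keep_orf
        prot <- substr(prot, 1L, keep_orf %/% 3L)
      }

      L <- nchar(construct)
      reverse <- g$frame >= 4L
      if (reverse) {
        seqs[i] <- revComp(construct)
        orf_start <- L - (orf_from + orf_len)
        orf_end <- L - orf_from
      } else {
        seqs[i] <- construct
        orf_start <- orf_from
        orf_end <- orf_from + orf_len
      }
      frame <- d0 + 1L + if (reverse) 3L else 0L
      if (flank_len == 0) frame <- if (reverse) 4L else 1L

      rows[[i]] <- data.frame(
        gene_id = g$gene_id,
        unigene_id = sprintf("u%04d", i),
        frame = frame, orf_start = orf_start, orf_end = orf_end,
        orf_nt_length = orf_len, protein = prot, truncated = truncated,
        cazy_family = fam,
        lineage = taxa$lineage[g$taxon_index],
        stringsAsFactors = FALSE)
    }
    tt <- do.call(rbind, rows)
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- tt$unigene_id
    list(sequences = ss, truth = tt)
  })
}

#' Simulate single-end reads from unigene sequences
#'
#' Uniform-position, random-strand, error-free reads with truth-tracked
#' origins, plus Phred+33 quality strings drawn uniformly from a given
#' quality range (for Q20/Q30 summaries).
#'
#' @param sequences `DNAStringSet` of unigenes.
#' @param n_reads number of reads.
#' @param read_len read length (sequences shorter than this are skipped).
#' @param seed integer seed.
#' @param weights per-sequence sampling weights (default proportional to
#'   length, the shotgun convention).
#' @param qual_range integer Phred range for per-base qualities, default
#'   `c(20, 40)`.
#' @return data.frame: `read_id`, `origin`, `strand`, `seq`, `qual`.
#' @export
generateReads <- function(sequences, n_reads, read_len = 100, seed = 1L,
                          weights = NULL, qual_range = c(20L, 40L)) {
  n_reads <- assertCount(n_reads, "n_reads")
  lens <- Biostrings::width(sequences)
  ok <- lens >= read_len
  if (!any(ok)) stop("no sequence is at least 'read_len' long",
                     call. = FALSE)
  if (is.null(weights)) weights <- lens
  weights <- weights * ok
  withSeed(seed, {
    pick <- sample.int(length(sequences), n_reads, replace = TRUE,
                       prob = weights)
    starts <- vapply(pick, function(i)
      sample.int(lens[i] - read_len + 1L, 1L), integer(1))
    frag <- as.character(Biostrings::subseq(sequences[pick], start = starts,
                                            width = read_len))
    rev <- runif(n_reads) < 0.5
    frag[rev] <- revComp(frag[rev])
    quals <- vapply(seq_len(n_reads), function(i)
      rawToChar(as.raw(33L + sample(qual_range[1]:qual_range[2], read_len,
                                    replace = TRUE))), character(1))
    data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
               origin = names(sequences)[pick],
               strand = ifelse(rev, "-", "+"),
               seq = unname(frag), qual = quals, stringsAsFactors = FALSE)
  })
}

#' Write simulated reads as FASTQ
#' @param reads data.frame from [generateReads()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n",
                    reads$qual), con)
  invisible(path)
}
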