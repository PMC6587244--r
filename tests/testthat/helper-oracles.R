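## Independent oracles and fixture builders used across the suite.
## These deliberately re-derive results with different algorithms than
## the package (per-codon walks, ancestor-set intersection, cophenetic
## comparison) so agreement is meaningful.

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

## Brute-force six-frame ORF scan: walk codons one by one on each
## strand, cut at stops, report (frame, nt_length, protein) plus a
## substring-verified forward-strand interval.
bruteForceOrfs <- function(seq, min_len = 600) {
  stops <- c("TAA", "TAG", "TGA")
  code <- Biostrings::getGeneticCode("1")
  out <- list()
  for (strand in 1:2) {
    s <- if (strand == 1) toupper(seq) else rc(toupper(seq))
    L <- nchar(s)
    for (off in 0:2) {
      i <- off + 1L
      run <- character(0)
      run_start <- i
      flush <- function(endpos) {
        if (length(run) * 3L >= min_len) {
          aa <- code[run]
          aa[is.na(aa)] <- "X"
          fr <- off + 1L + if (strand == 2) 3L else 0L
          ## forward-strand 0-based half-open interval
          s0 <- run_start - 1L
          e0 <- s0 + 3L * length(run)
          if (strand == 2) { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
          out[[length(out) + 1L]] <<- data.frame(
            frame = fr, start = s0, end = e0,
            nt_length = 3L * length(run),
            protein = paste(aa, collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
      while (i + 2L <= L) {
        cod <- substr(s, i, i + 2L)
        if (cod %in% stops) {
          flush(i - 1L)
          run <- character(0)
          run_start <- i + 3L
        } else run <- c(run, cod)
        i <- i + 3L
      }
      flush(i - 1L)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), nt_length = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$frame, df$start), , drop = FALSE]
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

## LCA oracle: resolve each lineage to a node by walking the node table,
## intersect full ancestor sets, return the deepest member.
lcaOracle <- function(tree, lineages) {
  nd <- taxonomyNodes(tree)
  resolve <- function(lin) {
    cur <- taxonomyRoot(tree)
    for (p in strsplit(lin, ";", fixed = TRUE)[[1]]) {
      nxt <- nd$id[!is.na(nd$parent) & nd$parent == cur & nd$name == p]
      if (length(nxt) != 1L) return(NA_integer_)
      cur <- nxt
    }
    cur
  }
  ancestors <- function(id) {
    out <- id
    while (!is.na(nd$parent[match(id, nd$id)])) {
      id <- nd$parent[match(id, nd$id)]
      out <- c(out, id)
    }
    out
  }
  depth <- function(id) length(ancestors(id))
  ids <- vapply(lineages, resolve, integer(1))
  ids <- ids[!is.na(ids)]
  if (!length(ids)) return(NA_integer_)
  common <- Reduce(intersect, lapply(ids, ancestors))
  common[which.max(vapply(common, depth, integer(1)))]
}

## Random toy taxonomy: lineages drawn from small per-rank label pools,
## so shared prefixes (and hence nontrivial LCAs) occur often.
randomLineages <- function(n, pool_sizes = c(2, 3, 3, 4, 4, 5)) {
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_along(pool_sizes), function(r)
      sprintf("r%d_%d", r, sample.int(pool_sizes[r], 1L)), character(1)),
      collapse = ";")
  }, character(1))
}

## Small hand-built CommunityTruth for targeted generator tests.
manualTruth <- function(rates, lengths_nt, families = NULL) {
  n <- length(rates)
  taxa <- data.frame(
    superkingdom = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = "Eubacteriales", family = "Ruminococcaceae",
    genus = "Ruminococcus",
    lineage = "Bacteria;Firmicutes;Clostridia;Eubacteriales;Ruminococcaceae;Ruminococcus",
    stringsAsFactors = FALSE)
  taxa <- rbind(taxa, taxa)
  taxa$genus[2] <- "Butyrivibrio"
  if (is.null(families)) families <- rep(NA_character_, n)
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n)),
    taxon_index = rep_len(1:2, n),
    cazy_family = families,
    cd_start = NA_integer_, cd_end = NA_integer_,
    cbm_start = NA_integer_, cbm_end = NA_integer_,
    orf_nt_length = as.integer(lengths_nt),
    frame = rep_len(1:6, n),
    expression_rate = rates, stringsAsFactors = FALSE)
  new("CommunityTruth", taxa = taxa, abundance = c(0.5, 0.5),
      genes = genes, seed = 0L)
}
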