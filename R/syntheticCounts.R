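## Negative-binomial fragment counts per gene and sample, with expected
## per-sample totals equal to the requested library size.

#' Generate per-sample fragment counts
#'
#' Counts are negative binomial with mean proportional to
#' `expression_rate x gene length (kb)`, rescaled so each sample's
#' expected column sum equals `library_size`. `dispersion` is the NB
#' size (shape) parameter (`var = mu + mu^2 / dispersion`);
#' `dispersion = Inf` gives the exact Poisson limit. A gene with
#' expression rate 0 always gets zero counts.
#'
#' @param truth a [CommunityTruth-class].
#' @param n_samples number of samples (columns).
#' @param library_size expected total fragments per sample (> 0).
#' @param dispersion NB size parameter (> 0; `Inf` for Poisson).
#' @param seed integer seed.
#' @return integer matrix, genes x samples, with gene ids as rownames
#'   and `"S1"..` as colnames.
#' @export
generateCounts <- function(truth, n_samples, library_size, dispersion,
                           seed = 1L) {
  stopifnot(is(truth, "CommunityTruth"))
  n_samples <- assertCount(n_samples, "n_samples")
  assertScalarNumeric(library_size, "library_size")
  if (library_size <= 0) stop("'library_size' must be > 0", call. = FALSE)
  if (!is.numeric(dispersion) || length(dispersion) != 1L ||
      is.na(dispersion) || dispersion <= 0)
    stop("'dispersion' must be a positive real (Inf for Poisson)",
         call. = FALSE)

  genes <- communityGenes(truth)
  w <- genes$expression_rate * genes$orf_nt_length / 1000
  if (sum(w) <= 0) stop("all expression rates are zero", call. = FALSE)
  mu <- library_size * w / sum(w)

  withSeed(seed, {
    draw <- function() {
      if (is.infinite(dispersion)) as.numeric(rpois(length(mu), mu))
      else ifelse(mu == 0, 0,
                  rnbinom(length(mu), mu = mu, size = dispersion))
    }
    m <- vapply(seq_len(n_samples), function(j) draw(),
                numeric(length(mu)))
    m <- matrix(as.integer(m), nrow = length(mu))
    dimnames(m) <- list(genes$gene_id, sprintf("S%d", seq_len(n_samples)))
    m
  })
}
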