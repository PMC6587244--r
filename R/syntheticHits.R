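## Synthetic homology hit tables. True genes get hits whose subject
## family and lineage match the truth and that pass every published
## filter; decoys are constructed to fail exactly one named filter each
## (coverage, bit score, or e-value) so per-filter sensitivity is
## attributable in tests.

#' Generate a hit table for a synthetic community
#'
#' Emits blastx-style records (nucleotide query vs protein subject, so
#' `Que_length` is in nt and `Align_length`/`Ref_length` in aa; use
#' `computeBcr(..., query_units = "nt")`). Bit scores are monotone in
#' alignment length for fixed identity (`bits = 2 * Align_length *
#' identity / 100`), and e-values decay with the bit score.
#'
#' @param truth a [CommunityTruth-class].
#' @param unigenes optional output of [generateUnigenes()]; when given,
#'   hits are keyed by unigene id with real query lengths (and truncated
#'   genes get correspondingly short alignments). Otherwise queries are
#'   gene ids with `Que_length = orf_nt_length`.
#' @param identity_noise SD (percentage points) of the Gaussian deviation
#'   of percent identity below 100 (default 0).
#' @param decoy_rate decoys added per true hit, in [0, 1] (default 0).
#' @param seed integer seed.
#' @return data.frame in the package hit layout plus `is_decoy` and
#'   `decoy_type` (`"bcr"`, `"bits"` or `"evalue"`).
#' @export
generateHitTable <- function(truth, unigenes = NULL, identity_noise = 0,
                             decoy_rate = 0, seed = 1L) {
  stopifnot(is(truth, "CommunityTruth"))
  assertScalarNumeric(identity_noise, "identity_noise", lower = 0)
  assertScalarNumeric(decoy_rate, "decoy_rate", lower = 0, upper = 1)
  genes <- communityGenes(truth)
  taxa <- communityTaxa(truth)

  if (!is.null(unigenes)) {
    ut <- unigenes$truth
    qid <- ut$unigene_id[match(genes$gene_id, ut$gene_id)]
    qlen <- nchar(as.character(unigenes$sequences))[
      match(qid, names(unigenes$sequences))]
    ret_aa <- ut$orf_nt_length[match(genes$gene_id, ut$gene_id)] / 3
  } else {
    qid <- genes$gene_id
    qlen <- genes$orf_nt_length
    ret_aa <- genes$orf_nt_length / 3
  }

  withSeed(seed, {
    has_fam <- !is.na(genes$cazy_family)
    idx <- which(has_fam)
    slen <- genes$orf_nt_length / 3          # full-length homolog, aa
    frac <- runif(length(idx), 0.85, 0.98)
    aln <- pmax(1, round(frac * pmin(slen[idx], ret_aa[idx])))
    ident <- pmin(100, pmax(30, 100 - abs(rnorm(length(idx), 0,
                                                identity_noise))))
    bits <- round(2 * aln * ident / 100, 1)
    true_hits <- data.frame(
      query_id = qid[idx],
      subject_id = sprintf("%s_ref%04d", genes$cazy_family[idx], idx),
      pct_identity = round(ident, 2),
      Align_length = aln,
      evalue = 10^(-pmin(bits / 3, 180)),
      bits = bits,
      Que_length = qlen[idx],
      Ref_length = slen[idx],
      subject_family = genes$cazy_family[idx],
      subject_lineage = taxa$lineage[genes$taxon_index[idx]],
      is_decoy = FALSE, decoy_type = NA_character_,
      stringsAsFactors = FALSE)

    n_decoy <- round(decoy_rate * nrow(true_hits))
    if (n_decoy > 0) {
      di <- sample(idx, n_decoy, replace = TRUE)
      type <- rep_len(c("bcr", "bits", "evalue"), n_decoy)
      d_aln <- ifelse(type == "bcr", pmax(1, round(0.2 * slen[di])),
                      pmax(1, round(0.9 * pmin(slen[di], ret_aa[di]))))
      d_bits <- ifelse(type == "bits", 55, 150 + round(runif(n_decoy, 0, 50)))
      d_eval <- ifelse(type == "evalue", 1e-4, 1e-30)
      decoys <- data.frame(
        query_id = qid[di],
        subject_id = sprintf("decoy%04d", seq_len(n_decoy)),
        pct_identity = round(runif(n_decoy, 35, 60), 2),
        Align_length = d_aln,
        evalue = d_eval,
        bits = d_bits,
        Que_length = qlen[di],
        Ref_length = slen[di],
        subject_family = sample(unique(genes$cazy_family[idx]), n_decoy,
                                replace = TRUE),
        subject_lineage = taxa$lineage[genes$taxon_index[di]],
        is_decoy = TRUE, decoy_type = type,
        stringsAsFactors = FALSE)
      true_hits <- rbind(true_hits, decoys)
    }
    rownames(true_hits) <- NULL
    true_hits
  })
}
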