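## Synthetic community generator: ground-truthed taxa, abundances and a
## planted-gene catalog emulating the statistical structure of a rumen
## metatranscriptome (bacteria-dominated community, CAZy-family gene mix,
## lognormal expression rates). All randomness is keyed by `seed`.

## Lineage pool: typical rumen-microbiome lineages, mostly bacterial, with
## archaeal/eukaryotic minorities. superkingdom;phylum;class;order;family;genus
.LINEAGE_POOL <- c(
  "Bacteria;Firmicutes;Clostridia;Eubacteriales;Ruminococcaceae;Ruminococcus",
  "Bacteria;Firmicutes;Clostridia;Eubacteriales;Lachnospiraceae;Butyrivibrio",
  "Bacteria;Firmicutes;Clostridia;Eubacteriales;Clostridiaceae;Clostridium",
  "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus",
  "Bacteria;Firmicutes;Negativicutes;Selenomonadales;Selenomonadaceae;Selenomonas",
  "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella",
  "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides",
  "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Rikenellaceae;Alistipes",
  "Bacteria;Fibrobacteres;Fibrobacteria;Fibrobacterales;Fibrobacteraceae;Fibrobacter",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Aeromonadales;Succinivibrionaceae;Succinivibrio",
  "Bacteria;Spirochaetes;Spirochaetia;Spirochaetales;Treponemataceae;Treponema",
  "Bacteria;Actinobacteria;Actinomycetia;Bifidobacteriales;Bifidobacteriaceae;Bifidobacterium",
  "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobrevibacter",
  "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanomicrobiaceae;Methanomicrobium",
  "Eukaryota;Neocallimastigomycota;Neocallimastigomycetes;Neocallimastigales;Neocallimastigaceae;Neocallimastix",
  "Eukaryota;Ciliophora;Litostomatea;Vestibuliferida;Ophryoscolecidae;Entodinium")

#' Generate a ground-truthed synthetic community
#'
#' Draws `n_taxa` lineages from a built-in pool of rumen-typical taxa
#' (extra genera are synthesised under existing families when the pool is
#' exhausted), Dirichlet(1) relative abundances, and a catalog of `n_genes`
#' planted genes. Each gene gets a taxon (multinomial in abundance), a CAZy
#' family drawn from `family_mix`, an ORF length (codon multiple), a
#' catalytic-domain interval sized to the built-in motif models, an
#' optional CBM interval for CBM families, an embedding frame (1-6) and a
#' lognormal expression rate in expected fragments per kilobase.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param n_genes number of planted genes (>= 1).
#' @param family_mix named nonnegative weights over CAZy family labels
#'   (e.g. `c(GH3 = .5, GH5 = .3, GH9 = .2)`); the name `"none"` yields
#'   genes without a CAZy family (and no planted domain).
#' @param seed integer seed; identical seeds give identical truth objects.
#' @param orf_aa_range min/max protein length in amino acids; the planted
#'   nucleotide ORF is three times this. Defaults span the <600 bp filter
#'   boundary region up to multi-kilobase genes.
#' @param mean_log_rate,sd_log_rate lognormal parameters of the expression
#'   rate (fragments per kilobase); defaults put most genes at low
#'   single-digit rates with a heavy right tail.
#' @return a [CommunityTruth-class] object.
#' @examples
#' ct <- generateCommunity(5, 40, c(GH5 = 1), seed = 1)
#' ct
#' @export
generateCommunity <- function(n_taxa, n_genes, family_mix, seed,
                              orf_aa_range = c(150L, 900L),
                              mean_log_rate = 0.5, sd_log_rate = 1) {
  n_taxa <- assertCount(n_taxa, "n_taxa", min = 2L)
  n_genes <- assertCount(n_genes, "n_genes", min = 1L)
  if (is.null(names(family_mix)) || any(!nzchar(names(family_mix))))
    stop("'family_mix' must be a named weight vector", call. = FALSE)
  if (any(family_mix < 0) || sum(family_mix) <= 0)
    stop("'family_mix' weights must be nonnegative and not all zero",
         call. = FALSE)

  withSeed(seed, {
    pool <- .LINEAGE_POOL
    if (n_taxa <= length(pool)) {
      lineages <- sample(pool, n_taxa)
    } else {
      extra <- sample(pool, n_taxa - length(pool), replace = TRUE)
      extra <- vapply(seq_along(extra), function(i) {
        parts <- strsplit(extra[i], ";", fixed = TRUE)[[1]]
        parts[6] <- sprintf("%s_gen%02d", parts[6], i)
        paste(parts, collapse = ";")
      }, character(1))
      lineages <- c(pool, extra)
    }
    ranks <- do.call(rbind, strsplit(lineages, ";", fixed = TRUE))
    taxa <- as.data.frame(ranks, stringsAsFactors = FALSE)
    names(taxa) <- .RANKS
    taxa$lineage <- lineages

    ab <- rgamma(n_taxa, shape = 1)
    ab <- ab / sum(ab)

    fams <- sample(names(family_mix), n_genes, replace = TRUE,
                   prob = family_mix / sum(family_mix))
    fams[fams == "none"] <- NA_character_
    taxon_index <- sample.int(n_taxa, n_genes, replace = TRUE, prob = ab)
    aa_len <- as.integer(round(runif(n_genes, orf_aa_range[1],
                                     orf_aa_range[2])))

    models <- builtinDomainModels()
    cd_start <- cd_end <- cbm_start <- cbm_end <- rep(NA_integer_, n_genes)
    for (i in seq_len(n_genes)) {
      fam <- fams[i]
      if (is.na(fam)) next
      m <- models[[fam]]
      if (is.null(m)) next
      w <- nchar(m$consensus)
      aa_len[i] <- max(aa_len[i], w + 20L)  # room for the domain
      cd_start[i] <- sample.int(aa_len[i] - w + 1L, 1L)
      cd_end[i] <- cd_start[i] + w - 1L
      if (m$kind == "CBM") {          # CBM families: the interval IS a CBM
        cbm_start[i] <- cd_start[i]; cbm_end[i] <- cd_end[i]
        cd_start[i] <- cd_end[i] <- NA_integer_
      }
    }

    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      taxon_index = taxon_index,
      cazy_family = fams,
      cd_start = cd_start, cd_end = cd_end,
      cbm_start = cbm_start, cbm_end = cbm_end,
      orf_nt_length = 3L * aa_len,
      frame = sample.int(6L, n_genes, replace = TRUE),
      expression_rate = rlnorm(n_genes, mean_log_rate, sd_log_rate),
      stringsAsFactors = FALSE)

    new("CommunityTruth", taxa = taxa, abundance = ab, genes = genes,
        seed = as.integer(seed))
  })
}

#' Build a TaxonomyTree from a CommunityTruth
#'
#' Materialises the lineages of a synthetic community as an explicit rooted
#' tree (the substrate for LCA assignment).
#'
#' @param truth a [CommunityTruth-class].
#' @return a [TaxonomyTree-class].
#' @export
communityTaxonomy <- function(truth) {
  taxonomyFromLineages(communityTaxa(truth)$lineage)
}
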