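#' @import methods
NULL

## Rank ladder used throughout: a synthetic community's taxonomy is a fixed
## seven-level tree (root + six named ranks, superkingdom down to genus).
.RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus")

#' Ordered taxonomic ranks used by the package
#'
#' @return character vector, superkingdom down to genus.
#' @export
taxonomicRanks <- function() .RANKS

#' CommunityTruth: ground truth for a synthetic microbial community
#'
#' Holds the taxa (full lineage paths), their relative abundances, and the
#' catalog of planted genes (CAZy family, catalytic-domain and
#' carbohydrate-binding-module intervals on the translated ORF, ORF length,
#' embedding frame and expected expression rate). Downstream recovery tests
#' compare pipeline output against this object.
#'
#' @slot taxa data.frame with one row per taxon and one column per rank
#'   (see [taxonomicRanks()]) plus a `lineage` string.
#' @slot abundance numeric simplex weights, one per taxon.
#' @slot genes data.frame of planted genes (`gene_id`, `taxon_index`,
#'   `cazy_family`, `cd_start`/`cd_end` and `cbm_start`/`cbm_end` in 1-based
#'   amino-acid coordinates (NA when absent), `orf_nt_length`, `frame`,
#'   `expression_rate` in expected fragments per kilobase).
#' @slot seed integer seed the community was generated from.
#' @export
setClass("CommunityTruth",
  representation(taxa = "data.frame", abundance = "numeric",
                 genes = "data.frame", seed = "integer"))

setValidity("CommunityTruth", function(object) {
  msg <- character()
  if (abs(sum(object@abundance) - 1) > 1e-9)
    msg <- c(msg, "abundances must sum to 1 (tolerance 1e-9)")
  if (any(object@abundance < 0))
    msg <- c(msg, "abundances must be nonnegative")
  if (length(object@abundance) != nrow(object@taxa))
    msg <- c(msg, "one abundance per taxon required")
  if (!all(.RANKS %in% names(object@taxa)))
    msg <- c(msg, "taxa must carry all rank columns")
  g <- object@genes
  if (nrow(g)) {
    if (any(g$taxon_index < 1L | g$taxon_index > nrow(object@taxa)))
      msg <- c(msg, "every gene must reference an existing taxon")
    if (any(g$orf_nt_length %% 3L != 0L))
      msg <- c(msg, "orf_nt_length must be divisible by 3")
    aa <- g$orf_nt_length / 3L
    cd_bad <- !is.na(g$cd_start) & (g$cd_start < 1L | g$cd_end > aa)
    cbm_bad <- !is.na(g$cbm_start) & (g$cbm_start < 1L | g$cbm_end > aa)
    if (any(cd_bad | cbm_bad))
      msg <- c(msg, "domain intervals must lie within the translated length")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CommunityTruth taxa table accessor
#' @param object,x a `CommunityTruth`.
#' @export
communityTaxa <- function(x) x@taxa

#' @describeIn CommunityTruth planted-gene catalog accessor
#' @export
communityGenes <- function(x) x@genes

#' @describeIn CommunityTruth relative-abundance accessor
#' @export
communityAbundance <- function(x) x@abundance

setMethod("show", "CommunityTruth", function(object) {
  cat(sprintf("CommunityTruth: %d taxa, %d planted genes (seed %d)\n",
              nrow(object@taxa), nrow(object@genes), object@seed))
  fams <- table(object@genes$cazy_family, useNA = "no")
  if (length(fams))
    cat("  families:",
        paste(sprintf("%s=%d", names(fams), fams), collapse = " "), "\n")
})

#' TaxonomyTree: rooted rank-labelled taxonomy
#'
#' Explicit tree over which lowest-common-ancestor assignment runs. Nodes
#' carry a name, a rank drawn from `c("root", taxonomicRanks())` and a
#' parent id; the root is its own ancestor with parent `NA`.
#'
#' @slot nodes data.frame with columns `id`, `name`, `rank`, `parent`.
#' @slot root integer id of the root node.
#' @export
setClass("TaxonomyTree",
  representation(nodes = "data.frame", root = "integer"))

setValidity("TaxonomyTree", function(object) {
  nd <- object@nodes
  msg <- character()
  need <- c("id", "name", "rank", "parent")
  if (!all(need %in% names(nd)))
    return("nodes must have columns id, name, rank, parent")
  if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
  roots <- nd$id[is.na(nd$parent)]
  if (length(roots) != 1L || roots != object@root)
    msg <- c(msg, "exactly one root (parent NA) matching @root required")
  if (!all(nd$parent[!is.na(nd$parent)] %in% nd$id))
    msg <- c(msg, "every non-root parent must exist")
  if (!all(nd$rank %in% c("root", .RANKS)))
    msg <- c(msg, "ranks must come from c('root', taxonomicRanks())")
  if (length(msg)) msg else TRUE
})

#' @describeIn TaxonomyTree node table accessor
#' @param object,x a `TaxonomyTree`.
#' @export
taxonomyNodes <- function(x) x@nodes

#' @describeIn TaxonomyTree root id accessor
#' @export
taxonomyRoot <- function(x) x@root

setMethod("show", "TaxonomyTree", function(object) {
  cat(sprintf("TaxonomyTree: %d nodes, root '%s'\n", nrow(object@nodes),
              object@nodes$name[match(object@root, object@nodes$id)]))
  print(table(object@nodes$rank))
})
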