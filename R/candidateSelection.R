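## GH5 candidate selection: identity-based pairwise distances, a
## neighbor-joining tree, distance-threshold clustering into clusters
## plus an unclustered pool, and stratified random selection across all
## strata.

#' Pairwise identity distances between catalytic-domain proteins
#'
#' Global (Needleman-Wunsch) pairwise alignment with BLOSUM62;
#' distance = 1 - fractional identity over aligned columns (gaps count
#' as columns). Symmetric with a zero diagonal.
#'
#' @param proteins named character vector or `AAStringSet` (>= 2
#'   sequences, unique non-empty labels).
#' @return symmetric numeric matrix with the sequence labels.
#' @export
pairwiseDistance <- function(proteins) {
  if (methods::is(proteins, "AAStringSet"))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  if (length(proteins) < 2L)
    stop("at least 2 sequences required", call. = FALSE)
  nm <- names(proteins)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("sequences must have unique non-empty labels", call. = FALSE)
  n <- length(proteins)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  aa <- Biostrings::AAStringSet(proteins)
  for (i in seq_len(n - 1L)) {
    pa <- Biostrings::pairwiseAlignment(
      rep(aa[i], n - i), aa[(i + 1L):n], type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4)
    pid <- Biostrings::pid(pa, type = "PID1")
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - pid / 100
  }
  d
}

#' Build a neighbor-joining tree
#'
#' Standard NJ agglomeration on a symmetric distance matrix; additive
#' distances are reproduced exactly (topology and branch lengths).
#'
#' @param dist symmetric numeric matrix (zero diagonal, >= 3 labels) or
#'   `dist` object.
#' @return an `ape` `phylo` tree (unrooted, binary).
#' @export
buildNjTree <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("'dist' must be a square matrix", call. = FALSE)
  if (max(abs(dist - t(dist))) > 1e-8)
    stop("'dist' must be symmetric", call. = FALSE)
  if (nrow(dist) < 3L) stop("need >= 3 taxa", call. = FALSE)
  ape::nj(stats::as.dist(dist))
}

#' Cut a tree into clusters at a path-length threshold
#'
#' Midpoint-roots the tree, then walks from the root keeping every
#' maximal clade whose within-clade leaf-to-leaf path lengths are all at
#' or below `height_threshold`; clades of size >= 2 become clusters and
#' all remaining leaves are reported unclustered. Negative NJ branch
#' lengths are clamped to zero first. Every leaf lands in exactly one
#' cluster or the unclustered pool.
#'
#' @param tree a `phylo` with branch lengths.
#' @param height_threshold maximum within-cluster path length (> 0).
#' @return list with `clusters` (named list of leaf-label vectors,
#'   `"cluster1"` ...) and `unclustered` (leaf labels).
#' @export
clusterTree <- function(tree, height_threshold) {
  stopifnot(inherits(tree, "phylo"))
  assertScalarNumeric(height_threshold, "height_threshold")
  if (height_threshold <= 0)
    stop("'height_threshold' must be > 0", call. = FALSE)
  tree$edge.length <- pmax(tree$edge.length, 0)
  rooted <- phangorn::midpoint(tree)
  coph <- ape::cophenetic.phylo(rooted)
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  kids <- split(rooted$edge[, 2], rooted$edge[, 1])

  cladeTips <- function(node) {
    if (node <= ntip) return(rooted$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], cladeTips), use.names = FALSE)
  }
  clusters <- list()
  unclustered <- character(0)
  walk <- function(node) {
    tips <- cladeTips(node)
    if (length(tips) >= 2L &&
        max(coph[tips, tips]) <= height_threshold) {
      clusters[[length(clusters) + 1L]] <<- tips
    } else if (node <= ntip) {
      unclustered <<- c(unclustered, tips)
    } else {
      for (ch in kids[[as.character(node)]]) walk(ch)
    }
  }
  walk(root)
  names(clusters) <- if (length(clusters))
    sprintf("cluster%d", seq_along(clusters)) else character(0)
  list(clusters = clusters, unclustered = unclustered)
}

#' Stratified random selection of validation candidates
#'
#' Draws up to `per_cluster` members from every cluster and from the
#' unclustered pool, so each stratum is represented; clusters smaller
#' than `per_cluster` are taken whole, empty strata are skipped with a
#' warning. Deterministic for a fixed seed.
#'
#' @param clustering output of [clusterTree()].
#' @param per_cluster candidates per stratum (>= 1).
#' @param seed integer seed.
#' @return data.frame: `stratum`, `candidate`.
#' @export
selectCandidates <- function(clustering, per_cluster, seed = 1L) {
  per_cluster <- assertCount(per_cluster, "per_cluster")
  strata <- c(clustering$clusters,
              list(unclustered = clustering$unclustered))
  withSeed(seed, {
    rows <- lapply(names(strata), function(s) {
      members <- strata[[s]]
      if (!length(members)) {
        warning("stratum '", s, "' is empty, skipped", call. = FALSE)
        return(NULL)
      }
      take <- if (length(members) <= per_cluster) members
      else sample(members, per_cluster)
      data.frame(stratum = s, candidate = take, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(stratum = character(), candidate = character(),
                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
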