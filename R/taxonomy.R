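## Lowest-common-ancestor taxonomic binning over an explicit rank-labelled
## tree, plus the class-by-phylum summary of CAZyme-annotated unigenes.

#' Build a TaxonomyTree from semicolon-delimited lineage strings
#'
#' @param lineages character vector,
#'   `"superkingdom;phylum;class;order;family;genus"` paths. Partial paths
#'   (fewer ranks) are allowed.
#' @return a [TaxonomyTree-class]; identical named paths share nodes.
#' @examples
#' tr <- taxonomyFromLineages(c("Bacteria;Firmicutes;Clostridia",
#'                              "Bacteria;Bacteroidetes;Bacteroidia"))
#' taxonomyNodes(tr)
#' @export
taxonomyFromLineages <- function(lineages) {
  paths <- strsplit(lineages, ";", fixed = TRUE)
  nodes <- data.frame(id = 1L, name = "root", rank = "root",
                      parent = NA_integer_, path = "",
                      stringsAsFactors = FALSE)
  for (p in paths) {
    parent <- 1L
    key <- ""
    for (d in seq_along(p)) {
      key <- paste(key, p[d], sep = ";")
      hit <- match(key, nodes$path)
      if (is.na(hit)) {
        id <- nrow(nodes) + 1L
        nodes <- rbind(nodes, data.frame(
          id = id, name = p[d], rank = .RANKS[d], parent = parent,
          path = key, stringsAsFactors = FALSE))
        parent <- id
      } else parent <- nodes$id[hit]
    }
  }
  new("TaxonomyTree", nodes = nodes[setdiff(names(nodes), "path")],
      root = 1L)
}

#' Build a TaxonomyTree from a parent-child edge list
#'
#' The on-disk interchange format: a two-column child/parent table of node
#' names plus a node-metadata table giving each node's rank.
#'
#' @param edges data.frame with columns `child`, `parent` (node names).
#' @param meta data.frame with columns `name`, `rank`.
#' @return a [TaxonomyTree-class].
#' @export
taxonomyFromEdges <- function(edges, meta) {
  stopifnot(all(c("child", "parent") %in% names(edges)),
            all(c("name", "rank") %in% names(meta)))
  nm <- unique(c(edges$child, edges$parent))
  root_nm <- setdiff(edges$parent, edges$child)
  if (length(root_nm) != 1L)
    stop("edge list must have exactly one root", call. = FALSE)
  nm <- c(root_nm, setdiff(nm, root_nm))
  id <- seq_along(nm)
  names(id) <- nm
  parent <- rep(NA_integer_, length(nm))
  parent[id[edges$child]] <- id[edges$parent]
  rank <- meta$rank[match(nm, meta$name)]
  rank[is.na(rank) & is.na(parent)] <- "root"
  new("TaxonomyTree",
      nodes = data.frame(id = id, name = nm, rank = rank, parent = parent,
                         stringsAsFactors = FALSE, row.names = NULL),
      root = unname(id[root_nm]))
}

## root-to-node id path; NULL when the lineage names don't resolve
.lineagePath <- function(tree, lineage) {
  nd <- taxonomyNodes(tree)
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  cur <- taxonomyRoot(tree)
  path <- cur
  for (p in parts) {
    nxt <- nd$id[!is.na(nd$parent) & nd$parent == cur & nd$name == p]
    if (length(nxt) != 1L) return(NULL)
    cur <- nxt
    path <- c(path, cur)
  }
  path
}

.ancestorSet <- function(tree, id) {
  nd <- taxonomyNodes(tree)
  out <- id
  while (!is.na(nd$parent[match(id, nd$id)])) {
    id <- nd$parent[match(id, nd$id)]
    out <- c(out, id)
  }
  out
}

#' Assign taxa to queries by lowest common ancestor
#'
#' For each query, hits passing the contribution filter (bit score strictly
#' above `bits_min` and alignment length strictly above `len_min`
#' nucleotides) vote with their subject lineage; the assignment is the
#' deepest tree node ancestral to all contributing lineages. Queries with
#' no contributing hits are reported unassigned. Hits whose lineage does
#' not resolve in the tree are dropped with a warning.
#'
#' @param hits data.frame with columns `query_id`, `bits`, `Align_length`,
#'   `subject_lineage`; if `aln_units = "aa"` alignment lengths are
#'   converted to nucleotides (x3) before filtering.
#' @param tree a [TaxonomyTree-class].
#' @param bits_min,len_min contribution thresholds (both strict), defaults
#'   50 bits and 25 nt.
#' @param aln_units `"nt"` (default) or `"aa"` for `Align_length`.
#' @return data.frame: `query_id`, `node_id` (NA if unassigned), `rank`,
#'   `name`, `phylum` (`"unclassified"` when the assignment is above
#'   phylum or absent).
#' @export
lcaAssign <- function(hits, tree, bits_min = 50, len_min = 25,
                      aln_units = c("nt", "aa")) {
  aln_units <- match.arg(aln_units)
  stopifnot(all(c("query_id", "bits", "Align_length", "subject_lineage")
                %in% names(hits)))
  nd <- taxonomyNodes(tree)
  len_nt <- hits$Align_length * if (aln_units == "aa") 3 else 1
  keep <- hits$bits > bits_min & len_nt > len_min
  hits <- hits[keep, , drop = FALSE]

  queries <- unique(hits$query_id)
  res <- lapply(queries, function(q) {
    lins <- hits$subject_lineage[hits$query_id == q]
    paths <- lapply(unique(lins), function(l) .lineagePath(tree, l))
    bad <- vapply(paths, is.null, logical(1))
    if (any(bad))
      warning(sprintf("query %s: %d lineage(s) not in tree, dropped",
                      q, sum(bad)), call. = FALSE)
    paths <- paths[!bad]
    if (!length(paths))
      return(data.frame(query_id = q, node_id = NA_integer_,
                        rank = NA_character_, name = NA_character_,
                        phylum = "unclassified", stringsAsFactors = FALSE))
    ## deepest common node = longest common prefix of root-to-leaf paths
    depth <- min(lengths(paths))
    lca <- taxonomyRoot(tree)
    for (d in seq_len(depth)) {
      ids <- vapply(paths, `[`, integer(1), d)
      if (length(unique(ids)) != 1L) break
      lca <- ids[1]
    }
    i <- match(lca, nd$id)
    phy <- .phylumOf(tree, lca)
    data.frame(query_id = q, node_id = lca, rank = nd$rank[i],
               name = nd$name[i], phylum = phy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(query_id = character(), node_id = integer(),
                      rank = character(), name = character(),
                      phylum = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## phylum-rank ancestor name, or "unclassified" when shallower than phylum
.phylumOf <- function(tree, id) {
  nd <- taxonomyNodes(tree)
  anc <- .ancestorSet(tree, id)
  phy <- nd$name[nd$id %in% anc & nd$rank == "phylum"]
  if (length(phy) == 1L) phy else "unclassified"
}

#' Cross-tabulate CAZyme classes by assigned phylum
#'
#' @param assignments output of [lcaAssign()].
#' @param annotations output of [assignFamilies()] (one row per
#'   query/family with a `class` column).
#' @return integer matrix, CAZyme classes x phyla; queries lacking an
#'   assignment (or assigned above phylum) fall in `"unclassified"`.
#' @export
phylumSummary <- function(assignments, annotations) {
  if (!nrow(annotations))
    return(matrix(integer(), 0, 0))
  phy <- assignments$phylum[match(annotations$query_id,
                                  assignments$query_id)]
  phy[is.na(phy)] <- "unclassified"
  tab <- table(class = annotations$class, phylum = phy)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}
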