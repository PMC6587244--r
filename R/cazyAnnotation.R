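## CAZy annotation from tabular homology hits: BLAST coverage ratios,
## the published hit filters, per-query family assignment, and the
## class/family tabulation with the cellulase subset flagged.

## Cellulase-containing GH families (the 15-family subset).
.CELLULASE_FAMILIES <- c("GH1", "GH3", "GH5", "GH6", "GH8", "GH9", "GH12",
                         "GH30", "GH44", "GH45", "GH48", "GH51", "GH74",
                         "GH116", "GH124")

#' The 15 cellulase-containing GH families
#' @return character vector of family labels.
#' @export
cellulaseFamilies <- function() .CELLULASE_FAMILIES

.CLASS_PREFIXES <- c("GH", "GT", "CE", "PL", "AA", "CBM")

## CAZy class from a family label ("GH5" -> "GH", "CBM_4_9" -> "CBM");
## NA if unrecognised
.familyClass <- function(family) {
  ok <- grepl("^(CBM|GH|GT|CE|PL|AA)_?[0-9]", family)
  ifelse(ok, sub("^(CBM|GH|GT|CE|PL|AA).*$", "\\1", family), NA_character_)
}

#' Compute BLAST coverage ratios
#'
#' Adds `BCR_Ref = 100 * Align_length / Ref_length` and
#' `BCR_Que = 100 * Align_length / Que_length` to a hit table. Alignment
#' lengths exceeding a sequence length (possible with gapped columns in
#' tabular output) are clamped to that length with a warning so BCR stays
#' at or below 100. When the query is a nucleotide sequence and the
#' subject a protein (`query_units = "nt"`, the blastx convention),
#' `Que_length` is divided by 3 before BCR_Que.
#'
#' @param hits data.frame with columns `Align_length`, `Ref_length`,
#'   `Que_length` (plus anything else, preserved).
#' @param query_units `"aa"` (default; query and subject in the same
#'   units) or `"nt"` (query length in nucleotides, alignment and subject
#'   in amino acids).
#' @return `hits` with numeric columns `BCR_Ref`, `BCR_Que` appended;
#'   rows with a nonpositive length are dropped with a warning (invalid
#'   records).
#' @examples
#' computeBcr(data.frame(Align_length = 200, Ref_length = 400,
#'                       Que_length = 500))
#' @export
computeBcr <- function(hits, query_units = c("aa", "nt")) {
  query_units <- match.arg(query_units)
  stopifnot(all(c("Align_length", "Ref_length", "Que_length")
                %in% names(hits)))
  bad <- hits$Ref_length <= 0 | hits$Que_length <= 0
  if (any(bad)) {
    warning(sprintf("%d hit(s) with nonpositive length skipped", sum(bad)),
            call. = FALSE)
    hits <- hits[!bad, , drop = FALSE]
  }
  qlen <- hits$Que_length / if (query_units == "nt") 3 else 1
  aln <- hits$Align_length
  over <- aln > pmin(hits$Ref_length, qlen)
  if (any(over)) {
    warning(sprintf("%d alignment length(s) exceed sequence length; clamped",
                    sum(over)), call. = FALSE)
    aln <- pmin(aln, hits$Ref_length, qlen)
  }
  hits$BCR_Ref <- 100 * aln / hits$Ref_length
  hits$BCR_Que <- 100 * aln / qlen
  hits
}

#' Apply the published hit filters
#'
#' A hit is retained iff `evalue <= evalue_max`, `bits > bits_min`
#' (strict: a hit at exactly 60 bits is excluded) and both coverage ratios
#' are `>= bcr_min` (exclusion is strictly below 40%, so exactly 40.0
#' passes). Idempotent and order-independent.
#'
#' @param hits data.frame with `evalue`, `bits`, `BCR_Ref`, `BCR_Que`
#'   (run [computeBcr()] first if the BCR columns are missing).
#' @param evalue_max,bits_min,bcr_min thresholds; defaults 1e-5, 60 bits,
#'   40%.
#' @return the retained rows of `hits`.
#' @export
filterHits <- function(hits, evalue_max = 1e-5, bits_min = 60,
                       bcr_min = 40) {
  stopifnot(is.finite(evalue_max), is.finite(bits_min), is.finite(bcr_min))
  if (!all(c("BCR_Ref", "BCR_Que") %in% names(hits)))
    hits <- computeBcr(hits)
  keep <- hits$evalue <= evalue_max & hits$bits > bits_min &
    hits$BCR_Ref >= bcr_min & hits$BCR_Que >= bcr_min
  hits[keep, , drop = FALSE]
}

#' Assign CAZy families per query
#'
#' For each query and each subject family among its (already filtered)
#' hits, the best hit is kept: highest bit score, ties broken by lower
#' e-value, then by lexicographically smallest subject id. One unigene may
#' carry several families (it can encode several CAZyme domains). Queries
#' with no hits are absent from the output (counted as unannotated).
#'
#' @param hits filtered hit table with `query_id`, `subject_id`,
#'   `subject_family`, `bits`, `evalue`.
#' @return data.frame, one row per (query, family): `query_id`, `family`,
#'   `class`, `subject_id`, `bits`, `evalue`.
#' @export
assignFamilies <- function(hits) {
  cols <- c("query_id", "subject_id", "subject_family", "bits", "evalue")
  stopifnot(all(cols %in% names(hits)))
  if (!nrow(hits))
    return(data.frame(query_id = character(), family = character(),
                      class = character(), subject_id = character(),
                      bits = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  ## best-first ordering, then keep first row per (query, family)
  o <- order(hits$query_id, hits$subject_family, -hits$bits, hits$evalue,
             hits$subject_id)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h[c("query_id", "subject_family")])
  h <- h[first, , drop = FALSE]
  out <- data.frame(query_id = h$query_id, family = h$subject_family,
                    class = .familyClass(h$subject_family),
                    subject_id = h$subject_id, bits = h$bits,
                    evalue = h$evalue, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tabulate CAZy annotations by class and family
#'
#' Counts annotated unigenes per family and per CAZyme class (GH, GT, CE,
#' PL, AA, CBM), flags the cellulase-containing GH subset
#' ([cellulaseFamilies()]), and reports each family's percentage of its
#' class and each cellulase family's percentage of the cellulase subset,
#' rounded half up to one decimal. Unrecognised family labels are counted
#' under class `"unclassified"` with a warning.
#'
#' @param annotations output of [assignFamilies()] (or any data.frame with
#'   `query_id` and `family`).
#' @return data.frame: `family`, `class`, `count`, `pct_of_class`,
#'   `cellulase`, `pct_of_cellulase` (NA outside the subset).
#' @export
tabulateFamilies <- function(annotations) {
  if (!nrow(annotations))
    return(data.frame(family = character(), class = character(),
                      count = integer(), pct_of_class = numeric(),
                      cellulase = logical(), pct_of_cellulase = numeric(),
                      stringsAsFactors = FALSE))
  ## one contribution per (query, family)
  ann <- annotations[!duplicated(annotations[c("query_id", "family")]), ]
  cls <- .familyClass(ann$family)
  if (anyNA(cls)) {
    warning(sprintf("%d annotation(s) with unknown family label counted as unclassified",
                    sum(is.na(cls))), call. = FALSE)
    cls[is.na(cls)] <- "unclassified"
  }
  tab <- as.data.frame(table(family = ann$family), stringsAsFactors = FALSE)
  names(tab)[2] <- "count"
  tab$class <- cls[match(tab$family, ann$family)]
  class_tot <- tapply(tab$count, tab$class, sum)
  tab$pct_of_class <- roundHalfUp(100 * tab$count /
                                    as.numeric(class_tot[tab$class]), 1)
  tab$cellulase <- tab$family %in% .CELLULASE_FAMILIES
  cell_tot <- sum(tab$count[tab$cellulase])
  tab$pct_of_cellulase <- ifelse(
    tab$cellulase & cell_tot > 0,
    roundHalfUp(100 * tab$count / cell_tot, 1), NA_real_)
  ## order families within classes numerically
  num <- suppressWarnings(as.numeric(sub("^[A-Za-z_]+", "", tab$family)))
  tab <- tab[order(tab$class, num, tab$family), ]
  rownames(tab) <- NULL
  tab[c("family", "class", "count", "pct_of_class", "cellulase",
        "pct_of_cellulase")]
}

#' Read a tabular homology hit file
#'
#' Tab-separated, standard 12-column tabular alignment layout (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' q/s start/end, e-value, bit score) extended with `qlen`, `slen`,
#' `subject_family` and `subject_lineage`. Lines starting `#` are skipped.
#'
#' @param path file path.
#' @return data.frame in the package's hit-record layout (`query_id`,
#'   `subject_id`, `pct_identity`, `Align_length`, `evalue`, `bits`,
#'   `Que_length`, `Ref_length`, `subject_family`, `subject_lineage`).
#' @export
readHitTable <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "Align_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bits", "Que_length", "Ref_length",
            "subject_family", "subject_lineage")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = cols, stringsAsFactors = FALSE,
                          quote = "")
  df
}

#' Write a hit table in the package's tab-separated layout
#' @param hits data.frame from [generateHitTable()] or [readHitTable()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  cols <- c("query_id", "subject_id", "pct_identity", "Align_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bits", "Que_length", "Ref_length",
            "subject_family", "subject_lineage")
  miss <- setdiff(cols, names(hits))
  for (m in miss) hits[[m]] <- if (m %in% c("mismatch", "gapopen", "qstart",
                                            "qend", "sstart", "send")) 0
  else NA
  utils::write.table(hits[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
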