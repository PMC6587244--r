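## Catalytic-domain / CBM screening of predicted proteins. Two routes:
## built-in position-weight motif models (self-contained test fixtures,
## scored by match/mismatch log-odds against a consensus), or an external
## HMMER domtblout file scored by the profile-HMM search that produced it.
## Either way, hits are kept at or above the model's gathering threshold
## (GA), and overlapping hits of the same model on the same protein are
## merged to the higher-scoring one.

## Built-in motif consensi are synthetic stand-ins shaped like the real
## Pfam families they are named after (invented sequences, not Pfam HMMs).
.BUILTIN_MODELS <- list(
  GH1     = list(model = "PF00232", kind = "CD",
                 consensus = "FIWGTATSAYQIEGAWNEDGKGES"),
  GH3     = list(model = "PF00933", kind = "CD",
                 consensus = "GFVMSDWGAVHSTVKSANAGLDLE"),
  GH5     = list(model = "PF00150", kind = "CD",
                 consensus = "HEYLDGMGAWNGGIIGSSDYAIES"),
  GH6     = list(model = "PF01341", kind = "CD",
                 consensus = "WDCCKPSCAWPGKASVNQPVFSCN"),
  GH8     = list(model = "PF01270", kind = "CD",
                 consensus = "YFDDIKFAMLWLYTGNRDAYDKSG"),
  GH9     = list(model = "PF00759", kind = "CD",
                 consensus = "HGYFDAGDYGKYVVNGGISVWTLN"),
  GH30    = list(model = "PF02055", kind = "CD",
                 consensus = "RYLLKIIDEMAKNGLKLFASPWSP"),
  GH45    = list(model = "PF02015", kind = "CD",
                 consensus = "TRYWDCCKPSCGWAKKAPVNQPVF"),
  CBM_2   = list(model = "PF00553", kind = "CBM",
                 consensus = "CSVTYTVNSWNTGFTANVTLKNTG"),
  CBM_3   = list(model = "PF00942", kind = "CBM",
                 consensus = "VSGNQIKMVIGLNAQHAGNPQLEL"),
  CBM_4_9 = list(model = "PF02018", kind = "CBM",
                 consensus = "WEMVWSDEFNGSELDRSKWNYDVG"),
  CBM_6   = list(model = "PF03422", kind = "CBM",
                 consensus = "AEAESMTKSGQYIGSIDNPDSSVE"))

#' Built-in domain motif models
#'
#' Compact consensus-based position-weight models for the common cellulase
#' catalytic-domain and CBM families, with per-model gathering thresholds.
#' They emulate the role of Pfam profile HMMs in a fully self-contained
#' way (the consensi are synthetic); use the domtblout route of
#' [screenDomains()] for real HMMER output.
#'
#' Scoring: +2 per consensus match, -1 per mismatch, over the consensus
#' width; the default GA of 30 bits on a 24-residue model requires 75%
#' identity to the consensus.
#'
#' @param ga gathering threshold applied to every model (default 30).
#' @return named list of models (`family` label as name; fields `model`,
#'   `family`, `kind`, `consensus`, `ga`).
#' @export
builtinDomainModels <- function(ga = 30) {
  out <- .BUILTIN_MODELS
  for (f in names(out)) {
    out[[f]]$family <- f
    out[[f]]$ga <- ga
  }
  out
}

## score one protein against one consensus at every offset
.motifScores <- function(pchars, mchars) {
  w <- length(mchars)
  n <- length(pchars) - w + 1L
  if (n < 1L) return(numeric(0))
  vapply(seq_len(n), function(i) {
    m <- sum(pchars[i:(i + w - 1L)] == mchars)
    2 * m - (w - m)
  }, numeric(1))
}

## greedy merge: keep highest-scoring, drop overlapping same-model hits
.mergeOverlaps <- function(df) {
  if (nrow(df) < 2L) return(df)
  key <- paste(df$orf_id, df$model)
  keep <- logical(nrow(df))
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(-df$score[idx], df$aa_start[idx])]
    taken <- integer(0)
    for (i in idx) {
      ov <- any(df$aa_start[i] <= df$aa_end[taken] &
                  df$aa_end[i] >= df$aa_start[taken])
      if (!ov) { keep[i] <- TRUE; taken <- c(taken, i) }
    }
  }
  df[keep, , drop = FALSE]
}

#' Screen proteins for catalytic domains and CBMs
#'
#' Either scans proteins with the built-in motif models, or consumes an
#' external HMMER domtblout file. Hits are retained when the score is at
#' or above the model's gathering threshold (GA is inclusive: a hit
#' exactly at GA is kept); overlapping hits of one model on one protein
#' are merged to the higher-scoring one.
#'
#' @param proteins named character vector (ORF id to amino-acid string);
#'   ignored when `domtblout` is given.
#' @param models model list as from [builtinDomainModels()].
#' @param domtblout optional path to a HMMER `--domtblout` file.
#' @param ga_table required with `domtblout`: data.frame mapping `model`
#'   (the query/model name in the file) to `ga`, `family`, `kind`.
#' @return data.frame: `orf_id`, `model`, `family`, `kind`, `aa_start`,
#'   `aa_end` (1-based inclusive), `score`, `ga`.
#' @export
screenDomains <- function(proteins = NULL, models = builtinDomainModels(),
                          domtblout = NULL, ga_table = NULL) {
  if (!is.null(domtblout)) {
    raw <- readDomtblout(domtblout)
    if (is.null(ga_table) ||
        !all(c("model", "ga", "family", "kind") %in% names(ga_table)))
      stop("'ga_table' with columns model, ga, family, kind is required",
           call. = FALSE)
    i <- match(raw$model, ga_table$model)
    if (anyNA(i))
      stop("domtblout contains models absent from 'ga_table': ",
           paste(unique(raw$model[is.na(i)]), collapse = ", "),
           call. = FALSE)
    raw$family <- ga_table$family[i]
    raw$kind <- ga_table$kind[i]
    raw$ga <- ga_table$ga[i]
    raw <- raw[raw$score >= raw$ga, , drop = FALSE]
    out <- .mergeOverlaps(raw)
    rownames(out) <- NULL
    return(out[c("orf_id", "model", "family", "kind", "aa_start",
                 "aa_end", "score", "ga")])
  }
  if (is.null(proteins) || is.null(names(proteins)))
    stop("'proteins' must be a named character vector", call. = FALSE)
  rows <- list()
  for (id in names(proteins)) {
    pchars <- strsplit(proteins[[id]], "")[[1]]
    for (m in models) {
      mchars <- strsplit(m$consensus, "")[[1]]
      sc <- .motifScores(pchars, mchars)
      hit <- which(sc >= m$ga)
      for (h in hit)
        rows[[length(rows) + 1L]] <- data.frame(
          orf_id = id, model = m$model, family = m$family, kind = m$kind,
          aa_start = h, aa_end = h + length(mchars) - 1L,
          score = sc[h], ga = m$ga, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) .mergeOverlaps(do.call(rbind, rows)) else
    data.frame(orf_id = character(), model = character(),
               family = character(), kind = character(),
               aa_start = integer(), aa_end = integer(),
               score = numeric(), ga = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a HMMER domtblout file
#'
#' Space-delimited per-domain table written by `hmmsearch --domtblout`
#' (comment lines start with `#`; the free-text description field is
#' everything past column 22). The per-domain score (column 14) and the
#' alignment coordinates on the target (columns 18-19) are extracted.
#'
#' @param path file path.
#' @return data.frame: `orf_id`, `model`, `score`, `evalue`, `aa_start`,
#'   `aa_end`.
#' @export
readDomtblout <- function(path) {
  lines <- readLines(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    x <- lines[ln]
    if (!nzchar(trimws(x)) || startsWith(x, "#")) next
    f <- strsplit(trimws(x), "[[:space:]]+")[[1]]
    if (length(f) < 22L)
      stop(sprintf("malformed domtblout line %d: %d field(s), need >= 22",
                   ln, length(f)), call. = FALSE)
    num <- suppressWarnings(as.numeric(f[c(13, 14, 18, 19)]))
    if (anyNA(num))
      stop(sprintf("malformed domtblout line %d: non-numeric score/coords",
                   ln), call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      orf_id = f[1], model = f[4], score = num[2], evalue = num[1],
      aa_start = as.integer(num[3]), aa_end = as.integer(num[4]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(orf_id = character(), model = character(),
                      score = numeric(), evalue = numeric(),
                      aa_start = integer(), aa_end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Tabulate domain hits per family
#'
#' For each family: the number of distinct ORFs carrying at least one
#' retained hit, and the total number of retained hits (domains). CBM
#' families that share one Pfam model are already pooled upstream (the
#' model-to-family map assigns them one combined label such as
#' `CBM_4_9`), so the table never splits them.
#'
#' @param domain_hits output of [screenDomains()].
#' @return data.frame: `family`, `kind`, `orf_count`, `domain_count`;
#'   empty input gives an empty table.
#' @export
tabulateDomains <- function(domain_hits) {
  if (!nrow(domain_hits))
    return(data.frame(family = character(), kind = character(),
                      orf_count = integer(), domain_count = integer(),
                      stringsAsFactors = FALSE))
  sp <- split(domain_hits, domain_hits$family)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    family = d$family[1], kind = d$kind[1],
    orf_count = length(unique(d$orf_id)),
    domain_count = nrow(d), stringsAsFactors = FALSE)))
  out <- out[order(out$kind, out$family), ]
  rownames(out) <- NULL
  out
}
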