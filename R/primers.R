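## RT-PCR primer design with vector-homology cloning tails. The cores
## anneal to the ORF termini; each primer carries a 22-nt 5' extension
## homologous to the pET-28a(+) insertion site so the amplicon can be
## cloned by homologous recombination. Tails are excluded from melting
## temperature.

.TAIL_F <- "GGCCATGGCTGATATCGGATCC"
.TAIL_R <- "CTTGTCGACGGAGCTCGAATTC"

#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` degrees C, the short-oligo counting rule.
#' @param core DNA string.
#' @return Tm in degrees C.
#' @examples
#' tmWallace("ATATATATATGCGCGCGCGC")  # 10 A/T + 10 G/C -> 60
#' @export
tmWallace <- function(core) {
  b <- strsplit(toupper(core), "")[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

#' GC-content melting temperature
#'
#' `Tm = 64.9 + 41 x (GC - 16.4) / N` degrees C, for oligos longer than
#' the Wallace-rule regime.
#' @param core DNA string.
#' @return Tm in degrees C.
#' @export
tmGc <- function(core) {
  b <- strsplit(toupper(core), "")[[1]]
  64.9 + 41 * (sum(b %in% c("G", "C")) - 16.4) / length(b)
}

#' Primer core melting temperature
#'
#' Wallace rule for cores of 14 nt or shorter, GC-content formula above.
#' @param core DNA string.
#' @return Tm in degrees C.
#' @export
primerTm <- function(core) {
  if (nchar(core) <= 14L) tmWallace(core) else tmGc(core)
}

#' Design a tailed RT-PCR primer pair for an ORF
#'
#' The forward core is the ORF's 5' terminus and the reverse core the
#' reverse complement of its 3' terminus; core lengths are chosen within
#' `core_len_range` to bring the two core Tm values within `tm_window`
#' of each other and as close as possible to `tm_target`. The 22-nt
#' vector-homology tails are prepended verbatim (and never enter the Tm
#' calculation). When no length combination satisfies the window the
#' best-effort pair is returned with `in_window = FALSE`.
#'
#' @param orf_nt ORF nucleotide sequence (>= 2x the minimum core
#'   length).
#' @param tail_f,tail_r 5' tails; defaults are the pET-28a(+)
#'   insertion-site homology arms.
#' @param core_len_range min/max core length in nt (default 18-25).
#' @param tm_window maximum |Tm_f - Tm_r| in degrees C (default 5).
#' @param tm_target global Tm target in degrees C (default 60).
#' @return list: `forward`, `reverse` (tailed primers), `core_f`,
#'   `core_r`, `tm_f`, `tm_r`, `in_window`.
#' @export
designPrimers <- function(orf_nt, tail_f = .TAIL_F, tail_r = .TAIL_R,
                          core_len_range = c(18L, 25L), tm_window = 5,
                          tm_target = 60) {
  orf_nt <- toupper(as.character(orf_nt))
  lens <- seq(core_len_range[1], core_len_range[2])
  if (nchar(orf_nt) < 2L * min(lens))
    stop("ORF shorter than twice the minimum core length", call. = FALSE)
  fwd <- vapply(lens, function(l) substr(orf_nt, 1L, l), character(1))
  rev <- vapply(lens, function(l)
    revComp(substr(orf_nt, nchar(orf_nt) - l + 1L, nchar(orf_nt))),
    character(1))
  tmf <- vapply(fwd, primerTm, numeric(1))
  tmr <- vapply(rev, primerTm, numeric(1))

  grid <- expand.grid(i = seq_along(lens), j = seq_along(lens))
  diff <- abs(tmf[grid$i] - tmr[grid$j])
  dev <- abs(tmf[grid$i] - tm_target) + abs(tmr[grid$j] - tm_target)
  best <- order(diff > tm_window, diff + 0.1 * dev)[1]
  i <- grid$i[best]; j <- grid$j[best]
  list(forward = paste0(tail_f, fwd[i]),
       reverse = paste0(tail_r, rev[j]),
       core_f = unname(fwd[i]), core_r = unname(rev[j]),
       tm_f = unname(tmf[i]), tm_r = unname(tmr[j]),
       in_window = unname(abs(tmf[i] - tmr[j]) <= tm_window))
}
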