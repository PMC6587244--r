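hit <- function(aln, ref, que, bits = 200, evalue = 1e-30,
                q = "q1", s = "s1", fam = "GH5") {
  data.frame(query_id = q, subject_id = s, Align_length = aln,
             Ref_length = ref, Que_length = que, bits = bits,
             evalue = evalue, subject_family = fam,
             stringsAsFactors = FALSE)
}

test_that("BCR formula: worked examples and random-instance oracle", {
  b <- computeBcr(hit(200, 400, 500))
  expect_equal(b$BCR_Ref, 50.0)
  expect_equal(b$BCR_Que, 40.0)
  b2 <- computeBcr(hit(300, 300, 300))
  expect_equal(c(b2$BCR_Ref, b2$BCR_Que), c(100, 100))
  ## random instances against direct recomputation from the raw fields
  set.seed(42)
  for (i in 1:25) {
    ref <- sample(50:500, 1); que <- sample(50:500, 1)
    aln <- sample.int(min(ref, que), 1)
    b3 <- computeBcr(hit(aln, ref, que))
    expect_equal(b3$BCR_Ref, 100 * aln / ref)
    expect_equal(b3$BCR_Que, 100 * aln / que)
  }
})

test_that("BCR handles unit mixing, clamping and invalid records", {
  ## nt query vs aa subject: query length divided by 3
  b <- computeBcr(hit(100, 200, 600), query_units = "nt")
  expect_equal(b$BCR_Que, 100 * 100 / 200)
  ## over-long alignments (gapped columns) clamp to 100
  expect_warning(b2 <- computeBcr(hit(500, 400, 450)), "clamped")
  expect_equal(b2$BCR_Ref, 100)
  expect_true(b2$BCR_Que <= 100)
  ## zero-length record skipped with a warning, not an error
  expect_warning(b3 <- computeBcr(rbind(hit(10, 0, 50), hit(10, 50, 50))),
                 "skipped")
  expect_equal(nrow(b3), 1L)
})

test_that("filter boundaries: bits strict, BCR inclusive, e-value cap", {
  at60 <- computeBcr(hit(90, 100, 100, bits = 60))
  expect_equal(nrow(filterHits(at60)), 0L)          # 60 bits excluded
  over60 <- computeBcr(hit(90, 100, 100, bits = 60.1))
  expect_equal(nrow(filterHits(over60)), 1L)
  at40 <- computeBcr(hit(40, 100, 100, bits = 200)) # BCR exactly 40
  expect_equal(nrow(filterHits(at40)), 1L)          # retained
  under40 <- computeBcr(hit(39, 100, 100, bits = 200))
  expect_equal(nrow(filterHits(under40)), 0L)
  bad_e <- computeBcr(hit(90, 100, 100, evalue = 1e-4))
  expect_equal(nrow(filterHits(bad_e)), 0L)
})

test_that("filtering is idempotent and order-independent", {
  set.seed(7)
  hits <- do.call(rbind, lapply(1:40, function(i)
    hit(sample(20:100, 1), 100, 100, bits = sample(40:200, 1),
        evalue = 10^-sample(3:40, 1), q = sprintf("q%d", i))))
  hits <- computeBcr(hits)
  once <- filterHits(hits)
  expect_identical(filterHits(once), once)
  perm <- hits[sample.int(nrow(hits)), ]
  again <- filterHits(perm)
  expect_setequal(rownames(again), rownames(once))
})

test_that("family assignment keeps best hit per family with tie rules", {
  h <- rbind(hit(90, 100, 100, bits = 100, s = "sA", fam = "GH5"),
             hit(90, 100, 100, bits = 120, s = "sB", fam = "GH5"),
             hit(90, 100, 100, bits = 80, s = "sC", fam = "CBM3"))
  h <- computeBcr(h)
  ann <- assignFamilies(h)
  expect_equal(nrow(ann), 2L)  # one unigene, two families
  expect_equal(ann$subject_id[ann$family == "GH5"], "sB")
  ## equal bits -> lower e-value wins; still tied -> smallest subject id
  t1 <- rbind(hit(90, 100, 100, bits = 100, evalue = 1e-10, s = "sZ"),
              hit(90, 100, 100, bits = 100, evalue = 1e-20, s = "sY"))
  expect_equal(assignFamilies(computeBcr(t1))$subject_id, "sY")
  t2 <- rbind(hit(90, 100, 100, bits = 100, evalue = 1e-10, s = "sB"),
              hit(90, 100, 100, bits = 100, evalue = 1e-10, s = "sA"))
  expect_equal(assignFamilies(computeBcr(t2))$subject_id, "sA")
  ## empty in, empty out
  expect_equal(nrow(assignFamilies(computeBcr(hit(90,100,100))[0, ])), 0L)
})

test_that("family tabulation counts, classes and cellulase subset", {
  ann <- data.frame(
    query_id = c("q1", "q1", "q2", "q3", "q4"),
    family = c("GH5", "CBM3", "GH5", "GT2", "XYZ9"),
    stringsAsFactors = FALSE)
  expect_warning(tab <- tabulateFamilies(ann), "unclassified")
  expect_equal(tab$count[tab$family == "GH5"], 2L)
  expect_equal(tab$class[tab$family == "CBM3"], "CBM")
  expect_true(tab$cellulase[tab$family == "GH5"])
  expect_false(any(tab$cellulase[tab$family %in% c("GT2", "CBM3")]))
  ## class totals equal sums of member families
  expect_equal(sum(tab$count[tab$class == "GH"]), 2L)
  ## single annotation
  one <- tabulateFamilies(data.frame(query_id = "q", family = "GH5"))
  expect_equal(one$count, 1L)
})

test_that("annotation recovers the planted family mix exactly", {
  ct <- generateCommunity(5, 60, c(GH3 = .5, GH5 = .3, GH9 = .2),
                          seed = 31, orf_aa_range = c(210, 500))
  ug <- generateUnigenes(ct, flank_len = 60, frag_fraction = 0, seed = 32)
  hits <- generateHitTable(ct, ug, identity_noise = 0, decoy_rate = .4,
                           seed = 33)
  ann <- assignFamilies(filterHits(computeBcr(hits, query_units = "nt")))
  tab <- tabulateFamilies(ann)
  planted <- table(communityGenes(ct)$cazy_family)
  expect_equal(stats::setNames(tab$count, tab$family),
               stats::setNames(as.integer(planted), names(planted)))
  ## no query contributes twice to the same family
  expect_false(any(duplicated(ann[c("query_id", "family")])))
})

test_that("hit tables round-trip through the tab-separated format", {
  ct <- generateCommunity(4, 8, c(GH5 = 1), seed = 35)
  hits <- generateHitTable(ct, identity_noise = 1, decoy_rate = 0,
                           seed = 36)
  f <- tempfile(fileext = ".tsv")
  writeHitTable(hits, f)
  back <- readHitTable(f)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$bits, hits$bits)
  expect_equal(back$Ref_length, hits$Ref_length)
  expect_equal(back$subject_lineage, hits$subject_lineage)
})
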