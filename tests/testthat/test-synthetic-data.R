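test_that("generators are deterministic for a fixed seed", {
  a <- generateCommunity(5, 50, c(GH3 = .5, GH5 = .5), seed = 1)
  b <- generateCommunity(5, 50, c(GH3 = .5, GH5 = .5), seed = 1)
  expect_identical(communityGenes(a), communityGenes(b))
  expect_identical(communityAbundance(a), communityAbundance(b))

  ua <- generateUnigenes(a, flank_len = 30, frag_fraction = .2, seed = 2)
  ub <- generateUnigenes(b, flank_len = 30, frag_fraction = .2, seed = 2)
  expect_identical(as.character(ua$sequences), as.character(ub$sequences))
  expect_identical(ua$truth, ub$truth)

  expect_identical(generateHitTable(a, ua, 1, .3, seed = 3),
                   generateHitTable(a, ua, 1, .3, seed = 3))
  expect_identical(generateCounts(a, 3, 1e4, 2, seed = 4),
                   generateCounts(a, 3, 1e4, 2, seed = 4))
  enz <- data.frame(enzyme = "E", substrate = "CMC",
                    activity_u_per_mg = 10)
  expect_identical(generateAssayPlate(enz, 0.5, .05, .01, seed = 5),
                   generateAssayPlate(enz, 0.5, .05, .01, seed = 5))
})

test_that("community generation honours the family mix", {
  ct <- generateCommunity(4, 60, c(GH5 = 1), seed = 7)
  expect_true(all(communityGenes(ct)$cazy_family == "GH5"))
  expect_error(generateCommunity(1, 10, c(GH5 = 1), seed = 1))
  expect_error(generateCommunity(4, 0, c(GH5 = 1), seed = 1))
  expect_error(generateCommunity(4, 10, c(GH5 = 0, GH3 = 0), seed = 1))
})

test_that("family mix proportions land within 3 sigma of multinomial", {
  mix <- c(GH3 = .5, GH5 = .3, GH9 = .2)
  ct <- generateCommunity(6, 1000, mix, seed = 11)
  obs <- table(communityGenes(ct)$cazy_family)[names(mix)]
  exp_n <- 1000 * mix
  sd_n <- sqrt(1000 * mix * (1 - mix))
  expect_true(all(abs(obs - exp_n) <= 3 * sd_n))
})

test_that("community truth satisfies its invariants", {
  ct <- generateCommunity(10, 200, c(GH3 = .4, GH5 = .4, none = .2),
                          seed = 3)
  expect_true(validObject(ct))
  g <- communityGenes(ct)
  expect_true(all(g$orf_nt_length %% 3 == 0))
  expect_equal(sum(communityAbundance(ct)), 1, tolerance = 1e-12)
})

test_that("unigenes embed planted ORFs retrievably", {
  ct <- generateCommunity(5, 25, c(GH5 = 1), seed = 9,
                          orf_aa_range = c(210, 400))
  ug <- generateUnigenes(ct, flank_len = 60, frag_fraction = 0, seed = 10)
  tt <- ug$truth
  expect_false(any(tt$truncated))
  expect_equal(tt$orf_nt_length, communityGenes(ct)$orf_nt_length)
  ## every planted ORF is an exact stop-free stretch at the recorded spot
  orfs <- findOrfs(ug$sequences, min_len = 600)
  key <- paste(tt$unigene_id, tt$orf_start, tt$orf_end, tt$protein)
  found <- paste(orfs$unigene_id, orfs$start, orfs$end, orfs$protein)
  expect_true(all(key %in% found))
})

test_that("reverse-strand plants are only visible in reverse frames", {
  ct <- generateCommunity(4, 12, c(GH5 = 1), seed = 13,
                          orf_aa_range = c(210, 300))
  g <- communityGenes(ct)
  g$frame <- rep(5L, nrow(g))  # force reverse strand
  ct2 <- new("CommunityTruth", taxa = communityTaxa(ct),
             abundance = communityAbundance(ct), genes = g, seed = 13L)
  ug <- generateUnigenes(ct2, flank_len = 30, frag_fraction = 0, seed = 14)
  for (i in seq_len(3)) {
    bf <- bruteForceOrfs(as.character(ug$sequences[[i]]), 600)
    hit <- bf[bf$protein == ug$truth$protein[i], ]
    expect_equal(nrow(hit), 1L)
    expect_gt(hit$frame, 3L)
  }
})

test_that("flank_len = 0 gives bare-ORF unigenes", {
  ct <- generateCommunity(4, 10, c(GH3 = 1), seed = 21)
  ug <- generateUnigenes(ct, flank_len = 0, frag_fraction = 0, seed = 22)
  expect_equal(unname(nchar(as.character(ug$sequences))),
               ug$truth$orf_nt_length)
  expect_error(generateUnigenes(ct, flank_len = 2, seed = 1))
})

test_that("frag_fraction truncates ORFs below the 600-nt filter", {
  ct <- generateCommunity(4, 40, c(GH5 = 1), seed = 15,
                          orf_aa_range = c(250, 500))
  ug <- generateUnigenes(ct, flank_len = 30, frag_fraction = 0.5, seed = 16)
  tt <- ug$truth
  expect_equal(sum(tt$truncated), 20L)
  expect_true(all(tt$orf_nt_length[tt$truncated] < 600))
  orfs <- findOrfs(ug$sequences[tt$unigene_id[tt$truncated]], 600)
  ## truncated unigenes contribute no ORF matching their planted protein
  expect_false(any(orfs$protein %in% tt$protein[tt$truncated]))
})

test_that("clean hit tables pass all filters; decoys fail their one filter", {
  ct <- generateCommunity(5, 30, c(GH3 = .5, GH5 = .5), seed = 17,
                          orf_aa_range = c(210, 600))
  ug <- generateUnigenes(ct, flank_len = 60, frag_fraction = 0, seed = 18)
  clean <- generateHitTable(ct, ug, identity_noise = 0, decoy_rate = 0,
                            seed = 19)
  fh <- filterHits(computeBcr(clean, query_units = "nt"))
  expect_equal(nrow(fh), nrow(clean))

  noisy <- generateHitTable(ct, ug, identity_noise = 0, decoy_rate = 1,
                            seed = 19)
  dec <- computeBcr(noisy[noisy$is_decoy, ], query_units = "nt")
  kept <- filterHits(dec)
  expect_equal(nrow(kept), 0L)
  ## the constructed-BCR decoy fails specifically the coverage filter
  bcr_dec <- dec[dec$decoy_type == "bcr", ]
  expect_true(all(bcr_dec$BCR_Ref < 40))
  expect_true(all(bcr_dec$bits > 60 & bcr_dec$evalue <= 1e-5))
})

test_that("counts: silenced genes, moment recovery, library-size totals", {
  tr <- manualTruth(rates = c(0, 5, 5, 2), lengths_nt = c(900, 900, 300, 600))
  m <- generateCounts(tr, 4, 1e4, dispersion = Inf, seed = 23)
  expect_true(all(m["g01", ] == 0L))
  expect_true(all(m >= 0L))

  ## sample-mean recovery over 200 replicate samples, NB moments
  disp <- 5
  m2 <- generateCounts(tr, 200, 1e4, dispersion = disp, seed = 24)
  w <- c(0, 5 * .9, 5 * .3, 2 * .6)
  mu <- 1e4 * w / sum(w)
  sdm <- sqrt((mu + mu^2 / disp) / 200)
  expect_true(all(abs(rowMeans(m2) - mu)[mu > 0] <= 3 * sdm[mu > 0]))

  ## per-sample totals centre on the library size: the mean over the
  ## 200 samples sits within 3 standard errors, and no single sample
  ## strays beyond 4.5 sigma (Bonferroni-safe over 200 draws)
  sd_tot <- sqrt(sum(mu + mu^2 / disp))
  expect_lt(abs(mean(colSums(m2)) - 1e4), 3 * sd_tot / sqrt(200))
  expect_true(all(abs(colSums(m2) - 1e4) <= 4.5 * sd_tot))

  expect_error(generateCounts(tr, 2, 1e4, dispersion = 0, seed = 1))
  expect_error(generateCounts(tr, 2, 0, dispersion = 1, seed = 1))
})

test_that("assay plates invert exactly at zero noise", {
  enz <- data.frame(enzyme = c("A", "B"), substrate = c("CMC", "pNPC"),
                    activity_u_per_mg = c(222.2, 0))
  plate <- generateAssayPlate(enz, slope = 0.4, intercept = 0.05,
                              noise_sd = 0, seed = 25)
  cfg <- attr(plate, "config")
  ## zero-activity sample wells equal the control mean
  ctrl <- plate$absorbance[plate$role == "control" &
                             plate$substrate == "pNPC"]
  bwell <- plate$absorbance[plate$role == "sample" & plate$enzyme == "B"]
  expect_equal(mean(bwell), mean(ctrl))
  ## planted 222.2 U/mg recovered through the curve inversion
  std <- plate[plate$role == "standard", ]
  cv <- fitStandardCurve(std$conc, std$absorbance)
  sa <- specificActivity(
    mean(plate$absorbance[plate$role == "sample" & plate$enzyme == "A"]),
    cv, cfg$reaction_minutes, cfg$reaction_volume_ml, cfg$protein_mg)
  expect_equal(sa, 222.2, tolerance = 2e-2 / 100)
  expect_error(generateAssayPlate(enz, slope = -1, seed = 1))
  expect_error(generateAssayPlate(enz, slope = 1, replicates = 1, seed = 1))
})
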