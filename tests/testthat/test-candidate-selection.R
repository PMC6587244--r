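randomProt <- function(n) paste(
  sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
  collapse = "")

## mutate m positions of a protein
mutate <- function(p, m) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(p, "")[[1]]
  at <- sample(seq_along(ch), m)
  ch[at] <- sample(aa, m, replace = TRUE)
  paste(ch, collapse = "")
}

test_that("identity distances: identical zero, disjoint one, symmetric", {
  p <- c(a = "MKLVNNWQE", b = "MKLVNNWQE", c = "GGGGGGGGG")
  d <- pairwiseDistance(p)
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d, t(d))
  ## completely different residues -> distance 1
  q <- c(x = "WWWWWWWW", y = "KKKKKKKK", z = "MMMMMMMM")
  expect_equal(unname(pairwiseDistance(q)["x", "y"]), 1)
  expect_error(pairwiseDistance(c(one = "MK")))
  expect_error(pairwiseDistance(c(a = "MK", a = "ML", b = "MM")))
})

test_that("NJ reproduces additive distances exactly (4-8 taxa)", {
  set.seed(91)
  for (n in c(4, 5, 8)) {
    ref <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    ref <- ape::unroot(ref)
    d <- ape::cophenetic.phylo(ref)
    nj <- buildNjTree(d)
    ## same unrooted topology
    expect_equal(phangorn::RF.dist(nj, ref), 0)
    ## branch lengths reproduced: path lengths match
    expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("NJ three-taxon closed form and label permutation", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- buildNjTree(d)
  ## closed form: la = (dab + dac - dbc)/2, etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
  ## permuting labels yields an isomorphic tree
  p <- c("c", "a", "b")
  tr2 <- buildNjTree(d[p, p])
  expect_equal(ape::cophenetic.phylo(tr2)[p, p], d[p, p], tolerance = 1e-10)
  ## validation
  dd <- d; dd[1, 2] <- 9
  expect_error(buildNjTree(dd), "symmetric")
})

test_that("tree clustering spans the threshold extremes", {
  set.seed(93)
  prot <- setNames(vapply(1:6, function(i) randomProt(60), character(1)),
                   paste0("s", 1:6))
  tr <- buildNjTree(pairwiseDistance(prot))
  diam <- max(ape::cophenetic.phylo(tr))
  all_in <- clusterTree(tr, diam + 1)
  expect_equal(length(all_in$clusters), 1L)
  expect_setequal(all_in$clusters[[1]], names(prot))
  none <- clusterTree(tr, 1e-9)
  expect_equal(length(none$clusters), 0L)
  expect_setequal(none$unclustered, names(prot))
  expect_error(clusterTree(tr, 0))
})

test_that("a planted 8-cluster family is recovered at the generating threshold", {
  set.seed(95)
  centers <- lapply(1:8, function(i) randomProt(120))
  prots <- character(0)
  truth <- character(0)
  for (i in 1:8) {
    for (j in 1:3) {
      prots <- c(prots, mutate(centers[[i]], 6))
      truth <- c(truth, sprintf("c%d", i))
    }
  }
  names(prots) <- sprintf("m%02d", seq_along(prots))
  d <- pairwiseDistance(prots)
  tr <- buildNjTree(d)
  cl <- clusterTree(tr, 0.4)
  expect_equal(length(cl$clusters), 8L)
  expect_equal(length(cl$unclustered), 0L)
  ## members co-cluster with their generating center
  for (g in cl$clusters)
    expect_equal(length(unique(truth[match(g, names(prots))])), 1L)
  ## every leaf appears exactly once
  all_members <- c(unlist(cl$clusters), cl$unclustered)
  expect_setequal(all_members, names(prots))
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("candidate selection is stratified, capped and seeded", {
  cl <- list(clusters = list(cluster1 = c("a", "b", "c"),
                             cluster2 = c("d"),
                             cluster3 = character(0)),
             unclustered = c("x", "y"))
  expect_warning(sel <- selectCandidates(cl, 2, seed = 5), "empty")
  ## every nonempty stratum represented
  expect_setequal(unique(sel$stratum),
                  c("cluster1", "cluster2", "unclustered"))
  ## a stratum smaller than per_cluster is taken whole
  expect_equal(sel$candidate[sel$stratum == "cluster2"], "d")
  expect_equal(sum(sel$stratum == "cluster1"), 2L)
  ## deterministic under the seed
  expect_identical(sel, suppressWarnings(selectCandidates(cl, 2, seed = 5)))
})

test_that("primer pairs carry the vector tails and exact ORF termini", {
  set.seed(97)
  orf <- randomDna(900)
  pr <- designPrimers(orf)
  expect_true(startsWith(pr$forward, "GGCCATGGCTGATATCGGATCC"))
  expect_true(startsWith(pr$reverse, "CTTGTCGACGGAGCTCGAATTC"))
  ## stripped cores reconstruct the ORF termini exactly
  expect_equal(pr$core_f, substr(orf, 1, nchar(pr$core_f)))
  expect_equal(rc(pr$core_r),
               substr(orf, 901 - nchar(pr$core_r), 900))
  expect_equal(pr$tm_f, primerTm(pr$core_f))
  ## Wallace rule: 10 A/T and 10 G/C -> 60 C
  expect_equal(tmWallace("ATATATATATGCGCGCGCGC"), 60)
  expect_error(designPrimers(randomDna(20)))
})
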