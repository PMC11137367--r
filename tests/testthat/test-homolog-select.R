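test_that("global identity matches the worked examples and the DP oracle", {
  p <- randomProtein(40, seed = 1)
  expect_equal(globalIdentity(p, p), 1.0)
  expect_equal(globalIdentity("AAAA", "AATA"), 0.75)
  expect_error(globalIdentity("", "AA"), "non-empty")
  ## random short pairs against the independent R dynamic program
  for (s in 1:8) {
    a <- randomProtein(sample(10:30, 1), seed = s)
    b <- randomProtein(sample(10:30, 1), seed = s + 100)
    expect_equal(globalIdentity(a, b), nwIdentityOracle(a, b),
                 info = paste("seed", s))
  }
  ## identity uses the shorter-sequence denominator
  long <- paste0(p, randomProtein(20, seed = 55))
  expect_equal(globalIdentity(p, long), 1.0)
})

test_that("seed filtering is strict and recovers planted identities", {
  seedP <- randomProtein(200, seed = 3)
  fam <- plantHomologFamily(seedP, 6, c(0.30, 0.30, 0.60, 0.60, 0.90, 0.90),
                            seed = 11)
  kept <- filterByIdentity(seedP, fam$proteins, minIdentity = 0.45)
  expect_setequal(names(kept),
                  fam$realized$id[fam$realized$realized > 0.45])
  expect_setequal(names(kept), fam$realized$id[3:6])  # 0.6 and 0.9 pairs
  ## boundary: exactly at the cutoff is dropped ("more than" rule)
  s20 <- paste(rep("A", 20), collapse = "")
  c45 <- paste(c(rep("A", 9), rep("C", 11)), collapse = "")  # 9/20 = 0.45
  expect_equal(globalIdentity(s20, c45), 0.45)
  expect_length(filterByIdentity(s20, c(x = c45), minIdentity = 0.45), 0L)
  ## the seed itself always survives any cutoff < 1
  expect_length(filterByIdentity(seedP, c(seed = seedP),
                                 minIdentity = 0.999), 1L)
})

test_that("greedy clustering satisfies its invariant and planted structure", {
  ## three identical sequences -> one cluster of three
  tri <- setNames(rep(randomProtein(50, seed = 2), 3), c("a", "b", "c"))
  cl <- greedyCluster(tri, threshold = 0.75)
  expect_equal(unique(cl$cluster_id), 1L)
  expect_equal(nrow(cl), 3L)
  ## representative is the longest member (ties by id)
  expect_equal(unique(cl$representative), "a")

  ## two planted families, tight within / distant between -> 2 clusters
  fam1 <- plantHomologFamily(randomProtein(150, seed = 5), 4, 0.92,
                             seed = 21, prefix = "famA")
  fam2 <- plantHomologFamily(randomProtein(150, seed = 6), 4, 0.92,
                             seed = 22, prefix = "famB")
  all8 <- c(fam1$proteins, fam2$proteins)
  cl2 <- greedyCluster(all8, threshold = 0.75)
  expect_equal(length(unique(cl2$cluster_id)), 2L)
  split_fam <- split(sub("_.*", "", cl2$member), cl2$cluster_id)
  expect_true(all(vapply(split_fam, function(x) length(unique(x)) == 1L,
                         logical(1))))
  ## invariant: every member has identity >= threshold to its rep
  expect_true(all(cl2$identity_to_rep >= 0.75))
  reps <- setNames(cl2$representative, cl2$member)
  for (k in seq_len(nrow(cl2)))
    expect_gte(globalIdentity(all8[[cl2$member[k]]],
                              all8[[cl2$representative[k]]]), 0.75)

  ## impossible threshold -> all singletons
  dist4 <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(s) randomProtein(60, seed = 30 + s), ""),
    paste0("d", 1:4)))
  cl3 <- greedyCluster(dist4, threshold = 1 + 1e-9)
  expect_equal(length(unique(cl3$cluster_id)), 4L)
})

test_that("neighbor joining matches the 3-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 1, tolerance = 1e-9)
  expect_equal(unname(bl["B"]), 1, tolerance = 1e-9)
  expect_equal(unname(bl["C"]), 3, tolerance = 1e-9)
  expect_error(njTree(d[1:2, 1:2]), "size >= 3")
  d2 <- d; d2[1, 2] <- 3
  expect_error(njTree(d2), "symmetric")
})

test_that("NJ exactly recovers additive and ultrametric trees", {
  ## additive 5-taxon matrix from a known random tree
  for (s in 1:10) {
    tr <- withr::with_seed(s, ape::rtree(5, rooted = FALSE,
                                         br = function(k)
                                           runif(k, 0.1, 1)))
    D <- ape::cophenetic.phylo(tr)
    est <- njTree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), est), 0,
                 ignore_attr = TRUE)
    D2 <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-9)
  }
  ## ultrametric balanced 4-taxon matrix: correct split
  D <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 2,
                8, 8, 2, 0), 4,
              dimnames = list(c("a1", "a2", "b1", "b2"),
                              c("a1", "a2", "b1", "b2")))
  est <- njTree(D)
  D2 <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
  expect_lt(max(abs(D2 - D)), 1e-9)
})

test_that("NJ output is deterministic, byte-identical newick", {
  seqs <- plantHomologFamily(randomProtein(120, seed = 9), 6,
                             c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                             seed = 17)$proteins
  d <- 1 - identityMatrix(seqs)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeTreeNewick(njTree(d), f1)
  writeTreeNewick(njTree(d), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("representative picking cuts long edges and returns medoids", {
  ## five planted clades of four leaves each, long stems
  nwk <- paste0("(", paste(vapply(1:5, function(c)
    paste0("(", paste0("t", c, "_", 1:4, ":0.1", collapse = ","), "):5"),
    ""), collapse = ","), ");")
  tree <- ape::unroot(ape::read.tree(text = nwk))
  reps <- pickRepresentatives(tree, 5)
  expect_length(reps, 5L)
  expect_setequal(sub("_.*", "", reps), paste0("t", 1:5))
  ## nGroups == leaf count -> every leaf
  expect_setequal(pickRepresentatives(tree, 20), tree$tip.label)
  ## nGroups == 1 -> the global medoid
  D <- ape::cophenetic.phylo(tree)
  med <- names(which.min(colMeans(D)))
  expect_identical(pickRepresentatives(tree, 1), med)
  expect_error(pickRepresentatives(tree, 0), ">= 1")
  expect_error(pickRepresentatives(tree, 21), "leaf count")
})

test_that("the full homolog pipeline returns one pick per planted branch", {
  seeds <- vapply(1:5, function(s) randomProtein(140, seed = 40 + s), "")
  fams <- lapply(1:5, function(i)
    plantHomologFamily(seeds[i], 4, 0.92, seed = 60 + i,
                       prefix = paste0("fam", i))$proteins)
  cand <- do.call(c, fams)
  ## seed the search with a member of family 1; between-family identity is
  ## low, so use a permissive seed filter to retain all families
  res <- selectHomologs(seeds[1], cand, minSeedIdentity = 0.05,
                        clusterThreshold = 0.75, nGroups = 5)
  expect_equal(length(unique(res$clusters$cluster_id)), 5L)
  expect_length(res$representatives, 5L)
  expect_setequal(sub("_.*", "", res$representatives),
                  paste0("fam", 1:5))
})
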