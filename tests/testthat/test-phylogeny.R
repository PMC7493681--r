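# Frequency/core distances, neighbor joining, and monophyly reporting.

test_that("jaccard frequency distance matches set arithmetic", {
  m <- matrix(c(1L, 1L, 0L, 0L,
                1L, 0L, 0L, 1L,
                0L, 0L, 1L, 1L,
                1L, 1L, 1L, 0L), 4, 4, byrow = TRUE,
              dimnames = list(paste0("C", 1:4), c("g1", "g2", "g3", "g4")))
  class(m) <- c("pa_matrix", class(m))
  d <- frequency_distance(m, "jaccard")
  # g1 {C1,C2,C4}, g2 {C1,C4}: shared 2, union 3
  expect_equal(d["g1", "g2"], 1 - 2 / 3)
  # g1 vs g3 {C3,C4}: shared 1, union 4
  expect_equal(d["g1", "g3"], 1 - 1 / 4)
  # identical presence rows -> 0; disjoint -> 1
  m2 <- matrix(c(1L, 1L, 0L,
                 1L, 1L, 0L,
                 0L, 0L, 2L), 3, 3, byrow = TRUE,
               dimnames = list(paste0("K", 1:3), c("a", "b", "c")))
  class(m2) <- c("pa_matrix", class(m2))
  d2 <- frequency_distance(m2, "jaccard")
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  expect_equal(diag(d2), c(a = 0, b = 0, c = 0))
  # genome with zero clusters is an error
  m3 <- m2; m3[, "c"] <- 0L
  expect_error(frequency_distance(m3), "zero clusters")
})

test_that("core-identity distance is the mean over shared single-copy clusters", {
  genes <- data.frame(
    gene_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    genome_id = rep(c("gA", "gB"), each = 3),
    sequence = c("ACGTACGTAC", "GGGGCCCCAA", "TTTTAAACCC",
                 "ACGTACGTAC", "GGGGCCCCTT", "TTTTAAACCC"),
    stringsAsFactors = FALSE)
  cl <- structure(list(
    members = data.frame(
      cluster_id = rep(c("C1", "C2", "C3"), 2),
      gene_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
      genome_id = rep(c("gA", "gB"), each = 3),
      identity = 1, stringsAsFactors = FALSE),
    representatives = data.frame(cluster_id = c("C1", "C2", "C3"),
                                 gene_id = c("a1", "a2", "a3"),
                                 sequence = NA, stringsAsFactors = FALSE),
    threshold = 0.5), class = "gene_clusters")
  d <- core_identity_distance(genes, cl, c("C1", "C2", "C3"))
  hand <- 1 - mean(c(pairwise_identity("ACGTACGTAC", "ACGTACGTAC")$identity,
                     pairwise_identity("GGGGCCCCAA", "GGGGCCCCTT")$identity,
                     pairwise_identity("TTTTAAACCC", "TTTTAAACCC")$identity))
  expect_equal(d["gA", "gB"], hand)
  # identical core genes -> distance 0
  d0 <- core_identity_distance(genes, cl, c("C1", "C3"))
  expect_equal(d0["gA", "gB"], 0)
  # no shared single-copy core cluster -> error (gA gains a paralogous
  # second copy in C1, so C1 is unusable for the gA/gB pair)
  cl$members$genome_id[4] <- "gA"
  expect_error(core_identity_distance(genes, cl, "C1"), "single-copy")
})

test_that("NJ recovers the worked 4-leaf additive case with branch lengths", {
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(d)
  # topology: split AB|CD
  target <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(target)), 0)
  # terminal branch lengths as generated: A 1, B 2, C 3, D 1
  tip_len <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                             tree$edge[, 2])],
                      tree$tip.label)
  expect_equal(tip_len[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 1))
  # the internal edge has length 1
  internal <- tree$edge.length[!(tree$edge[, 2] %in% seq_along(tree$tip.label))]
  expect_equal(sum(internal), 1)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 leaves")
  d2 <- d; d2[1, 2] <- 9
  expect_error(neighbor_joining(d2), "symmetric")
})

test_that("3-leaf star branch lengths follow the closed-form formulas", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tree <- neighbor_joining(d)
  tip_len <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                             tree$edge[, 2])],
                      tree$tip.label)
  expect_equal(tip_len[["a"]], (3 + 4 - 5) / 2)
  expect_equal(tip_len[["b"]], (3 + 5 - 4) / 2)
  expect_equal(tip_len[["c"]], (4 + 5 - 3) / 2)
})

test_that("NJ reconstructs random additive topologies exactly", {
  for (seed in 1:20) {
    set.seed(seed)
    t0 <- ape::rtree(10, br = function(n) runif(n, 0.1, 1))
    d <- ape::cophenetic.phylo(t0)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tree <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(t0)), 0)
  }
})

test_that("taxa form monophyletic clades on simulated data; relabeling is caught", {
  fx <- tiny_sim()
  tree <- neighbor_joining(frequency_distance(fx$matrix, "jaccard"))
  rep1 <- monophyly_report(tree, fx$manifest)
  expect_true(all(rep1$monophyletic))
  # relabel one genome into another taxon: that taxon becomes
  # non-monophyletic and names the foreign genome
  man2 <- fx$manifest
  moved <- man2$genome_id[man2$taxon == "taxon01"][1]
  man2$taxon[man2$genome_id == moved] <- "taxon02"
  rep2 <- monophyly_report(tree, man2)
  bad <- rep2[rep2$taxon == "taxon02", ]
  expect_false(bad$monophyletic)
  expect_match(bad$offending, "taxon01|taxon03")
  # single-genome taxon is trivially monophyletic
  man3 <- fx$manifest
  man3$taxon[man3$genome_id == moved] <- "loner"
  rep3 <- monophyly_report(tree, man3)
  expect_true(rep3$monophyletic[rep3$taxon == "loner"])
})

test_that("core tree separates taxa when cross divergence is high", {
  fx <- tiny_sim()
  part <- partition_pangenome(fx$matrix)
  # genus-wide core at this divergence = the decoy families
  expect_gt(length(part$core), 0)
  d <- core_identity_distance(fx$genes, fx$clusters, part$core)
  tree <- neighbor_joining(d)
  rep <- monophyly_report(tree, fx$manifest)
  expect_true(all(rep$monophyletic))
  within <- d["taxon01_g01", "taxon01_g02"]
  cross <- d["taxon01_g01", "taxon02_g01"]
  expect_lt(within, cross)
})
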