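# Marker candidate selection, cross/within screening, mobile-element
# exclusion, and the verification matrix.

test_that("planted markers are accepted and decoys rejected on fixtures", {
  fx <- tiny_sim()
  fams <- cluster_families(fx$clusters, fx$sim$truth)
  pm <- planted_markers(fx$sim$truth)
  for (tx in unique(fx$manifest$taxon)) {
    cand <- select_candidates(fx$clusters, fx$matrix, fx$manifest, fx$genes, tx)
    acc <- accepted_markers(cand)
    # every planted marker of the taxon is accepted ...
    for (f in pm$family[pm$taxon == tx]) {
      cid <- names(fams)[fams == f]
      expect_true(cid %in% acc$cluster_id)
    }
    # ... no decoy is, and each decoy is rejected for cross-identity
    dec <- names(fams)[grepl("decoy", fams)]
    hit <- cand[cand$cluster_id %in% dec, ]
    expect_true(all(hit$status == "rejected_cross"))
    expect_true(all(hit$cross_max_identity > 0.5))
    # accepted cross identities re-verified by exhaustive alignment
    nontarget <- fx$genes$sequence[
      fx$genes$genome_id %in% fx$manifest$genome_id[fx$manifest$taxon != tx]]
    for (i in seq_len(nrow(acc))) {
      ids <- vapply(nontarget, function(s)
        pairwise_identity(acc$sequence[i], s)$identity, numeric(1))
      expect_lte(max(ids), 0.5)
    }
    # candidates are sorted by cross asc then within desc
    expect_true(!is.unsorted(cand$cross_max_identity))
  }
})

test_that("a single-taxon input accepts its core vacuously with cross 0", {
  fx <- tiny_sim()
  keep <- fx$manifest$taxon == "taxon01"
  man1 <- fx$manifest[keep, ]
  genes1 <- fx$genes[fx$genes$genome_id %in% man1$genome_id, ]
  cl1 <- cluster_genes(genes1)
  m1 <- build_matrix(cl1, man1)
  cand <- select_candidates(cl1, m1, man1, genes1, "taxon01")
  expect_true(all(cand$status[cand$replicon != "plasmid"] == "accepted"))
  expect_true(all(cand$cross_max_identity == 0))
  expect_error(select_candidates(cl1, m1, man1, genes1, "ghost"), "no genomes")
})

test_that("tightening either threshold never grows the accepted set", {
  fx <- tiny_sim()
  base <- accepted_markers(select_candidates(fx$clusters, fx$matrix,
                                             fx$manifest, fx$genes, "taxon01"))
  tighter_cross <- accepted_markers(
    select_candidates(fx$clusters, fx$matrix, fx$manifest, fx$genes, "taxon01",
                      id_cross = 0.3))
  higher_within <- accepted_markers(
    select_candidates(fx$clusters, fx$matrix, fx$manifest, fx$genes, "taxon01",
                      id_within = 0.95))
  expect_true(all(tighter_cross$cluster_id %in% base$cluster_id))
  expect_true(all(higher_within$cluster_id %in% base$cluster_id))
})

test_that("prefilter on/off assigns identical statuses", {
  fx <- tiny_sim()
  on <- select_candidates(fx$clusters, fx$matrix, fx$manifest, fx$genes,
                          "taxon02", use_prefilter = TRUE)
  off <- select_candidates(fx$clusters, fx$matrix, fx$manifest, fx$genes,
                           "taxon02", use_prefilter = FALSE)
  expect_setequal(on$cluster_id, off$cluster_id)
  expect_identical(setNames(on$status, on$cluster_id)[sort(on$cluster_id)],
                   setNames(off$status, off$cluster_id)[sort(off$cluster_id)])
})

test_that("plasmid-borne and exclusion-set markers are rejected as mobile", {
  fx <- tiny_sim()
  cand <- select_candidates(fx$clusters, fx$matrix, fx$manifest, fx$genes,
                            "taxon01")
  acc <- accepted_markers(cand)
  expect_gt(nrow(acc), 0)

  # flag the first accepted marker's source genes as plasmid-borne
  genes_pl <- fx$genes
  memb <- fx$clusters$members$gene_id[
    fx$clusters$members$cluster_id == acc$cluster_id[1]]
  genes_pl$replicon[genes_pl$gene_id %in% memb] <- "plasmid"
  cand_pl <- select_candidates(fx$clusters, fx$matrix, fx$manifest, genes_pl,
                               "taxon01")
  expect_equal(cand_pl$status[cand_pl$cluster_id == acc$cluster_id[1]],
               "rejected_mobile")

  # exclusion FASTA containing the marker itself
  excl <- tempfile(fileext = ".fasta")
  writeLines(c(">mobile1", acc$sequence[1]), excl)
  filt <- mobile_element_filter(cand, fx$genes, fx$clusters, fx$manifest,
                                exclusion_fasta = excl)
  expect_equal(filt$status[filt$cluster_id == acc$cluster_id[1]],
               "rejected_mobile")

  # chromosome marker with empty exclusion set: unchanged
  filt2 <- mobile_element_filter(cand, fx$genes, fx$clusters, fx$manifest)
  expect_identical(filt2$status, cand$status)
  expect_error(
    mobile_element_filter(cand, fx$genes, fx$clusters, fx$manifest,
                          exclusion_fasta = tempfile()),
    "exclusion")
})

test_that("verification matrix separates target and non-target genomes", {
  fx <- tiny_sim()
  acc <- do.call(rbind, lapply(unique(fx$manifest$taxon), function(tx)
    accepted_markers(select_candidates(fx$clusters, fx$matrix, fx$manifest,
                                       fx$genes, tx))))
  fams <- cluster_families(fx$clusters, fx$sim$truth)
  planted <- acc[grepl("marker", fams[acc$cluster_id]), ]
  vm <- verify_markers(planted, fx$genes, fx$manifest)
  expect_true(all(vm >= 0 & vm <= 1))
  for (i in seq_len(nrow(planted))) {
    target <- fx$manifest$genome_id[fx$manifest$taxon == planted$taxon[i]]
    expect_true(all(vm[i, target] >= 0.9))
    expect_true(all(vm[i, setdiff(colnames(vm), target)] <= 0.5))
    # the marker's own source genome scores at least within_min_identity
    src <- fx$genes$genome_id[fx$genes$gene_id == planted$gene_id[i]]
    expect_gte(vm[i, src], planted$within_min_identity[i])
  }
  # a genome with no genes gives a zero column
  man_extra <- rbind(fx$manifest,
                     data.frame(genome_id = "empty_g01", taxon = "taxon01"))
  vm2 <- verify_markers(planted, fx$genes, man_extra)
  expect_true(all(vm2[, "empty_g01"] == 0))
})
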