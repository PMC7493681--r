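# Synthetic pan-genome generator: counts, determinism, planted-marker
# contract, plasmid placement.

test_that("minimal one-genome spec produces exactly the forced gene set", {
  spec <- simulation_spec(n_taxa = 1, genomes_per_taxon = 1, n_genus_core = 1,
                          n_taxon_markers = 1, n_accessory = 0, n_decoy = 0,
                          within_taxon_sub_rate = 0, cross_taxon_divergence = 0,
                          plasmid_fraction = 0, seed = 1)
  sim <- simulate_pangenome(spec, tempfile())
  expect_equal(nrow(sim$truth), 2L)
  expect_equal(sort(unique(sim$truth$type)), c("core", "marker"))
  expect_equal(nrow(planted_markers(sim$truth)), 1L)
  expect_equal(nrow(sim$manifest), 1L)
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(simulation_spec(n_taxa = 0), "n_taxa")
  expect_error(simulation_spec(within_taxon_sub_rate = 0.5),
               "within_taxon_sub_rate")
  expect_error(simulation_spec(cross_taxon_divergence = 0.1),
               "cross_taxon_divergence")
  expect_error(simulation_spec(decoy_identity_band = c(0.9, 0.7)),
               "decoy_identity_band")
  expect_error(simulation_spec(plasmid_fraction = 1.5), "plasmid_fraction")
  expect_error(simulation_spec(gene_length_range = c(10, 5)),
               "gene_length_range")
})

test_that("identical seeds give byte-identical output, different seeds differ", {
  spec <- simulation_spec(n_taxa = 2, genomes_per_taxon = 2, n_genus_core = 2,
                          n_taxon_markers = 1, n_accessory = 2, n_decoy = 1,
                          gene_length_range = c(150, 300), seed = 13)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  simulate_pangenome(spec, d1)
  simulate_pangenome(spec, d2)
  spec2 <- simulation_spec(n_taxa = 2, genomes_per_taxon = 2, n_genus_core = 2,
                           n_taxon_markers = 1, n_accessory = 2, n_decoy = 1,
                           gene_length_range = c(150, 300), seed = 14)
  simulate_pangenome(spec2, d3)
  files <- function(d) list.files(d, recursive = TRUE, full.names = TRUE)
  h <- function(d) vapply(files(d), function(f) unname(tools::md5sum(f)),
                          character(1), USE.NAMES = FALSE)
  expect_identical(basename(files(d1)), basename(files(d2)))
  expect_identical(h(d1), h(d2))
  expect_false(identical(h(d1), h(d3)))
})

test_that("per-genome CDS counts reconcile with the truth table", {
  fx <- tiny_sim()
  truth <- fx$sim$truth
  for (g in fx$manifest$genome_id) {
    fa <- Biostrings::readBStringSet(
      file.path(dirname(fx$sim$cds_paths[1]), paste0(g, "_cds.fasta")))
    expect_equal(length(fa), sum(truth$genome_id == g))
  }
  # every genome carries core + own markers + decoys
  spec <- fx$spec
  base <- spec$n_genus_core + spec$n_taxon_markers + spec$n_decoy
  counts <- table(truth$genome_id)
  expect_true(all(counts >= base))
})

test_that("planted markers satisfy the identity contract under an independent oracle", {
  fx <- tiny_sim()
  truth <- fx$sim$truth
  genes <- fx$genes
  pm <- planted_markers(truth)
  for (i in seq_len(nrow(pm))) {
    ids <- truth$gene_id[truth$family == pm$family[i]]
    seqs <- genes$sequence[match(ids, genes$gene_id)]
    # within-taxon: all pairwise identities >= 0.90 by the R DP oracle
    for (a in seq_len(length(seqs) - 1)) {
      for (b in (a + 1):length(seqs)) {
        expect_gte(oracle_align(seqs[a], seqs[b])$identity, 0.90)
      }
    }
    # cross-taxon: against every gene of every other-taxon genome
    other <- genes$sequence[genes$genome_id %in%
                              fx$manifest$genome_id[fx$manifest$taxon != pm$taxon[i]]]
    cross <- vapply(other, function(s)
      pairwise_identity(seqs[1], s)$identity, numeric(1))
    expect_lte(max(cross), 0.50)
  }
})

test_that("decoy families land inside the decoy identity band across taxa", {
  fx <- tiny_sim()
  truth <- fx$sim$truth
  genes <- fx$genes
  band <- fx$spec$decoy_identity_band
  dec <- unique(truth$family[truth$type == "decoy"])
  for (f in dec) {
    rows <- truth[truth$family == f, ]
    one_per_taxon <- rows[!duplicated(rows$taxon), ]
    seqs <- genes$sequence[match(one_per_taxon$gene_id, genes$gene_id)]
    for (a in seq_len(length(seqs) - 1)) {
      for (b in (a + 1):length(seqs)) {
        id <- pairwise_identity(seqs[a], seqs[b])$identity
        # within-genome noise (1%) can push copies slightly past the
        # variant-level band that the generator enforces
        expect_gte(id, band[1] - 0.03)
        expect_lte(id, band[2] + 0.03)
      }
    }
  }
})

test_that("plasmid contigs are emitted, flagged, and carry accessory genes", {
  spec <- simulation_spec(n_taxa = 2, genomes_per_taxon = 2, n_genus_core = 2,
                          n_taxon_markers = 1, n_accessory = 6, n_decoy = 0,
                          plasmid_fraction = 1, gene_length_range = c(150, 300),
                          seed = 3)
  sim <- simulate_pangenome(spec, tempfile())
  pl <- sim$truth[sim$truth$replicon == "plasmid", ]
  expect_gt(nrow(pl), 0)
  expect_true(all(pl$type == "accessory"))
  # headers carry the replicon tag
  one <- readLines(sim$genome_paths[match(pl$genome_id[1],
                                          sim$manifest$genome_id)])
  expect_true(any(grepl("replicon=plasmid", one)))
})

test_that("gene placements respect contig bounds and strand encoding", {
  fx <- tiny_sim()
  truth <- fx$sim$truth
  for (g in fx$manifest$genome_id) {
    rec <- fx$gset$genomes[[g]]
    rows <- truth[truth$genome_id == g, ]
    for (i in seq_len(nrow(rows))) {
      slice <- substring(rec$contigs[[rows$contig_id[i]]],
                         rows$start[i] + 1, rows$end[i])
      coding <- if (rows$strand[i] == "+") slice else revcomp(slice)
      expect_identical(coding,
                       fx$genes$sequence[fx$genes$gene_id == rows$gene_id[i]])
    }
  }
})
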