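# Melting temperature, primer design, and in-silico PCR.

test_that("wallace rule and nn thermodynamics match hand values and oracle", {
  expect_equal(melting_temperature("ACGT", method = "wallace"), 12)
  expect_equal(melting_temperature("GGGG", method = "wallace"), 16)
  expect_error(melting_temperature("ACG"), "length")
  expect_error(melting_temperature(paste(rep("A", 40), collapse = "")),
               "length")
  expect_error(melting_temperature("ACGTN"), "oligo")

  # nn Tm vs an independently coded nearest-neighbor oracle, over the
  # published assay panel
  pairs <- read_primer_table(system.file("extdata",
                                         "bifidobacterium_primers.tsv",
                                         package = "panmarker"))
  for (o in c(pairs$forward, pairs$reverse)) {
    expect_lt(abs(melting_temperature(o) - oracle_tm_nn(o)), 0.1)
  }
  # assay-panel oligos sit near the 60 C annealing step
  tms <- vapply(c(pairs$forward, pairs$reverse), melting_temperature,
                numeric(1))
  expect_true(all(tms > 50 & tms < 70))
})

test_that("dimer and hairpin scores behave on constructed cases", {
  # perfect self-complement run
  expect_gte(dimer_score("ACGTACGT", "ACGTACGT"), 8)
  # 3'-anchored complementarity is weighted double
  a <- "AAAAAAAAAAGGGCCC" # 3' CCC pairs GGG
  expect_gte(dimer_score(a, a), 6)
  expect_equal(hairpin_score("AAAAAAAAAAAAAAAAAAA"), 0)
  # stem GGGG...CCCC with a 5-nt loop
  expect_gte(hairpin_score("GGGGAATTACCCC"), 4)
})

test_that("primer design returns the engineered site pair on a planted marker", {
  set.seed(5)
  F <- "CAGACCTCGCCGATGAGCTA"
  R <- "GTCGCCAACCTTGACCACTT"
  at <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
  marker <- paste0(at(70), F, at(75), revcomp(R), at(70))
  pp <- design_primers(marker, top_n = 3)
  expect_gt(nrow(pp), 0)
  cs <- primer_constraints()
  # the top pair sits on the engineered sites (the AT background is
  # undesignable) and satisfies every constraint by direct recomputation
  expect_lt(pp$fwd_start[1], 90)
  expect_gt(pp$fwd_end[1], 70)
  expect_lt(pp$rev_start[1], 185)
  expect_gt(pp$rev_end[1], 165)
  for (i in seq_len(nrow(pp))) {
    expect_true(pp$product_size[i] >= cs$min_amplicon &&
                  pp$product_size[i] <= cs$max_amplicon)
    for (o in c(pp$forward[i], pp$reverse[i])) {
      tm <- melting_temperature(o)
      expect_true(tm >= cs$tm_range[1] && tm <= cs$tm_range[2])
      gc <- gc_fraction(o)
      expect_true(gc >= cs$gc_range[1] && gc <= cs$gc_range[2])
      expect_lte(max(rle(strsplit(o, NULL)[[1]])$lengths), cs$max_homopolymer)
      expect_lte(hairpin_score(o), cs$max_hairpin_score)
    }
    expect_lte(pp$dimer_score[i], cs$max_dimer_score)
    expect_equal(pp$product_size[i], pp$rev_end[i] - pp$fwd_start[i])
  }
  # re-running in-silico PCR on the source marker reproduces the product
  hits <- in_silico_pcr(pp[1, ], list(m = c(ctg = marker)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_size, pp$product_size[1])

  expect_error(design_primers(substr(marker, 1, 60)), "min_amplicon")
})

test_that("conservation mask excludes variable windows", {
  set.seed(6)
  F <- "CAGACCTCGCCGATGAGCTA"
  R <- "GTCGCCAACCTTGACCACTT"
  at <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
  marker <- paste0(at(70), F, at(75), revcomp(R), at(70))
  mask <- rep(TRUE, nchar(marker))
  mask[71:90] <- FALSE # forward site variable across strains
  pp <- design_primers(marker, top_n = 3, conservation = mask)
  if (nrow(pp)) {
    # no returned oligo may overlap the masked window
    expect_true(all(pp$fwd_end <= 70 | pp$fwd_start >= 90))
  } else {
    succeed() # nothing designable without the forward site
  }
})

test_that("in-silico PCR finds constructed amplicons under the binding model", {
  set.seed(8)
  F <- "CAGACCTCGCCGATGAGCTA"
  R <- "GTCGCCAACCTTGACCACTT"
  mid <- random_dna(70)
  tmpl <- paste0(F, mid, revcomp(R)) # 110 nt product
  pair <- list(forward = F, reverse = R, name = "p1")
  hits <- in_silico_pcr(pair, list(g = c(c1 = tmpl)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_size, 110L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 110L)
  expect_equal(hits$strand, "+")

  # the same template reverse-complemented: same product on "-"
  hits_rc <- in_silico_pcr(pair, list(g = c(c1 = revcomp(tmpl))))
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$product_size, 110L)
  expect_equal(hits_rc$strand, "-")

  # three substitutions inside the forward site exceed max_mismatch = 2
  Fbad <- F
  substr(Fbad, 3, 3) <- "T"; substr(Fbad, 7, 7) <- "A"
  substr(Fbad, 11, 11) <- "T"
  tmpl3 <- paste0(Fbad, mid, revcomp(R))
  expect_equal(nrow(in_silico_pcr(pair, list(g = c(c1 = tmpl3)))), 0L)
  # a single mismatch in the 3'-exact window also kills the site
  Ftp <- F
  substr(Ftp, 20, 20) <- if (substr(F, 20, 20) == "A") "C" else "A"
  tmpl4 <- paste0(Ftp, mid, revcomp(R))
  expect_equal(nrow(in_silico_pcr(pair, list(g = c(c1 = tmpl4)))), 0L)
  # ... but two mismatches outside it are tolerated
  F2 <- F
  substr(F2, 3, 3) <- "T"; substr(F2, 7, 7) <- "A"
  tmpl5 <- paste0(F2, mid, revcomp(R))
  h5 <- in_silico_pcr(pair, list(g = c(c1 = tmpl5)))
  expect_equal(nrow(h5), 1L)
  expect_equal(h5$fwd_mismatches, 2L)
})

test_that("binding-site search matches the naive scan oracle", {
  set.seed(9)
  for (rep in 1:6) {
    tmpl <- random_dna(800)
    # plant a mutated copy of an oligo to create near-miss sites
    oligo <- random_dna(20)
    pos <- sample(700, 1)
    mutated <- mutate_sequence(oligo, 0.08)
    substr(tmpl, pos, pos + 19) <- mutated
    got <- .oligo_sites(oligo, tmpl, 2L, 2L)
    want <- oracle_oligo_sites(oligo, tmpl, 2, 2)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})

test_that("strand invariance: reverse-complemented contigs give remapped hits", {
  fx <- tiny_sim()
  g <- fx$manifest$genome_id[1]
  contigs <- fx$gset$genomes[[g]]$contigs
  # use a planted marker's ends as a primer pair
  truth <- fx$sim$truth
  mk <- truth[truth$genome_id == g & truth$type == "marker", ][1, ]
  seqm <- fx$genes$sequence[fx$genes$gene_id == mk$gene_id]
  pair <- list(forward = substr(seqm, 1, 20),
               reverse = revcomp(substr(seqm, nchar(seqm) - 19, nchar(seqm))),
               name = "mk")
  h1 <- in_silico_pcr(pair, list(g = contigs))
  rc <- setNames(revcomp(unname(contigs)), names(contigs))
  h2 <- in_silico_pcr(pair, list(g = rc))
  expect_equal(nrow(h1), nrow(h2))
  expect_gt(nrow(h1), 0)
  L <- nchar(contigs[h1$contig_id])
  expect_setequal(paste(h2$contig_id, h2$start, h2$end),
                  paste(h1$contig_id, L - h1$end, L - h1$start))
  expect_setequal(h1$product_size, h2$product_size)
})

test_that("specificity matrix: planted pair is taxon-exclusive, shared gene is not", {
  fx <- tiny_sim()
  truth <- fx$sim$truth
  g <- fx$manifest$genome_id[1]
  tx <- fx$manifest$taxon[1]
  mk <- truth[truth$genome_id == g & truth$type == "marker", ][1, ]
  seqm <- fx$genes$sequence[fx$genes$gene_id == mk$gene_id]
  pairs <- data.frame(
    name = "planted", taxon = tx,
    forward = substr(seqm, 1, 20),
    reverse = revcomp(substr(seqm, nchar(seqm) - 19, nchar(seqm))),
    stringsAsFactors = FALSE)
  sm <- specificity_matrix(pairs, fx$gset$genomes, fx$manifest)
  target <- fx$manifest$genome_id[fx$manifest$taxon == tx]
  expect_true(all(!sm$amplified["planted", setdiff(colnames(sm$amplified),
                                                   target)]))

  # a deliberately shared gene amplifies across taxa when divergence is 0
  spec0 <- simulation_spec(n_taxa = 2, genomes_per_taxon = 2,
                           n_genus_core = 2, n_taxon_markers = 1,
                           n_accessory = 0, n_decoy = 0,
                           within_taxon_sub_rate = 0,
                           cross_taxon_divergence = 0,
                           plasmid_fraction = 0,
                           gene_length_range = c(200, 300), seed = 17)
  sim0 <- simulate_pangenome(spec0, tempfile())
  g0 <- read_genomes(sim0$genome_paths, sim0$manifest_path, sim0$cds_paths)
  genes0 <- do.call(rbind, lapply(g0$genomes, `[[`, "genes"))
  core_gene <- genes0[match(sim0$truth$gene_id[sim0$truth$type == "core"][1],
                            genes0$gene_id), ]
  s <- core_gene$sequence
  ctl <- data.frame(name = "ctl", taxon = g0$manifest$taxon[1],
                    forward = substr(s, 1, 20),
                    reverse = revcomp(substr(s, nchar(s) - 19, nchar(s))),
                    stringsAsFactors = FALSE)
  sm0 <- specificity_matrix(ctl, g0$genomes, g0$manifest)
  expect_true(all(sm0$amplified["ctl", ])) # amplifies every genome
  expect_equal(sm0$summary$specificity, 0)

  # empty genome list: empty matrix
  sm_empty <- specificity_matrix(ctl, list(), g0$manifest)
  expect_equal(ncol(sm_empty$amplified), 0L)
})
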