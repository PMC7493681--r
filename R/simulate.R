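# Synthetic labeled pan-genomes with planted taxon-specific markers.
#
# The generator emulates the statistical structure the marker screen
# relies on: genes conserved within a taxon (>= 0.90 identity), absent or
# highly diverged across taxa (<= 0.50), plus decoy families at
# intermediate divergence that must be rejected, and plasmid contigs that
# exercise the mobile-element filter. Substitutions only by default; an
# indel channel exists but is off, which keeps the identity bands
# analytically controllable.

# probability that an accessory family is carried by any given genome
ACC_PRESENT_P <- 0.3
# maximum regeneration sweeps before the generator gives up
MAX_REGEN_SWEEPS <- 20L

#' Specification of a synthetic pan-genome
#'
#' Defines the study conditions for a simulated set of labeled genomes:
#' a genus-wide core shared by every genome, `n_taxon_markers` planted
#' taxon-specific genes per taxon (present in every genome of the taxon,
#' absent elsewhere), randomly distributed accessory families, and decoy
#' families present in all genomes whose cross-taxon identity sits inside
#' `decoy_identity_band` - between the 0.50 rejection and 0.90 acceptance
#' thresholds, so a correct screen must reject them.
#'
#' @param n_taxa number of taxa (species/subspecies), >= 1.
#' @param genomes_per_taxon genomes per taxon, >= 1.
#' @param n_genus_core gene families shared by all genomes, >= 1.
#' @param n_taxon_markers planted taxon-specific families per taxon, >= 1.
#' @param n_accessory randomly distributed families, >= 0.
#' @param n_decoy cross-taxon decoy families at intermediate divergence, >= 0.
#' @param within_taxon_sub_rate per-site substitution probability applied
#'   to each genome's copy of a family, in \[0, 0.1\].
#' @param cross_taxon_divergence per-site substitution probability applied
#'   on each taxon's branch from the genus ancestor (0, or in \[0.2, 0.6\]).
#' @param decoy_identity_band target pairwise-identity interval between
#'   taxon variants of a decoy family.
#' @param plasmid_fraction fraction of genomes given a plasmid contig
#'   carrying some of their accessory genes, in \[0, 1\].
#' @param gene_length_range nt length interval for gene ancestors.
#' @param indel_rate per-site indel probability (default 0 and untested
#'   bands are not guaranteed when raised).
#' @param seed RNG seed; identical specs give byte-identical output.
#' @return object of class `sim_spec`.
#' @export
simulation_spec <- function(n_taxa = 3, genomes_per_taxon = 3,
                            n_genus_core = 12, n_taxon_markers = 3,
                            n_accessory = 12, n_decoy = 6,
                            within_taxon_sub_rate = 0.01,
                            cross_taxon_divergence = 0.45,
                            decoy_identity_band = c(0.65, 0.85),
                            plasmid_fraction = 0.25,
                            gene_length_range = c(300, 1500),
                            indel_rate = 0,
                            seed = 1) {
  chk_count <- function(x, nm, min) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
      stop(sprintf("invalid field '%s': must be an integer >= %d", nm, min),
           call. = FALSE)
  }
  chk_count(n_taxa, "n_taxa", 1)
  chk_count(genomes_per_taxon, "genomes_per_taxon", 1)
  chk_count(n_genus_core, "n_genus_core", 1)
  chk_count(n_taxon_markers, "n_taxon_markers", 1)
  chk_count(n_accessory, "n_accessory", 0)
  chk_count(n_decoy, "n_decoy", 0)
  chk_count(seed, "seed", -.Machine$integer.max)
  if (!is.numeric(within_taxon_sub_rate) || within_taxon_sub_rate < 0 ||
      within_taxon_sub_rate > 0.1)
    stop("invalid field 'within_taxon_sub_rate': must be in [0, 0.1]",
         call. = FALSE)
  if (!is.numeric(cross_taxon_divergence) ||
      !(cross_taxon_divergence == 0 ||
        (cross_taxon_divergence >= 0.2 && cross_taxon_divergence <= 0.6)))
    stop("invalid field 'cross_taxon_divergence': must be 0 or in [0.2, 0.6]",
         call. = FALSE)
  if (!is.numeric(decoy_identity_band) || length(decoy_identity_band) != 2 ||
      any(decoy_identity_band <= 0) || any(decoy_identity_band >= 1) ||
      decoy_identity_band[1] >= decoy_identity_band[2])
    stop("invalid field 'decoy_identity_band': must be an increasing interval in (0,1)",
         call. = FALSE)
  if (!is.numeric(plasmid_fraction) || plasmid_fraction < 0 || plasmid_fraction > 1)
    stop("invalid field 'plasmid_fraction': must be in [0, 1]", call. = FALSE)
  if (!is.numeric(gene_length_range) || length(gene_length_range) != 2 ||
      gene_length_range[1] < 50 || gene_length_range[1] > gene_length_range[2])
    stop("invalid field 'gene_length_range': must be an increasing nt interval (>= 50)",
         call. = FALSE)
  if (!is.numeric(indel_rate) || indel_rate < 0 || indel_rate > 0.05)
    stop("invalid field 'indel_rate': must be in [0, 0.05]", call. = FALSE)
  structure(list(
    n_taxa = as.integer(n_taxa), genomes_per_taxon = as.integer(genomes_per_taxon),
    n_genus_core = as.integer(n_genus_core),
    n_taxon_markers = as.integer(n_taxon_markers),
    n_accessory = as.integer(n_accessory), n_decoy = as.integer(n_decoy),
    within_taxon_sub_rate = within_taxon_sub_rate,
    cross_taxon_divergence = cross_taxon_divergence,
    decoy_identity_band = decoy_identity_band,
    plasmid_fraction = plasmid_fraction,
    gene_length_range = as.integer(gene_length_range),
    indel_rate = indel_rate,
    seed = as.integer(seed)), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic pan-genome spec: %d taxa x %d genomes, ",
                     "%d core + %d markers/taxon + %d accessory + %d decoy families, ",
                     "sub rates %.3g within / %.3g cross, seed %d\n"),
              x$n_taxa, x$genomes_per_taxon, x$n_genus_core, x$n_taxon_markers,
              x$n_accessory, x$n_decoy, x$within_taxon_sub_rate,
              x$cross_taxon_divergence, x$seed))
  invisible(x)
}

# per-branch substitution rate that yields a target pairwise identity t
# between two variants mutated independently from one ancestor:
# t = (1-q)^2 + q^2/3  (matching resubstitutions hit the same base w.p. 1/3)
branch_rate_for_identity <- function(t) {
  (2 - sqrt(4 - (16 / 3) * (1 - t))) / (8 / 3)
}

#' Simulate a labeled pan-genome with planted taxon-specific markers
#'
#' Generates one genome FASTA per genome (genes concatenated into 1-3
#' chromosome contigs with random 50-200 nt intergenic spacers, genes on
#' both strands; optionally a plasmid contig whose header carries
#' `replicon=plasmid`), one CDS FASTA and one GFF3 per genome, a
#' tab-separated genome-to-taxon manifest, and a tab-separated truth
#' table recording every gene placement with its family and type.
#'
#' The planted-marker contract (within-taxon identity >= 0.90,
#' cross-taxon identity <= 0.50 under [pairwise_identity()]) and the
#' decoy identity band are checked empirically on the generated
#' sequences; a family violating its contract is redrawn from the same
#' RNG stream and the number of regenerations is reported.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with `manifest` and `truth` data frames,
#'   file paths (`genome_paths`, `cds_paths`, `gff_paths`,
#'   `manifest_path`, `truth_path`), and `regenerations`.
#' @export
simulate_pangenome <- function(spec, out_dir) {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(file.path(out_dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "cds"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "gff"), showWarnings = FALSE)

  set.seed(spec$seed)
  taxa <- sprintf("taxon%02d", seq_len(spec$n_taxa))
  genomes <- as.vector(t(outer(taxa, seq_len(spec$genomes_per_taxon),
                               function(t, j) sprintf("%s_g%02d", t, j))))
  genome_taxon <- rep(taxa, each = spec$genomes_per_taxon)
  names(genome_taxon) <- genomes

  rlen <- function(n) {
    if (n == 0) return(integer(0))
    spec$gene_length_range[1] +
      sample.int(spec$gene_length_range[2] - spec$gene_length_range[1] + 1L,
                 n, replace = TRUE) - 1L
  }

  # --- draw order: lengths, core, markers, accessory, decoys, copies ---
  core_len <- rlen(spec$n_genus_core)
  mark_len <- matrix(rlen(spec$n_taxa * spec$n_taxon_markers),
                     nrow = spec$n_taxa)
  acc_len <- rlen(spec$n_accessory)
  decoy_len <- rlen(spec$n_decoy)

  core_anc <- vapply(core_len, random_dna, character(1))
  # per-taxon variants of the genus core
  core_var <- lapply(seq_len(spec$n_genus_core), function(i)
    setNames(vapply(taxa, function(t)
      mutate_sequence(core_anc[i], spec$cross_taxon_divergence), character(1)), taxa))

  marker_anc <- lapply(seq_len(spec$n_taxa), function(t)
    vapply(seq_len(spec$n_taxon_markers), function(j)
      random_dna(mark_len[t, j]), character(1)))

  acc_anc <- vapply(acc_len, random_dna, character(1))
  acc_present <- lapply(seq_len(spec$n_accessory), function(i) {
    repeat {
      p <- runif(length(genomes)) < ACC_PRESENT_P
      if (any(p)) return(setNames(p, genomes))
    }
  })

  decoy_q <- branch_rate_for_identity(mean(spec$decoy_identity_band))
  decoy_anc <- vapply(decoy_len, random_dna, character(1))
  decoy_var <- vector("list", spec$n_decoy)
  regenerations <- 0L
  for (i in seq_len(spec$n_decoy)) {
    tries <- 0L
    repeat {
      v <- setNames(vapply(taxa, function(t)
        mutate_sequence(decoy_anc[i], decoy_q), character(1)), taxa)
      ok <- TRUE
      if (spec$n_taxa > 1) {
        for (a in seq_len(spec$n_taxa - 1)) for (b in (a + 1):spec$n_taxa) {
          id <- pairwise_identity(v[a], v[b])$identity
          if (id < spec$decoy_identity_band[1] || id > spec$decoy_identity_band[2]) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) break
      tries <- tries + 1L
      regenerations <- regenerations + 1L
      if (tries >= MAX_REGEN_SWEEPS)
        stop("decoy family ", i, " could not be placed in the identity band")
    }
    decoy_var[[i]] <- v
  }

  # per-genome copies, genome-major then family-major order
  copy_of <- function(seq) mutate_sequence(seq, spec$within_taxon_sub_rate)
  gene_copies <- list() # [[genome]] -> data.frame(family, type, sequence)
  draw_genome_copies <- function(g) {
    t <- genome_taxon[g]
    ti <- match(t, taxa)
    fam <- character(0); typ <- character(0); sq <- character(0)
    for (i in seq_len(spec$n_genus_core)) {
      fam <- c(fam, sprintf("core%03d", i)); typ <- c(typ, "core")
      sq <- c(sq, copy_of(core_var[[i]][t]))
    }
    for (j in seq_len(spec$n_taxon_markers)) {
      fam <- c(fam, sprintf("%s_marker%02d", t, j)); typ <- c(typ, "marker")
      sq <- c(sq, copy_of(marker_anc[[ti]][j]))
    }
    for (i in seq_len(spec$n_decoy)) {
      fam <- c(fam, sprintf("decoy%03d", i)); typ <- c(typ, "decoy")
      sq <- c(sq, copy_of(decoy_var[[i]][t]))
    }
    for (i in seq_len(spec$n_accessory)) {
      if (acc_present[[i]][g]) {
        fam <- c(fam, sprintf("acc%03d", i)); typ <- c(typ, "accessory")
        sq <- c(sq, copy_of(acc_anc[i]))
      }
    }
    data.frame(family = fam, type = typ, sequence = sq,
               stringsAsFactors = FALSE)
  }
  for (g in genomes) gene_copies[[g]] <- draw_genome_copies(g)

  # --- planted-marker contract sweep -------------------------------------
  # cross pool for taxon t: every sequence carried by a non-t genome,
  # approximated at the variant/ancestor level (copies differ by <= the
  # within rate). Length-ratio pruning is exact: identity <= Lmin/Lmax.
  marker_cross_ok <- function(mseq, ti) {
    lm <- nchar(mseq)
    pool <- character(0)
    for (u in seq_len(spec$n_taxa)) {
      if (u == ti) next
      pool <- c(pool,
                vapply(core_var, function(v) v[[u]], character(1)),
                marker_anc[[u]],
                vapply(decoy_var, function(v) v[[u]], character(1)))
    }
    if (spec$n_accessory > 0) {
      nontarget <- genomes[genome_taxon != taxa[ti]]
      keep <- vapply(acc_present, function(p) any(p[nontarget]), logical(1))
      pool <- c(pool, acc_anc[keep])
    }
    # the pipeline's identity is seed-gated: a pair sharing no k-mer is
    # no hit, so the contract is checked under the same definition
    prof <- kmer_profile(mseq, 12L)
    for (s in pool) {
      if (identity_upper_bound(lm, nchar(s)) <= 0.5) next
      if (!shares_kmers(prof, kmer_profile(s, 12L))) next
      if (pairwise_identity(mseq, s)$identity > 0.5) return(FALSE)
    }
    TRUE
  }
  marker_within_ok <- function(ti, j) {
    gs <- genomes[genome_taxon == taxa[ti]]
    if (length(gs) < 2) return(TRUE)
    fam <- sprintf("%s_marker%02d", taxa[ti], j)
    seqs <- vapply(gs, function(g) {
      df <- gene_copies[[g]]
      df$sequence[df$family == fam]
    }, character(1))
    for (a in seq_len(length(seqs) - 1)) for (b in (a + 1):length(seqs)) {
      if (pairwise_identity(seqs[a], seqs[b])$identity < 0.9) return(FALSE)
    }
    TRUE
  }

  for (sweep in seq_len(MAX_REGEN_SWEEPS)) {
    clean <- TRUE
    for (ti in seq_len(spec$n_taxa)) {
      for (j in seq_len(spec$n_taxon_markers)) {
        if (marker_cross_ok(marker_anc[[ti]][j], ti) && marker_within_ok(ti, j))
          next
        clean <- FALSE
        regenerations <- regenerations + 1L
        marker_anc[[ti]][j] <- random_dna(mark_len[ti, j])
        fam <- sprintf("%s_marker%02d", taxa[ti], j)
        for (g in genomes[genome_taxon == taxa[ti]]) {
          df <- gene_copies[[g]]
          df$sequence[df$family == fam] <- copy_of(marker_anc[[ti]][j])
          gene_copies[[g]] <- df
        }
      }
    }
    if (clean) break
    if (sweep == MAX_REGEN_SWEEPS)
      stop("planted-marker contract could not be satisfied after ",
           MAX_REGEN_SWEEPS, " sweeps")
  }

  # --- assemble genomes ---------------------------------------------------
  truth <- list()
  genome_paths <- cds_paths <- gff_paths <- character(0)
  for (g in genomes) {
    df <- gene_copies[[g]]
    n <- nrow(df)
    ord <- sample.int(n)
    df <- df[ord, , drop = FALSE]
    df$strand <- sample(c("+", "-"), n, replace = TRUE)
    df$gene_id <- sprintf("%s_g%03d", g, seq_len(n))

    is_plasmid_genome <- runif(1) < spec$plasmid_fraction
    acc_rows <- which(df$type == "accessory")
    plasmid_rows <- integer(0)
    if (is_plasmid_genome && length(acc_rows) > 0) {
      n_pl <- min(3L, length(acc_rows))
      plasmid_rows <- sort(sample(acc_rows, n_pl))
    }
    chrom_rows <- setdiff(seq_len(n), plasmid_rows)
    n_chr <- min(sample.int(3L, 1L), length(chrom_rows))
    contig_assign <- integer(n)
    if (length(chrom_rows)) {
      cuts <- sort(rep(seq_len(n_chr), length.out = length(chrom_rows)))
      contig_assign[chrom_rows] <- cuts
    }
    contig_assign[plasmid_rows] <- 0L # plasmid

    contig_seqs <- character(0)
    contig_ids <- character(0)
    contig_repl <- character(0)
    rows <- list()
    build_contig <- function(ridx, cid, repl) {
      pos <- 0L
      parts <- character(0)
      for (r in ridx) {
        sp <- random_dna(sample(50:200, 1))
        parts <- c(parts, sp)
        pos <- pos + nchar(sp)
        placed <- if (df$strand[r] == "+") df$sequence[r] else revcomp(df$sequence[r])
        parts <- c(parts, placed)
        start <- pos
        pos <- pos + nchar(placed)
        rows[[length(rows) + 1L]] <<- data.frame(
          gene_id = df$gene_id[r], genome_id = g, contig_id = cid,
          replicon = repl, start = start, end = pos, strand = df$strand[r],
          family = df$family[r], type = df$type[r],
          taxon = genome_taxon[[g]], stringsAsFactors = FALSE)
      }
      parts <- c(parts, random_dna(sample(50:200, 1)))
      paste(parts, collapse = "")
    }
    for (ci in seq_len(n_chr)) {
      ridx <- which(contig_assign == ci)
      if (!length(ridx)) next
      cid <- sprintf("%s_chr%d", g, ci)
      contig_seqs <- c(contig_seqs, build_contig(ridx, cid, "chromosome"))
      contig_ids <- c(contig_ids, cid)
      contig_repl <- c(contig_repl, "chromosome")
    }
    if (length(plasmid_rows)) {
      cid <- sprintf("%s_plasmid1", g)
      contig_seqs <- c(contig_seqs, build_contig(plasmid_rows, cid, "plasmid"))
      contig_ids <- c(contig_ids, cid)
      contig_repl <- c(contig_repl, "plasmid")
    }

    gdf <- do.call(rbind, rows)
    gdf <- gdf[order(match(gdf$gene_id, df$gene_id)), , drop = FALSE]
    truth[[g]] <- gdf

    gp <- file.path(out_dir, "genomes", paste0(g, ".fasta"))
    write_fasta(contig_seqs, gp,
                headers = sprintf("%s replicon=%s", contig_ids, contig_repl))
    genome_paths <- c(genome_paths, gp)

    cheads <- sprintf("%s genome=%s contig=%s start=%d end=%d strand=%s replicon=%s family=%s type=%s",
                      gdf$gene_id, gdf$genome_id, gdf$contig_id, gdf$start,
                      gdf$end, gdf$strand, gdf$replicon, gdf$family, gdf$type)
    cp <- file.path(out_dir, "cds", paste0(g, "_cds.fasta"))
    write_fasta(df$sequence[match(gdf$gene_id, df$gene_id)], cp, headers = cheads)
    cds_paths <- c(cds_paths, cp)

    fp <- file.path(out_dir, "gff", paste0(g, ".gff3"))
    con <- file(fp, open = "wb")
    writeLines("##gff-version 3", con)
    writeLines(sprintf("%s\tpanmarker_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       gdf$contig_id, gdf$start + 1L, gdf$end, gdf$strand,
                       gdf$gene_id), con)
    close(con)
    gff_paths <- c(gff_paths, fp)
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  manifest <- data.frame(genome_id = genomes, taxon = unname(genome_taxon),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(manifest = manifest, truth = truth,
                 genome_paths = genome_paths, cds_paths = cds_paths,
                 gff_paths = gff_paths, manifest_path = manifest_path,
                 truth_path = truth_path, regenerations = regenerations,
                 spec = spec))
}

#' Read a truth table written by [simulate_pangenome()]
#'
#' @param path path to `truth.tsv`.
#' @return data frame of gene placements.
#' @export
read_truth_table <- function(path) {
  if (!file.exists(path)) stop("truth table not found: ", path, call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Planted marker families of a truth table
#'
#' @param truth data frame from [read_truth_table()].
#' @return data frame with one row per (taxon, family) planted marker.
#' @export
planted_markers <- function(truth) {
  m <- truth[truth$type == "marker", c("taxon", "family")]
  unique(m)
}
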