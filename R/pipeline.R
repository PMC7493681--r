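# End-to-end orchestration: simulate/ingest -> cluster -> trees ->
# markers -> primers -> in-silico PCR -> specificity report, and the
# qPCR monitoring workflow.

#' Default discovery-run configuration
#'
#' A flat list of every threshold the discovery pipeline uses, plus
#' input/output paths. The config is serialized verbatim into the run
#' directory so a completed run is reproducible from its config copy.
#'
#' @param genomes_dir directory of genome FASTA files.
#' @param cds_dir directory of `<genome>_cds.fasta` files.
#' @param manifest path to the genome-to-taxon manifest.
#' @param out_dir run output directory.
#' @param cluster_id pan-genome clustering identity threshold.
#' @param id_within,id_cross,presence_fraction marker-selection
#'   thresholds (see [select_candidates()]).
#' @param prefilter_k k-mer size of the alignment seed screen.
#' @param tree_metric `"jaccard"` or `"euclidean"` for the pan tree.
#' @param markers_per_taxon top-ranked accepted markers to design
#'   primers on (one primer pair is emitted per marker, mirroring
#'   one-assay-per-target panel design).
#' @param max_amplicon,min_amplicon primer product-size bounds (bp).
#' @param ispcr_max_mismatch,ispcr_three_prime_exact,ispcr_max_product
#'   in-silico PCR binding model.
#' @param exclusion_fasta optional mobile-element FASTA.
#' @param seed RNG seed recorded in the config.
#' @return named list of class `run_config`.
#' @export
run_config <- function(genomes_dir, cds_dir, manifest, out_dir,
                       cluster_id = 0.5, id_within = 0.90, id_cross = 0.50,
                       presence_fraction = 1.0, prefilter_k = 12L,
                       tree_metric = "jaccard", markers_per_taxon = 1L,
                       max_amplicon = 200L, min_amplicon = 80L,
                       ispcr_max_mismatch = 2L, ispcr_three_prime_exact = 2L,
                       ispcr_max_product = 1500L, exclusion_fasta = NA,
                       seed = 1L) {
  cfg <- list(genomes_dir = genomes_dir, cds_dir = cds_dir,
              manifest = manifest, out_dir = out_dir,
              cluster_id = cluster_id, id_within = id_within,
              id_cross = id_cross, presence_fraction = presence_fraction,
              prefilter_k = prefilter_k, tree_metric = tree_metric,
              markers_per_taxon = markers_per_taxon,
              max_amplicon = max_amplicon, min_amplicon = min_amplicon,
              ispcr_max_mismatch = ispcr_max_mismatch,
              ispcr_three_prime_exact = ispcr_three_prime_exact,
              ispcr_max_product = ispcr_max_product,
              exclusion_fasta = exclusion_fasta, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run config as a flat key=value file
#' @param config a `run_config` (write) or path (read).
#' @param path destination file.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, "=", as.character(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  names(cfg) <- vapply(kv, `[[`, character(1), 1)
  num <- c("cluster_id", "id_within", "id_cross", "presence_fraction",
           "prefilter_k", "markers_per_taxon", "max_amplicon", "min_amplicon",
           "ispcr_max_mismatch", "ispcr_three_prime_exact",
           "ispcr_max_product", "seed")
  for (k in intersect(num, names(cfg))) cfg[[k]] <- as.numeric(cfg[[k]])
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the marker-discovery pipeline
#'
#' Orchestrates ingest, clustering, matrix and partition, pan and core
#' trees, monophyly audit, marker selection with mobile-element
#' filtering, primer design on the top-ranked accepted markers (on
#' windows conserved across all target-taxon copies), in-silico PCR, and
#' the specificity summary. Emits `matrix.tsv`, `pan_tree.nwk`,
#' `core_tree.nwk` (when shared single-copy core clusters exist),
#' `monophyly.tsv`, `markers.tsv`, `markers.fasta`, `primers.tsv`,
#' `ispcr_hits.tsv`, `specificity.tsv`, `run.log` and a config copy into
#' the run directory.
#'
#' @param config a `run_config`.
#' @return (invisibly) a list with the principal in-memory results.
#' @export
run_discover <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wb")
  on.exit(close(logf))
  write_run_config(config, file.path(config$out_dir, "config.txt"))
  set.seed(as.integer(config$seed))
  params <- align_params()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  }

  gset <- stage("ingest", {
    gp <- sort(list.files(config$genomes_dir, pattern = "\\.(fasta|fa|fna)$",
                          full.names = TRUE))
    cp <- sort(list.files(config$cds_dir, pattern = "_cds\\.(fasta|fa|fna)$",
                          full.names = TRUE))
    read_genomes(gp, config$manifest, cds_paths = cp)
  })
  genes <- genes_table(gset)
  manifest <- gset$manifest
  log_line(logf, "ingest: %d genomes, %d genes, %d taxa",
           length(gset$genomes), nrow(genes), length(unique(manifest$taxon)))

  clusters <- stage("cluster",
    cluster_genes(genes, threshold = config$cluster_id,
                  prefilter_k = config$prefilter_k, params = params))
  log_line(logf, "cluster: %d clusters at identity >= %.2f",
           nrow(clusters$representatives), config$cluster_id)

  mat <- stage("matrix", build_matrix(clusters, manifest))
  write_matrix(mat, file.path(config$out_dir, "matrix.tsv"))
  part <- stage("partition", partition_pangenome(mat))
  log_line(logf, "partition: %d core / %d accessory / %d unique clusters",
           length(part$core), length(part$accessory), length(part$unique))

  pan_tree <- stage("pan_tree",
    neighbor_joining(frequency_distance(mat, config$tree_metric)))
  write_newick(pan_tree, file.path(config$out_dir, "pan_tree.nwk"))

  core_tree <- NULL
  if (length(part$core)) {
    core_tree <- tryCatch(
      neighbor_joining(core_identity_distance(genes, clusters, part$core,
                                              params)),
      error = function(e) {
        log_line(logf, "core_tree: skipped (%s)", conditionMessage(e))
        NULL
      })
    if (!is.null(core_tree))
      write_newick(core_tree, file.path(config$out_dir, "core_tree.nwk"))
  } else {
    log_line(logf, "core_tree: skipped (no genus-wide core clusters)")
  }

  mono <- stage("monophyly", monophyly_report(pan_tree, manifest))
  write.table(mono, file.path(config$out_dir, "monophyly.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_line(logf, "monophyly: %d/%d taxa monophyletic in the pan tree",
           sum(mono$monophyletic), nrow(mono))

  taxa <- unique(manifest$taxon)
  excl <- if (is.na(config$exclusion_fasta) ||
              config$exclusion_fasta %in% c("", "NA")) NULL else
    config$exclusion_fasta
  cands <- stage("markers", {
    do.call(rbind, lapply(taxa, function(tx) {
      cc <- select_candidates(clusters, mat, manifest, genes, tx,
                              id_within = config$id_within,
                              id_cross = config$id_cross,
                              presence_fraction = config$presence_fraction,
                              prefilter_k = config$prefilter_k,
                              params = params)
      mobile_element_filter(cc, genes, clusters, manifest,
                            exclusion_fasta = excl, params = params)
    }))
  })
  write.table(cands[, setdiff(names(cands), "sequence")],
              file.path(config$out_dir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  acc <- accepted_markers(cands)
  log_line(logf, "markers: %d candidates, %d accepted across %d taxa",
           nrow(cands), nrow(acc), length(taxa))

  pairs_list <- list()
  if (nrow(acc)) {
    write_fasta(acc$sequence,
                file.path(config$out_dir, "markers.fasta"),
                headers = sprintf("%s taxon=%s cluster=%s", acc$gene_id,
                                  acc$taxon, acc$cluster_id))
    pairs_list <- stage("primers", {
      out <- list()
      for (tx in taxa) {
        top <- acc[acc$taxon == tx, , drop = FALSE]
        if (!nrow(top)) next
        top <- utils::head(top, config$markers_per_taxon)
        for (i in seq_len(nrow(top))) {
          mask <- marker_conservation_mask(top[i, ], clusters, genes, manifest)
          pp <- design_primers(
            top$sequence[i],
            constraints = primer_constraints(
              min_amplicon = config$min_amplicon,
              max_amplicon = config$max_amplicon),
            top_n = 1L, conservation = mask,
            name_prefix = paste0(tx, "_", top$cluster_id[i], "_p"),
            taxon = tx)
          if (nrow(pp)) out[[length(out) + 1L]] <- pp
        }
      }
      out
    })
  }
  pairs <- if (length(pairs_list)) do.call(rbind, pairs_list) else
    design_primers_empty()
  write.table(pairs, file.path(config$out_dir, "primers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_line(logf, "primers: %d pair(s) designed", nrow(pairs))

  hits <- data.frame()
  specs <- NULL
  if (nrow(pairs)) {
    hits <- stage("ispcr", do.call(rbind, lapply(seq_len(nrow(pairs)),
      function(i) {
        h <- in_silico_pcr(pairs[i, ], gset$genomes,
                           max_mismatch = config$ispcr_max_mismatch,
                           three_prime_exact = config$ispcr_three_prime_exact,
                           max_product = config$ispcr_max_product)
        h$pair <- rep(pairs$name[i], nrow(h))
        h
      })))
    specs <- stage("ispcr",
      specificity_matrix(pairs, gset$genomes, manifest,
                         max_mismatch = config$ispcr_max_mismatch,
                         three_prime_exact = config$ispcr_three_prime_exact,
                         max_product = config$ispcr_max_product))
    write.table(specs$summary, file.path(config$out_dir, "specificity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_line(logf, "ispcr: %d amplicon hit(s); min sensitivity %.3f, min specificity %.3f",
             nrow(hits), min(specs$summary$sensitivity),
             min(specs$summary$specificity))
  } else {
    write.table(data.frame(name = character(0), taxon = character(0),
                           n_target = integer(0), n_nontarget = integer(0),
                           sensitivity = numeric(0), specificity = numeric(0)),
                file.path(config$out_dir, "specificity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_line(logf, "ispcr: skipped (no primer pairs)")
  }
  write.table(hits, file.path(config$out_dir, "ispcr_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(manifest = manifest, genes = genes, clusters = clusters,
                 matrix = mat, partition = part, pan_tree = pan_tree,
                 core_tree = core_tree, monophyly = mono,
                 candidates = cands, accepted = acc, pairs = pairs,
                 hits = hits, specificity = specs))
}

design_primers_empty <- function() {
  data.frame(name = character(0), taxon = character(0),
             forward = character(0), reverse = character(0),
             fwd_start = integer(0), fwd_end = integer(0),
             rev_start = integer(0), rev_end = integer(0),
             product_size = integer(0), tm_forward = numeric(0),
             tm_reverse = numeric(0), gc_forward = numeric(0),
             gc_reverse = numeric(0), dimer_score = integer(0),
             hairpin_score = integer(0), stringsAsFactors = FALSE)
}

#' Conservation mask of a marker across its target-taxon copies
#'
#' TRUE at positions where every target-genome copy of the marker's
#' cluster agrees with the representative. Copies whose length differs
#' from the representative contribute no constraint beyond disabling the
#' positions they cannot confirm (the default substitution-only
#' simulations keep copies equal length).
#'
#' @param candidate one row of a `marker_candidates` data frame.
#' @param clusters the source `gene_clusters`.
#' @param genes gene table.
#' @param manifest manifest data frame.
#' @return logical vector along the representative sequence.
#' @export
marker_conservation_mask <- function(candidate, clusters, genes, manifest) {
  rep_seq <- candidate$sequence
  L <- nchar(rep_seq)
  mask <- rep(TRUE, L)
  target <- manifest$genome_id[manifest$taxon == candidate$taxon]
  memb <- clusters$members[clusters$members$cluster_id == candidate$cluster_id &
                             clusters$members$genome_id %in% target, ]
  rv <- strsplit(rep_seq, NULL, fixed = TRUE)[[1]]
  for (gid in memb$gene_id) {
    s <- genes$sequence[genes$gene_id == gid]
    if (nchar(s) != L) {
      mask[] <- FALSE
      next
    }
    mask <- mask & (strsplit(s, NULL, fixed = TRUE)[[1]] == rv)
  }
  mask
}

#' Run the qPCR monitoring workflow
#'
#' Fits one standard curve per taxon from the dilution-series points,
#' calls detections from per-product Ct values (positive iff Ct present
#' and at most `ct_cutoff`), quantifies positives against their taxon's
#' curve, and compares detections to the label claims. A positive call
#' for a taxon without a curve is an error naming the taxon.
#'
#' @param curves_path TSV with columns taxon, log10_conc, ct.
#' @param calls_path TSV with columns product_id, taxon, ct (empty/NA ct
#'   means no amplification).
#' @param labels_path TSV with columns product_id, label (one row per
#'   labeled taxon).
#' @param out_dir report directory.
#' @param taxonomy taxonomy data frame (see [bifidobacterium_taxonomy()]).
#' @param nonspecific_tokens see [compare_to_label()].
#' @param ct_cutoff detection cutoff (the assay runs 35 cycles).
#' @return (invisibly) list with `report` and `quantification` data
#'   frames.
#' @export
run_monitor <- function(curves_path, calls_path, labels_path, out_dir,
                        taxonomy = bifidobacterium_taxonomy(),
                        nonspecific_tokens = c("Lactic acid bacteria",
                                               "Bifidus"),
                        ct_cutoff = 35) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pts <- read.delim(curves_path, stringsAsFactors = FALSE)
  calls <- read.delim(calls_path, stringsAsFactors = FALSE)
  labels <- read.delim(labels_path, stringsAsFactors = FALSE)
  calls$ct <- suppressWarnings(as.numeric(calls$ct))

  curves <- lapply(split(pts, pts$taxon), function(d)
    fit_standard_curve(d, taxon = d$taxon[1]))

  calls$positive <- !is.na(calls$ct) & calls$ct <= ct_cutoff
  pos <- calls[calls$positive, , drop = FALSE]
  no_curve <- setdiff(unique(pos$taxon), names(curves))
  if (length(no_curve))
    stop("no standard curve for detected taxon/taxa: ",
         paste(no_curve, collapse = ", "), call. = FALSE)

  quant <- if (nrow(pos)) do.call(rbind, lapply(seq_len(nrow(pos)), function(i) {
    q <- quantify_ct(pos$ct[i], curves[[pos$taxon[i]]])
    data.frame(product_id = pos$product_id[i], taxon = pos$taxon[i],
               ct = pos$ct[i], log10_cfu = q$log10_conc,
               extrapolated = q$extrapolated, stringsAsFactors = FALSE)
  })) else data.frame(product_id = character(0), taxon = character(0),
                      ct = numeric(0), log10_cfu = numeric(0),
                      extrapolated = logical(0))

  products <- unique(labels$product_id)
  report <- do.call(rbind, lapply(products, function(p) {
    lb <- labels$label[labels$product_id == p]
    dt <- pos$taxon[pos$product_id == p]
    cmp <- compare_to_label(lb, dt, taxonomy, nonspecific_tokens)
    data.frame(product_id = p, verdict = cmp$verdict,
               labeled = paste(sort(unique(lb)), collapse = "; "),
               detected = paste(sort(unique(dt)), collapse = "; "),
               notes = paste(cmp$notes, collapse = " | "),
               stringsAsFactors = FALSE)
  }))
  if (is.null(report))
    report <- data.frame(product_id = character(0), verdict = character(0),
                         labeled = character(0), detected = character(0),
                         notes = character(0), stringsAsFactors = FALSE)

  write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(quant, file.path(out_dir, "quantification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  curve_df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(taxon = cv$taxon, slope = cv$slope, intercept = cv$intercept,
               r_squared = cv$r_squared,
               efficiency_percent = cv$efficiency_percent,
               stringsAsFactors = FALSE)))
  write.table(curve_df, file.path(out_dir, "curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(report = report, quantification = quant, curves = curves))
}
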