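# Taxon-specific marker selection: taxon cores screened against all
# non-target genes, mobile-element exclusion, and the marker-by-genome
# verification matrix.

# below this cross threshold the k-mer seed gate is bypassed (an
# unseeded pair certifies identity << 0.5, not identity ~0)
SEED_GATE_MIN_ID <- 0.3

# best identity of `seq` against a set of genes, using the exact length
# bound and (optionally) the shared-k-mer hit definition; genes without a
# k-mer seed contribute nothing (identity 0 when nothing hits).
# Candidates are visited in decreasing shared-seed order, which does not
# change the maximum but makes the length-bound prune effective; when
# `stop_above` is set the scan stops early once the decision threshold
# is exceeded (the reported value is then a witness, not the maximum).
best_hit_identity <- function(seq, gene_seqs, params, prefilter_k = 12L,
                              use_prefilter = TRUE, stop_above = NULL,
                              gene_profs = NULL) {
  if (!length(gene_seqs)) return(0)
  ls <- nchar(seq)
  best <- 0
  idx <- seq_along(gene_seqs)
  if (use_prefilter) {
    prof <- kmer_profile(seq, prefilter_k)
    if (is.null(gene_profs))
      gene_profs <- lapply(gene_seqs, kmer_profile, k = prefilter_k)
    shared <- .shared_kmer_counts(prof, gene_profs)
    idx <- idx[shared > 0]
    idx <- idx[order(-shared[idx])]
  }
  for (i in idx) {
    gseq <- gene_seqs[[i]]
    if (identity_upper_bound(ls, nchar(gseq)) <= best) next
    id <- pairwise_identity(seq, gseq, params)$identity
    if (id > best) best <- id
    if (!is.null(stop_above) && best > stop_above) break
  }
  best
}

#' Select taxon-specific marker candidates
#'
#' Starting from the taxon core clusters, each candidate's representative
#' is aligned against the best-matching gene of every target genome
#' (`within_min_identity` = the minimum over target genomes) and against
#' every gene of every non-target genome (`cross_max_identity` = the
#' maximum; a gene without a shared k-mer seed is no hit, and with no hit
#' at all the cross identity is recorded as 0; for a rejected candidate
#' the scan stops at the first hit exceeding `id_cross`, so its recorded
#' cross identity is a witness of rejection rather than the exhaustive
#' maximum). A candidate is accepted
#' when `within_min_identity >= id_within`, `cross_max_identity <=
#' id_cross`, and no target-genome copy lies on a plasmid replicon.
#' Candidates are sorted by cross identity ascending, then within
#' identity descending, then cluster id.
#'
#' @param clusters a `gene_clusters` object.
#' @param matrix the `pa_matrix` built from `clusters`.
#' @param manifest manifest data frame.
#' @param genes gene table (must carry a `replicon` column; `unknown` is
#'   assumed when absent).
#' @param taxon target taxon.
#' @param id_within minimum within-taxon identity (default 0.90).
#' @param id_cross maximum cross-taxon identity (default 0.50).
#' @param presence_fraction passed to [taxon_core()].
#' @param prefilter_k,use_prefilter k-mer hit screen controls.
#' @param params alignment scoring.
#' @return data frame of class `marker_candidates`: cluster_id, taxon,
#'   representative gene_id and sequence, within_min_identity,
#'   cross_max_identity, replicon, status.
#' @export
select_candidates <- function(clusters, matrix, manifest, genes, taxon,
                              id_within = 0.90, id_cross = 0.50,
                              presence_fraction = 1.0, prefilter_k = 12L,
                              use_prefilter = TRUE, params = align_params()) {
  target <- manifest$genome_id[manifest$taxon == taxon]
  if (!length(target)) stop("taxon has no genomes: ", taxon, call. = FALSE)
  nontarget <- manifest$genome_id[manifest$taxon != taxon]
  core_ids <- taxon_core(matrix, manifest, taxon, presence_fraction)
  if (!"replicon" %in% names(genes)) genes$replicon <- "unknown"

  mem <- clusters$members
  reps <- clusters$representatives
  nt_seqs <- genes$sequence[genes$genome_id %in% nontarget]
  target_seqs <- lapply(setNames(target, target), function(g)
    genes$sequence[genes$genome_id == g])
  nt_profs <- if (use_prefilter) lapply(nt_seqs, kmer_profile, k = prefilter_k)
    else NULL
  target_profs <- if (use_prefilter) lapply(target_seqs, function(ss)
    lapply(ss, kmer_profile, k = prefilter_k)) else NULL

  rows <- lapply(core_ids, function(cl) {
    rep_gene <- reps$gene_id[reps$cluster_id == cl]
    rep_seq <- reps$sequence[reps$cluster_id == cl]
    within <- min(vapply(target, function(g)
      best_hit_identity(rep_seq, target_seqs[[g]], params, prefilter_k,
                        use_prefilter, gene_profs = target_profs[[g]]),
      numeric(1)))
    # the seed gate certifies only that unseeded pairs sit far below
    # conventional thresholds; for very low id_cross fall back to the
    # exhaustive scan so that "no seed" cannot masquerade as identity 0
    gate_cross <- use_prefilter && id_cross >= SEED_GATE_MIN_ID
    cross <- best_hit_identity(rep_seq, nt_seqs, params, prefilter_k,
                               gate_cross, stop_above = id_cross,
                               gene_profs = if (gate_cross) nt_profs)
    memb <- mem[mem$cluster_id == cl & mem$genome_id %in% target, ]
    repl_set <- unique(genes$replicon[match(memb$gene_id, genes$gene_id)])
    replicon <- if ("plasmid" %in% repl_set) "plasmid"
      else if (identical(repl_set, "chromosome")) "chromosome" else
        if (all(repl_set %in% c("chromosome", "unknown"))) repl_set[1] else "unknown"
    status <- if (replicon == "plasmid") "rejected_mobile"
      else if (cross > id_cross) "rejected_cross"
      else if (within < id_within) "rejected_within"
      else "accepted"
    data.frame(cluster_id = cl, taxon = taxon, gene_id = rep_gene,
               sequence = rep_seq, within_min_identity = within,
               cross_max_identity = cross, replicon = replicon,
               status = status, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), taxon = character(0),
               gene_id = character(0), sequence = character(0),
               within_min_identity = numeric(0),
               cross_max_identity = numeric(0), replicon = character(0),
               status = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$cross_max_identity, -out$within_min_identity,
                   out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "id_within") <- id_within
  attr(out, "id_cross") <- id_cross
  class(out) <- c("marker_candidates", class(out))
  out
}

#' Mobile-element exclusion filter
#'
#' A candidate whose source gene lies on a plasmid-flagged contig in any
#' target genome, or whose representative aligns to any sequence of the
#' exclusion set at identity >= `hit_identity`, becomes
#' `rejected_mobile`. Intended for plasmid/prophage sequence sets
#' maintained by the operator; exclusion entries should be gene-sized
#' (identity is global).
#'
#' @param candidates a `marker_candidates` data frame.
#' @param genes gene table with `replicon` column.
#' @param clusters the `gene_clusters` the candidates came from.
#' @param manifest manifest data frame (defines each candidate's target
#'   genomes).
#' @param exclusion_fasta optional FASTA of mobile-element sequences.
#' @param hit_identity exclusion alignment threshold (default 0.80).
#' @param params alignment scoring.
#' @return the candidates with updated `status`.
#' @export
mobile_element_filter <- function(candidates, genes, clusters, manifest,
                                  exclusion_fasta = NULL, hit_identity = 0.80,
                                  params = align_params()) {
  excl <- NULL
  if (!is.null(exclusion_fasta)) {
    excl <- tryCatch(read_fasta(exclusion_fasta), error = function(e)
      stop("unreadable exclusion FASTA: ", conditionMessage(e), call. = FALSE))
  }
  if (!nrow(candidates)) return(candidates)
  mem <- clusters$members
  if (!"replicon" %in% names(genes)) genes$replicon <- "unknown"
  for (i in seq_len(nrow(candidates))) {
    cl <- candidates$cluster_id[i]
    target <- manifest$genome_id[manifest$taxon == candidates$taxon[i]]
    memb <- mem[mem$cluster_id == cl & mem$genome_id %in% target, ]
    repl <- genes$replicon[match(memb$gene_id, genes$gene_id)]
    on_plasmid <- any(repl == "plasmid")
    hit <- FALSE
    if (!is.null(excl)) {
      hit <- best_hit_identity(candidates$sequence[i], excl, params,
                               use_prefilter = FALSE,
                               stop_above = hit_identity) >= hit_identity
    }
    if (on_plasmid || hit) candidates$status[i] <- "rejected_mobile"
  }
  candidates
}

#' Accepted markers of a candidate table
#'
#' @param candidates a `marker_candidates` data frame.
#' @return the accepted subset.
#' @export
accepted_markers <- function(candidates) {
  candidates[candidates$status == "accepted", , drop = FALSE]
}

#' Marker-by-genome verification matrix
#'
#' Best-hit identity of each marker representative against every genome's
#' gene set (0 when no gene seeds a hit) - the tabular analog of a
#' marker-to-genome alignment heatmap. Target-taxon cells are expected
#' high (>= id_within), non-target cells low (<= id_cross).
#'
#' @param markers a `marker_candidates` data frame (typically the
#'   accepted subset).
#' @param genes gene table.
#' @param manifest manifest data frame (defines genome column order).
#' @param prefilter_k,use_prefilter,params as in [select_candidates()].
#' @return numeric matrix markers x genomes with entries in \[0, 1\],
#'   rownames `taxon:cluster_id`.
#' @export
verify_markers <- function(markers, genes, manifest, prefilter_k = 12L,
                           use_prefilter = TRUE, params = align_params()) {
  if (!nrow(markers)) stop("no markers to verify", call. = FALSE)
  gs <- manifest$genome_id
  m <- matrix(0, nrow(markers), length(gs),
              dimnames = list(paste0(markers$taxon, ":", markers$cluster_id), gs))
  gene_seqs <- lapply(setNames(gs, gs), function(g)
    genes$sequence[genes$genome_id == g])
  for (i in seq_len(nrow(markers))) {
    for (j in seq_along(gs)) {
      m[i, j] <- best_hit_identity(markers$sequence[i], gene_seqs[[gs[j]]],
                                   params, prefilter_k, use_prefilter)
    }
  }
  m
}
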