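# Greedy incremental centroid clustering of genes into a pan-genome,
# presence/absence matrix, and core/accessory/unique partitioning.

#' Cluster genes into pan-genome gene families
#'
#' Greedy incremental centroid clustering: genes are processed in
#' deterministic order (length descending, gene_id ascending tie-break);
#' each gene joins the first existing centroid whose global-alignment
#' identity is at least `threshold`, otherwise it founds a new cluster.
#' Before alignment, candidate centroids are screened by an exact length
#' bound (identity cannot exceed shorter/longer length) and, when
#' `use_prefilter` is TRUE, by requiring at least one shared k-mer.
#'
#' @param genes gene table (columns gene_id, genome_id, sequence, ...).
#' @param threshold identity threshold in (0, 1]; 0.50 is the
#'   conventional pan-genome default.
#' @param prefilter_k k-mer size for the shared-k-mer screen.
#' @param use_prefilter logical; disable to force alignment against every
#'   length-compatible centroid (used to verify the screen only prunes).
#' @param params alignment scoring from [align_params()].
#' @return object of class `gene_clusters`: list with `members`
#'   (data.frame cluster_id, gene_id, genome_id, identity) and
#'   `representatives` (data.frame cluster_id, gene_id, sequence).
#' @export
cluster_genes <- function(genes, threshold = 0.5, prefilter_k = 12L,
                          use_prefilter = TRUE, params = align_params()) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  stopifnot(all(c("gene_id", "genome_id", "sequence") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids", call. = FALSE)

  lens <- nchar(genes$sequence)
  ord <- order(-lens, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  lens <- lens[ord]
  n <- nrow(genes)

  cent_seq <- character(0)
  cent_len <- integer(0)
  cent_gene <- character(0)
  cent_prof <- list()

  assign_cluster <- integer(n)
  assign_ident <- numeric(n)

  for (i in seq_len(n)) {
    s <- genes$sequence[i]
    li <- lens[i]
    prof <- if (use_prefilter) kmer_profile(s, prefilter_k) else NULL
    hit <- 0L
    hit_id <- NA_real_
    cand_idx <- seq_along(cent_seq)
    if (use_prefilter && length(cand_idx)) {
      shared <- .shared_kmer_counts(prof, cent_prof)
      cand_idx <- cand_idx[shared > 0] # creation order preserved
    }
    for (ci in cand_idx) {
      if (identity_upper_bound(li, cent_len[ci]) < threshold) next
      id <- pairwise_identity(s, cent_seq[ci], params)$identity
      if (id >= threshold) {
        hit <- ci
        hit_id <- id
        break
      }
    }
    if (hit == 0L) {
      cent_seq <- c(cent_seq, s)
      cent_len <- c(cent_len, li)
      cent_gene <- c(cent_gene, genes$gene_id[i])
      cent_prof[[length(cent_seq)]] <- if (use_prefilter) prof else
        kmer_profile(s, prefilter_k)
      hit <- length(cent_seq)
      hit_id <- 1.0
    }
    assign_cluster[i] <- hit
    assign_ident[i] <- hit_id
  }

  cid <- sprintf("C%05d", seq_along(cent_seq))
  members <- data.frame(cluster_id = cid[assign_cluster],
                        gene_id = genes$gene_id,
                        genome_id = genes$genome_id,
                        identity = assign_ident,
                        stringsAsFactors = FALSE)
  representatives <- data.frame(cluster_id = cid, gene_id = cent_gene,
                                sequence = cent_seq, stringsAsFactors = FALSE)
  structure(list(members = members, representatives = representatives,
                 threshold = threshold),
            class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat(sprintf("pan-genome: %d genes in %d clusters (identity threshold %.2f)\n",
              nrow(x$members), nrow(x$representatives), x$threshold))
  invisible(x)
}

#' Build the clusters-by-genomes presence/absence (copy count) matrix
#'
#' @param clusters a `gene_clusters` object.
#' @param manifest genome-to-taxon manifest data frame; defines the
#'   column set and order. A cluster member from a genome absent from the
#'   manifest is an error.
#' @return integer matrix of class `pa_matrix` (clusters x genomes copy
#'   counts).
#' @export
build_matrix <- function(clusters, manifest) {
  stopifnot(inherits(clusters, "gene_clusters"))
  mem <- clusters$members
  unknown <- setdiff(unique(mem$genome_id), manifest$genome_id)
  if (length(unknown))
    stop("genome(s) absent from manifest: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cl <- clusters$representatives$cluster_id
  m <- table(factor(mem$cluster_id, levels = cl),
             factor(mem$genome_id, levels = manifest$genome_id))
  m <- matrix(as.integer(m), nrow = length(cl),
              dimnames = list(cl, manifest$genome_id))
  class(m) <- c("pa_matrix", class(m))
  m
}

#' Partition a pan-genome into core, accessory and unique clusters
#'
#' Core clusters are present (copy count >= 1) in every genome, unique
#' clusters in exactly one genome, accessory clusters in the rest; the
#' three sets partition all clusters.
#'
#' @param matrix a `pa_matrix`.
#' @return list with character vectors `core`, `accessory`, `unique`.
#' @export
partition_pangenome <- function(matrix) {
  if (ncol(matrix) < 2)
    stop("partition requires at least 2 genomes", call. = FALSE)
  pres <- rowSums(matrix > 0)
  list(core = rownames(matrix)[pres == ncol(matrix)],
       accessory = rownames(matrix)[pres > 1 & pres < ncol(matrix)],
       unique = rownames(matrix)[pres == 1])
}

#' Taxon core clusters
#'
#' Clusters present in at least `presence_fraction` of the taxon's
#' genomes (default 1.0: strict core). The strict default is deliberate:
#' when a marker is missing from some genomes of its labeled taxon, the
#' documented remedy is to audit the labels with [monophyly_report()]
#' rather than to loosen presence.
#'
#' @param matrix a `pa_matrix`.
#' @param manifest manifest data frame.
#' @param taxon taxon label.
#' @param presence_fraction fraction in (0, 1].
#' @return character vector of cluster ids.
#' @export
taxon_core <- function(matrix, manifest, taxon, presence_fraction = 1.0) {
  gs <- manifest$genome_id[manifest$taxon == taxon]
  if (!length(gs))
    stop("unknown taxon (no genomes): ", taxon, call. = FALSE)
  sub <- matrix[, gs, drop = FALSE]
  frac <- rowSums(sub > 0) / length(gs)
  rownames(matrix)[frac >= presence_fraction - 1e-9]
}
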