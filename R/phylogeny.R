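# Pan-genome frequency tree, core-identity tree, and taxon monophyly.

#' Distance between genomes from pan-genome cluster frequencies
#'
#' `jaccard` (default): 1 - shared/union on binary cluster presence.
#' `euclidean`: Euclidean distance on per-genome cluster count vectors,
#' normalized by the total number of clusters.
#'
#' @param matrix a `pa_matrix` (clusters x genomes).
#' @param metric `"jaccard"` or `"euclidean"`.
#' @return symmetric distance matrix with zero diagonal (genomes x
#'   genomes).
#' @export
frequency_distance <- function(matrix, metric = c("jaccard", "euclidean")) {
  metric <- match.arg(metric)
  if (ncol(matrix) < 3)
    stop("need at least 3 genomes", call. = FALSE)
  empty <- colSums(matrix > 0) == 0
  if (any(empty))
    stop("genome(s) with zero clusters: ",
         paste(colnames(matrix)[empty], collapse = ", "), call. = FALSE)
  if (metric == "jaccard") {
    d <- vegan::vegdist(t(matrix > 0), method = "jaccard", binary = TRUE)
  } else {
    d <- dist(t(matrix)) / nrow(matrix)
  }
  as.matrix(d)
}

#' Distance between genomes from mean core-gene identity
#'
#' For each genome pair, the mean [pairwise_identity()] over core
#' clusters in which both genomes have exactly one member (paralogous
#' copies are excluded per pair); distance is 1 minus that mean. A pair
#' with no usable single-copy core cluster is an error.
#'
#' @param genes gene table.
#' @param clusters a `gene_clusters` object.
#' @param core_ids character vector of core cluster ids.
#' @param params alignment scoring.
#' @return symmetric distance matrix with zero diagonal.
#' @export
core_identity_distance <- function(genes, clusters, core_ids,
                                   params = align_params()) {
  mem <- clusters$members[clusters$members$cluster_id %in% core_ids, ]
  if (!nrow(mem)) stop("no core clusters supplied", call. = FALSE)
  gs <- sort(unique(clusters$members$genome_id))
  seq_of <- setNames(genes$sequence, genes$gene_id)
  # single-copy members per (cluster, genome)
  key <- paste(mem$cluster_id, mem$genome_id)
  multi <- names(which(table(key) > 1))
  single <- mem[!(paste(mem$cluster_id, mem$genome_id) %in% multi), ]
  d <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  for (a in seq_len(length(gs) - 1)) {
    for (b in (a + 1):length(gs)) {
      sa <- single[single$genome_id == gs[a], ]
      sb <- single[single$genome_id == gs[b], ]
      shared <- intersect(sa$cluster_id, sb$cluster_id)
      if (!length(shared))
        stop("no shared single-copy core cluster for pair ", gs[a], " / ",
             gs[b], call. = FALSE)
      ids <- vapply(shared, function(cl) {
        pairwise_identity(seq_of[[sa$gene_id[sa$cluster_id == cl]]],
                          seq_of[[sb$gene_id[sb$cluster_id == cl]]],
                          params)$identity
      }, numeric(1))
      d[a, b] <- d[b, a] <- 1 - mean(ids)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining (via [ape::nj()]), exact on
#' additive distance matrices. Negative branch-length estimates are
#' clamped to zero and the clamped total is reported as a message.
#'
#' @param d symmetric distance matrix with zero diagonal, >= 3 leaves.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 leaves", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sprintf("neighbor_joining: clamped %d negative branch length(s), total %.4g",
                    sum(neg), -sum(tree$edge.length[neg])))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Test each taxon for monophyly in a tree
#'
#' A taxon is monophyletic iff some edge bipartition isolates exactly its
#' leaf set. For a non-monophyletic taxon the offending leaves are the
#' foreign genomes inside the smallest clade spanning the taxon.
#'
#' @param tree a `phylo` tree whose tips are genome ids.
#' @param manifest manifest data frame.
#' @return data frame with columns taxon, n_genomes, monophyletic,
#'   offending (comma-separated foreign leaves, empty when monophyletic).
#' @export
monophyly_report <- function(tree, manifest) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  extra <- setdiff(tips, manifest$genome_id)
  if (length(extra))
    stop("tree leaves missing from manifest: ", paste(extra, collapse = ", "),
         call. = FALSE)
  taxa <- unique(manifest$taxon[manifest$genome_id %in% tips])
  rows <- lapply(taxa, function(tx) {
    S <- intersect(manifest$genome_id[manifest$taxon == tx], tips)
    if (length(S) <= 1 || length(S) == length(tips)) {
      return(data.frame(taxon = tx, n_genomes = length(S),
                        monophyletic = TRUE, offending = "",
                        stringsAsFactors = FALSE))
    }
    out <- setdiff(tips, S)[1]
    rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
    mono <- ape::is.monophyletic(rooted, S)
    off <- ""
    if (!mono) {
      mrca <- ape::getMRCA(rooted, S)
      clade <- ape::extract.clade(rooted, mrca)$tip.label
      off <- paste(sort(setdiff(clade, S)), collapse = ",")
    }
    data.frame(taxon = tx, n_genomes = length(S), monophyletic = mono,
               offending = off, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
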