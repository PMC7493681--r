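# Reading and validating genomes, gene sets, annotations, manifests and
# primer tables; writing matrices and trees. Coordinates are 0-based
# half-open internally; GFF3 (1-based inclusive) is converted on ingest.

#' Read a genome-to-taxon manifest
#'
#' Two tab-separated columns, `genome_id` and `taxon` (header optional).
#'
#' @param path manifest path.
#' @return data frame with columns `genome_id`, `taxon`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- grepl("genome_id", first, fixed = TRUE)
  m <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(m)[1:2] <- c("genome_id", "taxon")
  m <- m[, c("genome_id", "taxon")]
  if (anyDuplicated(m$genome_id))
    stop("duplicate genome_id in manifest: ",
         paste(unique(m$genome_id[duplicated(m$genome_id)]), collapse = ", "),
         call. = FALSE)
  m
}

# parse "key=value" tokens from a FASTA header line; first token is the id
parse_header <- function(h) {
  toks <- strsplit(trimws(h), "\\s+")[[1]]
  kv <- toks[-1][grepl("=", toks[-1], fixed = TRUE)]
  vals <- sub("^[^=]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  list(id = toks[1], attrs = vals)
}

#' Read genome FASTA files with a taxon manifest
#'
#' One multi-FASTA per genome; the genome id is the file name without its
#' extension. A `replicon=` key in a contig header sets the replicon flag
#' (`chromosome`, `plasmid`), otherwise it is `unknown`. Optional CDS
#' FASTA files (headers as written by [simulate_pangenome()]) attach gene
#' records.
#'
#' @param genome_paths character vector of genome FASTA paths.
#' @param manifest_path path to the genome-to-taxon manifest.
#' @param cds_paths optional CDS FASTA paths, matched to genomes by the
#'   file name prefix `<genome_id>_cds`.
#' @return list with `genomes` (named list of `genome_record`: genome_id,
#'   taxon, contigs, replicon, genes) and `manifest`.
#' @export
read_genomes <- function(genome_paths, manifest_path, cds_paths = NULL) {
  manifest <- read_manifest(manifest_path)
  ids <- sub("\\.(fasta|fa|fna)$", "", basename(genome_paths))
  if (anyDuplicated(ids))
    stop("duplicate genome_id among input files: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  missing_file <- setdiff(manifest$genome_id, ids)
  if (length(missing_file))
    stop("manifest lists genomes with no genome file: ",
         paste(missing_file, collapse = ", "), call. = FALSE)
  missing_manifest <- setdiff(ids, manifest$genome_id)
  if (length(missing_manifest))
    stop("genome files not covered by manifest: ",
         paste(missing_manifest, collapse = ", "), call. = FALSE)

  cds_map <- list()
  if (!is.null(cds_paths)) {
    cds_ids <- sub("_cds\\.(fasta|fa|fna)$", "", basename(cds_paths))
    cds_map <- setNames(as.list(cds_paths), cds_ids)
  }

  genomes <- list()
  for (i in seq_along(genome_paths)) {
    g <- ids[i]
    fa <- read_fasta(genome_paths[i])
    heads <- lapply(names(fa), parse_header)
    contig_ids <- vapply(heads, `[[`, character(1), "id")
    if (anyDuplicated(contig_ids))
      stop("duplicate contig ids in genome ", g, call. = FALSE)
    repl <- vapply(heads, function(h) {
      r <- h$attrs["replicon"]
      if (is.na(r) || !r %in% c("chromosome", "plasmid")) "unknown" else unname(r)
    }, character(1))
    seqs <- setNames(unname(fa), contig_ids)
    assert_alphabet(seqs, IUPAC_CHARS, paste0("genome ", g))

    genes <- NULL
    if (!is.null(cds_map[[g]])) {
      genes <- read_gene_fasta(cds_map[[g]], genome_id = g)
      bad <- !(genes$contig_id %in% contig_ids)
      if (any(bad))
        stop("genes of genome ", g, " reference unknown contigs: ",
             paste(unique(genes$contig_id[bad]), collapse = ", "), call. = FALSE)
      lens <- nchar(seqs)[genes$contig_id]
      if (any(genes$start < 0 | genes$end > lens | genes$end <= genes$start))
        stop("gene coordinates outside contig bounds in genome ", g,
             call. = FALSE)
    }
    genomes[[g]] <- structure(
      list(genome_id = g, taxon = manifest$taxon[manifest$genome_id == g],
           contigs = seqs, replicon = setNames(repl, contig_ids),
           genes = genes),
      class = "genome_record")
  }
  list(genomes = genomes, manifest = manifest)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome %s (%s): %d contig(s), %s gene(s)\n", x$genome_id,
              x$taxon, length(x$contigs),
              if (is.null(x$genes)) "no" else nrow(x$genes)))
  invisible(x)
}

#' Read a CDS FASTA into a gene table
#'
#' Headers carry `genome=`, `contig=`, `start=`, `end=`, `strand=` and
#' optionally `replicon=` keys (the dialect written by
#' [simulate_pangenome()]); missing keys default to placeholders so that
#' plain CDS FASTA files are also accepted.
#'
#' @param path CDS FASTA path.
#' @param genome_id genome the genes belong to (overrides the header key).
#' @return data frame with columns gene_id, genome_id, contig_id, start,
#'   end, strand, replicon, sequence.
#' @export
read_gene_fasta <- function(path, genome_id = NULL) {
  fa <- read_fasta(path)
  heads <- lapply(names(fa), parse_header)
  get <- function(key, default) vapply(heads, function(h) {
    v <- h$attrs[key]
    if (is.na(v)) default else unname(v)
  }, character(1))
  gid <- if (is.null(genome_id)) get("genome", NA_character_) else genome_id
  df <- data.frame(
    gene_id = vapply(heads, `[[`, character(1), "id"),
    genome_id = gid,
    contig_id = get("contig", NA_character_),
    start = suppressWarnings(as.integer(get("start", NA_character_))),
    end = suppressWarnings(as.integer(get("end", NA_character_))),
    strand = get("strand", "+"),
    replicon = get("replicon", "unknown"),
    sequence = unname(fa),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids in ", path, call. = FALSE)
  assert_alphabet(df$sequence, IUPAC_CHARS, paste0("CDS of ", path))
  df
}

#' Extract CDS gene records from a GFF3 annotation
#'
#' CDS features are sliced from the genome contigs; minus-strand features
#' are reverse complemented so the stored sequence is always the coding
#' strand. GFF3 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param genome a `genome_record` from [read_genomes()].
#' @param gff_path path to a GFF3 file.
#' @return gene table (as in [read_gene_fasta()]).
#' @export
extract_cds <- function(genome, gff_path) {
  stopifnot(inherits(genome, "genome_record"))
  gr <- as.data.frame(rtracklayer::import(gff_path))
  gr <- gr[gr$type == "CDS", , drop = FALSE]
  if (nrow(gr) == 0) return(NULL)
  seqid <- as.character(gr$seqnames)
  unknown <- setdiff(unique(seqid), names(genome$contigs))
  if (length(unknown))
    stop("GFF references unknown seqid(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  start0 <- gr$start - 1L
  end0 <- gr$end
  lens <- nchar(genome$contigs)[seqid]
  if (any(start0 < 0 | end0 > lens))
    stop("CDS outside contig bounds in ", gff_path, call. = FALSE)
  strand <- as.character(gr$strand)
  strand[!strand %in% c("+", "-")] <- "+"
  seqs <- substring(genome$contigs[seqid], start0 + 1L, end0)
  neg <- strand == "-"
  seqs[neg] <- revcomp(seqs[neg])
  ids <- if (!is.null(gr$ID) && !anyNA(gr$ID)) as.character(gr$ID) else
    sprintf("%s|%s|%d-%d(%s)", genome$genome_id, seqid, start0, end0, strand)
  data.frame(gene_id = ids, genome_id = genome$genome_id, contig_id = seqid,
             start = start0, end = end0, strand = strand,
             replicon = unname(genome$replicon[seqid]),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write / read a presence-absence matrix
#'
#' Tab-separated, clusters as rows, genomes as columns, integer copy
#' counts; first column `cluster_id`.
#'
#' @param matrix a `pa_matrix` (or plain integer matrix with dimnames).
#' @param path output path.
#' @return the path (write) or the matrix (read).
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(cluster_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cluster_id
  storage.mode(m) <- "integer"
  class(m) <- c("pa_matrix", class(m))
  m
}

#' Write / read a tree in newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so that
#' trees round-trip with branch lengths.
#'
#' @param tree a `phylo` object.
#' @param path newick file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read a primer table
#'
#' Tab-separated columns `taxon`, `name`, `sequence` and optionally
#' `size` (expected product size). The dialect follows published primer
#' tables: whitespace inside oligo sequences is ignored (triplet-spaced
#' oligos parse correctly) and the taxon cell of a reverse-primer row may
#' be empty, inheriting the previous row's taxon. Rows are paired F then
#' R per taxon. Degenerate bases are illegal in primers: any non-ACGT
#' character is an error.
#'
#' @param path primer table path.
#' @return data frame of class `primer_pairs` with columns `name`,
#'   `taxon`, `forward`, `reverse`, `expected_size`.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("primer table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- grepl("name", first) && grepl("taxon", first)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!has_header) {
    names(df)[1:3] <- c("taxon", "name", "sequence")
    if (ncol(df) >= 4) names(df)[4] <- "size"
  }
  if (!"size" %in% names(df)) df$size <- NA
  # fill empty taxon cells down (reverse rows inherit the pair's taxon)
  tx <- df$taxon
  for (i in seq_along(tx)) if (!nzchar(tx[i]) || is.na(tx[i])) tx[i] <- tx[i - 1]
  df$taxon <- tx
  df$sequence <- toupper(gsub("\\s+", "", df$sequence))
  assert_alphabet(df$sequence, DNA_BASES, "primer sequence")
  if (nrow(df) %% 2 != 0)
    stop("primer table must contain an even number of oligo rows (F/R pairs)",
         call. = FALSE)
  fi <- seq(1, nrow(df), by = 2)
  ri <- fi + 1
  pairs <- data.frame(
    name = sub("[-_]?[FfRr]$", "", df$name[fi]),
    taxon = df$taxon[fi],
    forward = df$sequence[fi],
    reverse = df$sequence[ri],
    expected_size = suppressWarnings(as.integer(df$size[fi])),
    stringsAsFactors = FALSE)
  class(pairs) <- c("primer_pairs", class(pairs))
  pairs
}

# pooled gene table across a genome set read by read_genomes()
genes_table <- function(genome_set) {
  gl <- lapply(genome_set$genomes, `[[`, "genes")
  gl <- gl[!vapply(gl, is.null, logical(1))]
  if (!length(gl)) stop("no gene records attached to the genome set", call. = FALSE)
  df <- do.call(rbind, gl)
  rownames(df) <- NULL
  df
}
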