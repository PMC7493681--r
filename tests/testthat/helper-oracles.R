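# Independent oracle implementations used to cross-check the package's
# compiled/optimized code paths. These deliberately share no code with
# the implementations they verify.

# --- global alignment: plain-R Gotoh DP with the same objective --------
# lexicographic (score desc, matches desc, columns asc); gap run of
# length L costs open + (L-1)*extend
oracle_align <- function(a, b, match = 1, mismatch = -1, open = 10,
                         extend = 1) {
  va <- strsplit(a, NULL, fixed = TRUE)[[1]]
  vb <- strsplit(b, NULL, fixed = TRUE)[[1]]
  n <- length(va)
  m <- length(vb)
  NEG <- -1e15
  worse <- c(NEG, 0, 0)
  better <- function(x, y) {
    if (x[1] != y[1]) return(x[1] > y[1])
    if (x[2] != y[2]) return(x[2] > y[2])
    x[3] < y[3]
  }
  best_of <- function(...) {
    cells <- list(...)
    r <- cells[[1]]
    for (c2 in cells[-1]) if (better(c2, r)) r <- c2
    r
  }
  # cells are c(score, matches, columns)
  M <- X <- Y <- array(NEG, dim = c(n + 1, m + 1, 3))
  M[1, 1, ] <- c(0, 0, 0)
  for (j in 2:(m + 1)) Y[1, j, ] <- c(-open - (j - 2) * extend, 0, j - 1)
  for (i in 2:(n + 1)) X[i, 1, ] <- c(-open - (i - 2) * extend, 0, i - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      eq <- va[i - 1] == vb[j - 1]
      s <- if (eq) match else mismatch
      d <- best_of(M[i - 1, j - 1, ], X[i - 1, j - 1, ], Y[i - 1, j - 1, ])
      if (d[1] > NEG / 2) M[i, j, ] <- c(d[1] + s, d[2] + eq, d[3] + 1)
      xo <- best_of(M[i - 1, j, ], Y[i - 1, j, ])
      x1 <- if (xo[1] > NEG / 2) c(xo[1] - open, xo[2], xo[3] + 1) else worse
      x2 <- if (X[i - 1, j, 1] > NEG / 2)
        c(X[i - 1, j, 1] - extend, X[i - 1, j, 2], X[i - 1, j, 3] + 1) else worse
      X[i, j, ] <- if (better(x1, x2)) x1 else x2
      yo <- best_of(M[i, j - 1, ], X[i, j - 1, ])
      y1 <- if (yo[1] > NEG / 2) c(yo[1] - open, yo[2], yo[3] + 1) else worse
      y2 <- if (Y[i, j - 1, 1] > NEG / 2)
        c(Y[i, j - 1, 1] - extend, Y[i, j - 1, 2], Y[i, j - 1, 3] + 1) else worse
      Y[i, j, ] <- if (better(y1, y2)) y1 else y2
    }
  }
  r <- best_of(M[n + 1, m + 1, ], X[n + 1, m + 1, ], Y[n + 1, m + 1, ])
  list(score = r[1], matches = r[2], alignment_length = r[3],
       identity = r[2] / r[3])
}

# --- brute-force enumeration of every global alignment (tiny strings) --
oracle_align_enum <- function(a, b, match = 1, mismatch = -1, open = 10,
                              extend = 1) {
  va <- strsplit(a, NULL, fixed = TRUE)[[1]]
  vb <- strsplit(b, NULL, fixed = TRUE)[[1]]
  best <- NULL
  rec <- function(i, j, last, score, matches, len) {
    if (i > length(va) && j > length(vb)) {
      cand <- c(score, matches, len)
      if (is.null(best) || cand[1] > best[1] ||
          (cand[1] == best[1] && cand[2] > best[2]) ||
          (cand[1] == best[1] && cand[2] == best[2] && cand[3] < best[3]))
        best <<- cand
      return(invisible())
    }
    if (i <= length(va) && j <= length(vb)) {
      eq <- va[i] == vb[j]
      rec(i + 1, j + 1, "d", score + if (eq) match else mismatch,
          matches + eq, len + 1)
    }
    if (i <= length(va))
      rec(i + 1, j, "x", score - if (last == "x") extend else open,
          matches, len + 1)
    if (j <= length(vb))
      rec(i, j + 1, "y", score - if (last == "y") extend else open,
          matches, len + 1)
  }
  rec(1, 1, "none", 0, 0, 0)
  list(score = best[1], matches = best[2], alignment_length = best[3],
       identity = best[2] / best[3])
}

# --- naive greedy clustering: same ordering rule, no prefilter ---------
oracle_cluster <- function(genes, threshold = 0.5, params = align_params()) {
  lens <- nchar(genes$sequence)
  genes <- genes[order(-lens, genes$gene_id), , drop = FALSE]
  cent <- character(0)
  assign <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- 0L
    for (ci in seq_along(cent)) {
      if (pairwise_identity(genes$sequence[i], cent[ci], params)$identity >=
          threshold) {
        hit <- ci
        break
      }
    }
    if (hit == 0L) {
      cent <- c(cent, genes$sequence[i])
      hit <- length(cent)
    }
    assign[i] <- hit
  }
  data.frame(gene_id = genes$gene_id, cluster = assign,
             stringsAsFactors = FALSE)
}

# --- naive binding-site scan for in-silico PCR -------------------------
oracle_oligo_sites <- function(oligo, tmpl, max_mm = 2, tpe = 2) {
  ov <- strsplit(oligo, NULL, fixed = TRUE)[[1]]
  rv <- strsplit(revcomp(oligo), NULL, fixed = TRUE)[[1]]
  tv <- strsplit(tmpl, NULL, fixed = TRUE)[[1]]
  l <- length(ov)
  out <- list()
  for (p in 0:(length(tv) - l)) {
    w <- tv[(p + 1):(p + l)]
    mm <- sum(w != ov)
    if (mm <= max_mm && all(w[(l - tpe + 1):l] == ov[(l - tpe + 1):l]))
      out[[length(out) + 1]] <- c(p, 1L, mm)
    mm <- sum(w != rv)
    if (mm <= max_mm && all(w[1:tpe] == rv[1:tpe]))
      out[[length(out) + 1]] <- c(p, -1L, mm)
  }
  if (!length(out)) return(matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("start", "strand", "mismatches"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "strand", "mismatches")
  m
}

# --- closed-form OLS ---------------------------------------------------
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# --- independently coded nearest-neighbor Tm ---------------------------
# full 16-stack table entered separately (SantaLucia 1998 unified set)
oracle_tm_nn <- function(oligo, Na_mM = 50, oligo_uM = 0.5) {
  dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
          CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
          GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
          TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
          CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
          GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
          TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  v <- strsplit(oligo, NULL, fixed = TRUE)[[1]]
  n <- length(v)
  din <- paste0(v[-n], v[-1])
  H <- sum(dh[din])
  S <- sum(ds[din])
  for (term in c(v[1], v[n])) {
    if (term %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  S <- S + 0.368 * (n - 1) * log(Na_mM / 1000)
  1000 * H / (S + 1.9872 * log(oligo_uM * 1e-6 / 4)) - 273.15
}

# --- small simulated fixture shared across tests -----------------------
# built once per test run; small genes keep the R alignment oracle usable
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(n_taxa = 3, genomes_per_taxon = 2,
                              n_genus_core = 3, n_taxon_markers = 2,
                              n_accessory = 3, n_decoy = 2,
                              within_taxon_sub_rate = 0.01,
                              cross_taxon_divergence = 0.45,
                              plasmid_fraction = 0.5,
                              gene_length_range = c(150, 400), seed = 7)
      dir <- file.path(tempdir(), "panmarker_tiny_sim")
      sim <- simulate_pangenome(spec, dir)
      gset <- read_genomes(sim$genome_paths, sim$manifest_path, sim$cds_paths)
      genes <- do.call(rbind, lapply(gset$genomes, `[[`, "genes"))
      rownames(genes) <- NULL
      clusters <- cluster_genes(genes)
      mat <- build_matrix(clusters, gset$manifest)
      cache <<- list(spec = spec, sim = sim, gset = gset, genes = genes,
                     clusters = clusters, matrix = mat,
                     manifest = gset$manifest)
    }
    cache
  }
})

# map each cluster to the simulation family/families of its members
cluster_families <- function(clusters, truth) {
  fam <- truth$family[match(clusters$members$gene_id, truth$gene_id)]
  vapply(split(fam, clusters$members$cluster_id), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
}
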