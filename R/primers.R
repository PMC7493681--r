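# qPCR primer design on marker genes and in-silico PCR specificity
# screening.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); dinucleotides read 5'->3' on one
# strand, the complementary stack shares the value of its reverse
# complement.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
# fill in the complementary stacks (TT = AA etc.)
local({
  rc2 <- function(d) chartr("ACGT", "TGCA", paste(rev(strsplit(d, NULL)[[1]]), collapse = ""))
  for (d in names(NN_DH)) {
    r <- rc2(d)
    if (!r %in% names(NN_DH)) {
      NN_DH[[r]] <<- NN_DH[[d]]
      NN_DS[[r]] <<- NN_DS[[d]]
    }
  }
})
# initiation terms per terminal base
NN_INIT_DH <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
NN_INIT_DS <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)
GAS_R <- 1.9872 # cal/(mol K)

#' Oligo melting temperature
#'
#' `wallace`: the 2AT+4GC rule. `nn`: SantaLucia (1998) unified
#' nearest-neighbor thermodynamics with terminal initiation terms, the
#' entropic salt correction dS + 0.368 (N-1) ln\[Na+\], and
#' Tm = 1000 dH / (dS + R ln(C/4)) - 273.15 for a non-self-complementary
#' oligo at total strand concentration C. Defaults match the assay
#' conditions (0.5 uM of each primer, 50 mM monovalent salt, annealing
#' target 60 degrees C).
#'
#' @param oligo primer sequence, 4-36 nt over A/C/G/T.
#' @param method `"nn"` (default) or `"wallace"`.
#' @param Na_mM monovalent cation concentration in mM.
#' @param oligo_uM oligo concentration in uM.
#' @return melting temperature in degrees C.
#' @export
#' @examples
#' melting_temperature("ACGT", method = "wallace")  # 12
melting_temperature <- function(oligo, method = c("nn", "wallace"),
                                Na_mM = 50, oligo_uM = 0.5) {
  method <- match.arg(method)
  if (!is.character(oligo) || length(oligo) != 1)
    stop("oligo must be a single string", call. = FALSE)
  n <- nchar(oligo)
  if (n < 4 || n > 36)
    stop("oligo length must be in 4..36", call. = FALSE)
  assert_alphabet(oligo, DNA_BASES, "oligo")
  v <- strsplit(oligo, NULL, fixed = TRUE)[[1]]
  if (method == "wallace") {
    return(2 * sum(v %in% c("A", "T")) + 4 * sum(v %in% c("G", "C")))
  }
  din <- paste0(v[-n], v[-1])
  dH <- sum(NN_DH[din]) + NN_INIT_DH[[v[1]]] + NN_INIT_DH[[v[n]]]
  dS <- sum(NN_DS[din]) + NN_INIT_DS[[v[1]]] + NN_INIT_DS[[v[n]]]
  dS <- dS + 0.368 * (n - 1) * log(Na_mM / 1000)
  ct <- oligo_uM * 1e-6
  1000 * dH / (dS + GAS_R * log(ct / 4)) - 273.15
}

# vectorized nn Tm for all windows of a fixed length over a sequence
tm_nn_windows <- function(seq, len, Na_mM = 50, oligo_uM = 0.5) {
  v <- strsplit(seq, NULL, fixed = TRUE)[[1]]
  n <- length(v)
  if (n < len) return(numeric(0))
  din <- paste0(v[-n], v[-1])
  cdh <- c(0, cumsum(NN_DH[din]))
  cds <- c(0, cumsum(NN_DS[din]))
  starts <- seq_len(n - len + 1L)
  ends <- starts + len - 1L
  dH <- cdh[ends] - cdh[starts] + NN_INIT_DH[v[starts]] + NN_INIT_DH[v[ends]]
  dS <- cds[ends] - cds[starts] + NN_INIT_DS[v[starts]] + NN_INIT_DS[v[ends]]
  dS <- dS + 0.368 * (len - 1) * log(Na_mM / 1000)
  ct <- oligo_uM * 1e-6
  unname(1000 * dH / (dS + GAS_R * log(ct / 4)) - 273.15)
}

#' GC fraction of an oligo
#' @param oligo sequence over A/C/G/T.
#' @return fraction in \[0, 1\].
#' @export
gc_fraction <- function(oligo) {
  v <- strsplit(oligo, NULL, fixed = TRUE)[[1]]
  mean(v %in% c("G", "C"))
}

max_homopolymer <- function(oligo) {
  max(rle(strsplit(oligo, NULL, fixed = TRUE)[[1]])$lengths)
}

# longest common substring length between two strings (small inputs)
lcs_substring <- function(a, b) {
  va <- strsplit(a, NULL, fixed = TRUE)[[1]]
  vb <- strsplit(b, NULL, fixed = TRUE)[[1]]
  best <- 0L
  prev <- integer(length(vb))
  for (i in seq_along(va)) {
    cur <- integer(length(vb))
    eq <- va[i] == vb
    cur[eq] <- c(0L, prev)[which(eq)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# longest suffix of `a` occurring contiguously in `b`
suffix_run <- function(a, b) {
  la <- nchar(a)
  for (r in la:1) {
    if (grepl(substring(a, la - r + 1, la), b, fixed = TRUE)) return(r)
  }
  0L
}

#' Primer-dimer complementarity score
#'
#' Maximal antiparallel complementary run length between two oligos
#' (longest common substring of `a` and the reverse complement of `b`);
#' runs anchored at either 3' end are weighted double, reflecting their
#' extension potential.
#'
#' @param a,b oligo sequences.
#' @return integer score.
#' @export
dimer_score <- function(a, b) {
  rb <- revcomp(b)
  ra <- revcomp(a)
  run <- lcs_substring(a, rb)
  anchored <- max(suffix_run(a, rb), suffix_run(b, ra))
  max(run, 2L * anchored)
}

#' Hairpin complementarity score
#'
#' Longest self-complementary stem with a loop of at least 3 nt.
#'
#' @param a oligo sequence.
#' @return integer stem length.
#' @export
hairpin_score <- function(a) {
  v <- strsplit(a, NULL, fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(v)
  best <- 0L
  # R[i,j]: stem length of pairing (i,j),(i+1,j-1),... requires i < j
  for (i in seq_len(n - 4)) {
    for (j in seq.int(n, i + 4)) {
      r <- 0L
      while (i + r < j - r && v[i + r] == comp[[v[j - r]]]) r <- r + 1L
      # loop between the innermost paired bases must be >= 3
      if (r > 0L && (j - r) - (i + r - 1L) - 1L >= 3L) best <- max(best, r)
    }
  }
  best
}

#' Default primer design constraints
#'
#' Products are capped at 200 bp - short amplicons amplify efficiently
#' from processed-food DNA - with an 80 bp floor so products stay
#' separable from primer artifacts in SYBR assays. Tm window brackets the
#' 60 degree annealing step.
#'
#' @param min_len,max_len oligo length bounds (nt).
#' @param tm_range nearest-neighbor Tm interval (degrees C).
#' @param gc_range GC-fraction interval.
#' @param min_amplicon,max_amplicon product-size bounds (bp).
#' @param max_homopolymer longest allowed single-base run.
#' @param max_dimer_score,max_hairpin_score complementarity caps (see
#'   [dimer_score()], [hairpin_score()]).
#' @return named list of constraints.
#' @export
primer_constraints <- function(min_len = 18L, max_len = 24L,
                               tm_range = c(58, 62), gc_range = c(0.40, 0.60),
                               min_amplicon = 80L, max_amplicon = 200L,
                               max_homopolymer = 4L, max_dimer_score = 8L,
                               max_hairpin_score = 6L) {
  list(min_len = min_len, max_len = max_len, tm_range = tm_range,
       gc_range = gc_range, min_amplicon = min_amplicon,
       max_amplicon = max_amplicon, max_homopolymer = max_homopolymer,
       max_dimer_score = max_dimer_score,
       max_hairpin_score = max_hairpin_score)
}

#' Design qPCR primer pairs on a marker sequence
#'
#' Exhaustive scan of forward/reverse windows passing the per-oligo
#' filters (Tm, GC, homopolymer, hairpin, optional conservation mask);
#' pairs within the product-size bounds are ranked by Tm balance
#' |Tm_f - Tm_r| ascending, then |mean Tm - Tm target| ascending, then
#' product size ascending, with coordinates as the deterministic
#' tie-break; the dimer filter is applied in rank order. All returned
#' pairs satisfy every constraint.
#'
#' @param marker marker nucleotide sequence (coding strand).
#' @param constraints from [primer_constraints()].
#' @param top_n number of pairs to return.
#' @param conservation optional logical vector, one element per marker
#'   position; oligo windows must lie entirely on TRUE positions. Use
#'   the positions invariant across all target-taxon copies so designed
#'   primers bind every strain of the target.
#' @param tm_target ranking target for the mean Tm (degrees C).
#' @param name_prefix,taxon used to label the returned pairs.
#' @return `primer_pairs` data frame (possibly 0 rows) with oligo
#'   sequences, 0-based half-open binding coordinates on the marker,
#'   product size, Tm, GC, dimer and hairpin scores.
#' @export
design_primers <- function(marker, constraints = primer_constraints(),
                           top_n = 5L, conservation = NULL, tm_target = 60,
                           name_prefix = "pair", taxon = NA_character_) {
  cs <- constraints
  L <- nchar(marker)
  if (L < cs$min_amplicon)
    stop("marker shorter than min_amplicon (", cs$min_amplicon, " nt)",
         call. = FALSE)
  assert_alphabet(marker, DNA_BASES, "marker")
  if (!is.null(conservation) && length(conservation) != L)
    stop("conservation mask length must equal marker length", call. = FALSE)
  cons_cum <- if (is.null(conservation)) NULL else c(0L, cumsum(!conservation))

  # per-oligo candidates over all window lengths; sense windows serve as
  # forward oligos, their reverse complements as reverse oligos
  cand <- list()
  for (len in cs$min_len:cs$max_len) {
    if (L < len) next
    starts <- seq_len(L - len + 1L) # 1-based
    tm <- tm_nn_windows(marker, len)
    win <- substring(marker, starts, starts + len - 1L)
    ok <- tm >= cs$tm_range[1] & tm <= cs$tm_range[2]
    gc <- vapply(win, gc_fraction, numeric(1), USE.NAMES = FALSE)
    ok <- ok & gc >= cs$gc_range[1] & gc <= cs$gc_range[2]
    ok <- ok & !grepl(sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                              cs$max_homopolymer + 1L, cs$max_homopolymer + 1L,
                              cs$max_homopolymer + 1L, cs$max_homopolymer + 1L),
                      win)
    if (!is.null(cons_cum))
      ok <- ok & (cons_cum[starts + len] - cons_cum[starts]) == 0L
    if (any(ok)) {
      cand[[length(cand) + 1L]] <- data.frame(
        start0 = starts[ok] - 1L, end0 = starts[ok] - 1L + len,
        len = len, seq = win[ok], tm = tm[ok], gc = gc[ok],
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(name = character(0), taxon = character(0),
                      forward = character(0), reverse = character(0),
                      fwd_start = integer(0), fwd_end = integer(0),
                      rev_start = integer(0), rev_end = integer(0),
                      product_size = integer(0), tm_forward = numeric(0),
                      tm_reverse = numeric(0), gc_forward = numeric(0),
                      gc_reverse = numeric(0), dimer_score = integer(0),
                      hairpin_score = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("primer_pairs", class(empty))
  if (!length(cand)) {
    message("design_primers: no oligo window satisfies the per-oligo filters")
    return(empty)
  }
  cand <- do.call(rbind, cand)
  # hairpin filter per oligo (forward sense and reverse complement both
  # fold identically up to relabeling, so one score per window suffices)
  cand$hairpin <- vapply(cand$seq, hairpin_score, integer(1), USE.NAMES = FALSE)
  cand <- cand[cand$hairpin <= cs$max_hairpin_score, , drop = FALSE]
  if (!nrow(cand)) {
    message("design_primers: all windows rejected by the hairpin filter")
    return(empty)
  }

  # enumerate pairs within the product-size bounds
  fwd <- cand
  rev <- cand
  pairs <- list()
  for (i in seq_len(nrow(fwd))) {
    prod <- rev$end0 - fwd$start0[i]
    sel <- which(prod >= cs$min_amplicon & prod <= cs$max_amplicon &
                   rev$start0 >= fwd$end0[i])
    if (length(sel)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        fi = i, ri = sel, product = prod[sel], stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) {
    message("design_primers: no pair satisfies the product-size bounds")
    return(empty)
  }
  pairs <- do.call(rbind, pairs)
  dtm <- abs(fwd$tm[pairs$fi] - rev$tm[pairs$ri])
  mtm <- abs((fwd$tm[pairs$fi] + rev$tm[pairs$ri]) / 2 - tm_target)
  ord <- order(dtm, mtm, pairs$product, fwd$start0[pairs$fi],
               rev$start0[pairs$ri])
  pairs <- pairs[ord, , drop = FALSE]

  # dimer filter lazily in rank order
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    fi <- pairs$fi[r]
    ri <- pairs$ri[r]
    f_seq <- fwd$seq[fi]
    r_seq <- revcomp(rev$seq[ri])
    ds <- max(dimer_score(f_seq, f_seq), dimer_score(r_seq, r_seq),
              dimer_score(f_seq, r_seq))
    if (ds > cs$max_dimer_score) next
    k <- length(out) + 1L
    out[[k]] <- data.frame(
      name = sprintf("%s%02d", name_prefix, k), taxon = taxon,
      forward = f_seq, reverse = r_seq,
      fwd_start = fwd$start0[fi], fwd_end = fwd$end0[fi],
      rev_start = rev$start0[ri], rev_end = rev$end0[ri],
      product_size = pairs$product[r],
      tm_forward = fwd$tm[fi], tm_reverse = rev$tm[ri],
      gc_forward = fwd$gc[fi], gc_reverse = rev$gc[ri],
      dimer_score = ds,
      hairpin_score = max(fwd$hairpin[fi], rev$hairpin[ri]),
      stringsAsFactors = FALSE)
    if (k >= top_n) break
  }
  if (!length(out)) {
    message("design_primers: all ranked pairs rejected by the dimer filter")
    return(empty)
  }
  res <- do.call(rbind, out)
  class(res) <- c("primer_pairs", class(res))
  res
}

#' In-silico PCR of a primer pair against genomes
#'
#' Finds all binding sites of the forward and reverse oligos on both
#' strands of every contig (no indels; at most `max_mismatch`
#' substitutions per oligo, none in the 3'-terminal `three_prime_exact`
#' bases) and reports every convergent, non-overlapping site pair whose
#' product is at most `max_product` bp.
#'
#' @param pair one row of a `primer_pairs` data frame (or a list with
#'   `forward`, `reverse`, `name`).
#' @param genomes named list of `genome_record`s, or a named list of
#'   named character vectors of contigs.
#' @param max_mismatch allowed substitutions per oligo.
#' @param three_prime_exact 3'-terminal bases that must match exactly.
#' @param max_product maximal product size in bp.
#' @return data frame of amplicon hits: genome_id, contig_id, start, end
#'   (0-based half-open), strand (`+` if the forward oligo matches the
#'   plus strand), fwd_mismatches, rev_mismatches, product_size.
#' @export
in_silico_pcr <- function(pair, genomes, max_mismatch = 2L,
                          three_prime_exact = 2L, max_product = 1500L) {
  fwd <- toupper(pair$forward)
  rev <- toupper(pair$reverse)
  lf <- nchar(fwd)
  lr <- nchar(rev)
  hits <- list()
  for (g in names(genomes)) {
    rec <- genomes[[g]]
    contigs <- if (inherits(rec, "genome_record")) rec$contigs else rec
    for (cid in names(contigs)) {
      tmpl <- contigs[[cid]]
      fh <- .oligo_sites(fwd, tmpl, max_mismatch, three_prime_exact)
      rh <- .oligo_sites(rev, tmpl, max_mismatch, three_prime_exact)
      if (!nrow(fh) || !nrow(rh)) next
      # plus-strand amplicon: forward on +, reverse on -
      fp <- fh[fh[, "strand"] == 1L, , drop = FALSE]
      rm_ <- rh[rh[, "strand"] == -1L, , drop = FALSE]
      for (i in seq_len(nrow(fp))) {
        prod <- rm_[, "start"] + lr - fp[i, "start"]
        sel <- which(rm_[, "start"] >= fp[i, "start"] + lf & prod <= max_product)
        for (j in sel) {
          hits[[length(hits) + 1L]] <- data.frame(
            genome_id = g, contig_id = cid,
            start = fp[i, "start"], end = rm_[j, "start"] + lr,
            strand = "+", fwd_mismatches = fp[i, "mismatches"],
            rev_mismatches = rm_[j, "mismatches"],
            product_size = prod[j], stringsAsFactors = FALSE)
        }
      }
      # minus-strand amplicon: forward on -, reverse on +
      fm <- fh[fh[, "strand"] == -1L, , drop = FALSE]
      rp <- rh[rh[, "strand"] == 1L, , drop = FALSE]
      for (i in seq_len(nrow(fm))) {
        prod <- fm[i, "start"] + lf - rp[, "start"]
        sel <- which(fm[i, "start"] >= rp[, "start"] + lr & prod <= max_product)
        for (j in sel) {
          hits[[length(hits) + 1L]] <- data.frame(
            genome_id = g, contig_id = cid,
            start = rp[j, "start"], end = fm[i, "start"] + lf,
            strand = "-", fwd_mismatches = fm[i, "mismatches"],
            rev_mismatches = rp[j, "mismatches"],
            product_size = prod[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(genome_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0), product_size = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$genome_id, out$contig_id, out$start, out$end), , drop = FALSE]
}

#' Amplification matrix and per-pair sensitivity/specificity
#'
#' Runs [in_silico_pcr()] for every pair against every genome and
#' summarizes, per pair, sensitivity (fraction of its taxon's genomes
#' amplified) and specificity (fraction of non-target genomes not
#' amplified).
#'
#' @param pairs `primer_pairs` data frame with a `taxon` column.
#' @param genomes named list of `genome_record`s (or contig vectors).
#' @param manifest manifest data frame.
#' @param ... passed to [in_silico_pcr()].
#' @return list with `amplified` (logical pairs x genomes matrix),
#'   `products` (comma-separated product sizes, same shape) and
#'   `summary` (per-pair data frame with sensitivity and specificity).
#' @export
specificity_matrix <- function(pairs, genomes, manifest, ...) {
  if (!nrow(pairs)) stop("no primer pairs supplied", call. = FALSE)
  gs <- names(genomes)
  amp <- matrix(FALSE, nrow(pairs), length(gs),
                dimnames = list(pairs$name, gs))
  prods <- matrix("", nrow(pairs), length(gs), dimnames = list(pairs$name, gs))
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_along(gs)) {
      h <- in_silico_pcr(pairs[i, ], genomes[gs[j]], ...)
      amp[i, j] <- nrow(h) > 0
      prods[i, j] <- paste(h$product_size, collapse = ",")
    }
  }
  taxon_of <- setNames(manifest$taxon, manifest$genome_id)
  summary <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    tg <- gs[taxon_of[gs] == pairs$taxon[i]]
    ng <- setdiff(gs, tg)
    data.frame(name = pairs$name[i], taxon = pairs$taxon[i],
               n_target = length(tg), n_nontarget = length(ng),
               sensitivity = if (length(tg)) mean(amp[i, tg]) else NA_real_,
               specificity = if (length(ng)) mean(!amp[i, ng]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(amplified = amp, products = prods, summary = summary)
}
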