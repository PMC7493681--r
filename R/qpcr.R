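# Standard curves, amplification efficiency, quantification, and product
# label-claim comparison.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct against log10 concentration (log10
#' CFU/mL). R^2 is the squared Pearson correlation; amplification
#' efficiency is derived from the slope. A warning is emitted when R^2
#' falls below 0.98, the conventional reliability floor for quantitative
#' real-time PCR.
#'
#' @param points data frame with columns `log10_conc` and `ct` (>= 3
#'   distinct concentrations; a 5-point serial dilution in triplicate is
#'   typical).
#' @param taxon label carried on the curve.
#' @param dynamic_range log10 interval within which quantification is
#'   interpolation; defaults to the 8e5..8e9 CFU/mL assay range.
#' @return object of class `standard_curve`: taxon, slope, intercept,
#'   r_squared, efficiency_percent, dynamic_range, n_points.
#' @export
fit_standard_curve <- function(points, taxon = NA_character_,
                               dynamic_range = log10(c(8e5, 8e9))) {
  stopifnot(all(c("log10_conc", "ct") %in% names(points)))
  x <- points$log10_conc
  y <- points$ct
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  if (isTRUE(all.equal(var(x), 0)))
    stop("zero variance in concentrations", call. = FALSE)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- cor(x, y)^2
  if (r2 < 0.98)
    warning(sprintf("standard curve R^2 = %.4f is below the 0.98 reliability floor", r2))
  eff <- if (slope < 0) efficiency_from_slope(slope) else NA_real_
  if (slope >= 0)
    warning("non-negative slope: Ct should decrease with concentration")
  structure(list(taxon = taxon, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency_percent = eff,
                 dynamic_range = dynamic_range, n_points = length(x)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve [%s]: Ct = %.3f x + %.2f, R^2 = %.4f, Eff%% = %.3f\n",
              x$taxon, x$slope, x$intercept, x$r_squared, x$efficiency_percent))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `(10^(-1/slope) - 1) * 100`; 100 percent means perfect doubling per
#' cycle (slope -1/log10(2) = -3.3219).
#'
#' @param slope Ct per log10 concentration, must be negative.
#' @return efficiency in percent.
#' @export
#' @examples
#' efficiency_from_slope(-1 / log10(2))  # 100
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || any(slope >= 0))
    stop("slope must be negative", call. = FALSE)
  (10^(-1 / slope) - 1) * 100
}

#' Quantify a Ct value against a standard curve
#'
#' Inverts the curve: x = (Ct - intercept) / slope. Values outside the
#' curve's dynamic range are still returned but flagged as extrapolated.
#'
#' @param ct threshold-cycle value(s).
#' @param curve a `standard_curve`.
#' @return data frame with `log10_conc` and `extrapolated`.
#' @export
quantify_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  x <- (ct - curve$intercept) / curve$slope
  data.frame(log10_conc = x,
             extrapolated = x < curve$dynamic_range[1] |
               x > curve$dynamic_range[2])
}

#' Predict Ct from a concentration (inverse of [quantify_ct()])
#' @param log10_conc log10 concentration(s).
#' @param curve a `standard_curve`.
#' @return predicted Ct value(s).
#' @export
predict_ct <- function(log10_conc, curve) {
  curve$slope * log10_conc + curve$intercept
}

#' Species/subspecies taxonomy of the Bifidobacterium assay panel
#'
#' The 22 targets the assay distinguishes, with subspecies nested under
#' their species where the panel resolves below species level.
#'
#' @return data frame with columns `species` and `taxon` (the full
#'   species-or-subspecies label; equal to `species` for species-level
#'   targets).
#' @export
bifidobacterium_taxonomy <- function() {
  sub <- function(sp, ss) data.frame(species = sp,
                                     taxon = paste(sp, "subsp.", ss),
                                     stringsAsFactors = FALSE)
  spp <- function(sp) data.frame(species = sp, taxon = sp,
                                 stringsAsFactors = FALSE)
  rbind(
    sub("B. animalis", "animalis"), sub("B. animalis", "lactis"),
    sub("B. longum", "longum"), sub("B. longum", "infantis"),
    sub("B. longum", "suis"),
    spp("B. breve"), spp("B. bifidum"), spp("B. gallicum"),
    spp("B. thermacidophilum"), spp("B. thermophilum"),
    spp("B. coryneforme"), spp("B. asteroides"), spp("B. adolescentis"),
    spp("B. pseudolongum"), spp("B. cuniculi"), spp("B. gallinarum"),
    spp("B. scardovii"), spp("B. pseudocatenulatum"), spp("B. angulatum"),
    spp("B. dentium"), spp("B. tsurumiense"), spp("B. catenulatum"))
}

#' Compare detected taxa to a product's label claim
#'
#' Deterministic four-verdict rule, applied in order:
#' 1. if every label is a non-specific token (e.g. "Lactic acid
#'    bacteria"), the claim is `unverifiable_label` and the detections
#'    are attached;
#' 2. each labeled subspecies must be detected exactly; a labeled
#'    species is satisfied by itself or by any of its subspecies;
#' 3. any detected taxon not covered by a label (a species label covers
#'    its subspecies) is a `mismatch`, as is any unsatisfied label;
#' 4. otherwise the claim is `consistent`, or
#'    `consistent_with_refinement` when a species-level label was
#'    satisfied only at subspecies resolution.
#'
#' Non-specific tokens mixed with specific labels are ignored for
#' satisfaction but cover any otherwise-uncovered detection (noted in
#' the detail).
#'
#' @param labeled character vector of label-claim taxa.
#' @param detected character vector of detected taxa.
#' @param taxonomy data frame as [bifidobacterium_taxonomy()] (columns
#'   `species`, `taxon`).
#' @param nonspecific_tokens labels that name no checkable taxon.
#' @return object of class `label_comparison`: list with `verdict`,
#'   `labeled`, `detected`, `notes`.
#' @export
#' @examples
#' tax <- bifidobacterium_taxonomy()
#' compare_to_label("B. longum", "B. longum subsp. longum", tax)$verdict
compare_to_label <- function(labeled, detected,
                             taxonomy = bifidobacterium_taxonomy(),
                             nonspecific_tokens = c("Lactic acid bacteria",
                                                    "Bifidus")) {
  labeled <- unique(trimws(labeled))
  detected <- unique(trimws(detected))
  vocab <- unique(c(taxonomy$taxon, taxonomy$species, nonspecific_tokens))
  bad <- setdiff(c(labeled, detected), vocab)
  if (length(bad))
    stop("unknown taxon string(s): ", paste(bad, collapse = ", "),
         "; known vocabulary: ", paste(sort(vocab), collapse = "; "),
         call. = FALSE)
  species_of <- setNames(taxonomy$species, taxonomy$taxon)
  specific <- setdiff(labeled, nonspecific_tokens)
  has_nonspecific <- length(setdiff(labeled, specific)) > 0

  mk <- function(verdict, notes = character(0)) {
    structure(list(verdict = verdict, labeled = labeled, detected = detected,
                   notes = notes), class = "label_comparison")
  }
  if (!length(specific)) {
    return(mk("unverifiable_label",
              notes = paste0("detected: ",
                             paste(sort(detected), collapse = ", "))))
  }
  # label satisfaction
  notes <- character(0)
  refined <- FALSE
  unsat <- character(0)
  for (lb in specific) {
    if (lb %in% setdiff(taxonomy$taxon, taxonomy$species) ||
        !(lb %in% taxonomy$species)) {
      # subspecies-level (or species with no subdivisions listed as taxon)
      if (!(lb %in% detected)) unsat <- c(unsat, lb)
    } else {
      # species-level label: itself or any subspecies
      subs <- taxonomy$taxon[taxonomy$species == lb]
      hit_exact <- lb %in% detected
      hit_sub <- any(setdiff(subs, lb) %in% detected)
      if (!hit_exact && !hit_sub) unsat <- c(unsat, lb)
      if (!hit_exact && hit_sub) refined <- TRUE
    }
  }
  # detection coverage
  covered <- vapply(detected, function(d) {
    d %in% specific || unname(species_of[d]) %in% specific
  }, logical(1))
  uncovered <- detected[!covered]
  if (length(uncovered) && has_nonspecific) {
    notes <- c(notes, paste0("covered by non-specific label: ",
                             paste(sort(uncovered), collapse = ", ")))
    uncovered <- character(0)
  }
  if (length(unsat) || length(uncovered)) {
    if (length(unsat))
      notes <- c(notes, paste0("labeled but not detected: ",
                               paste(sort(unsat), collapse = ", ")))
    if (length(uncovered))
      notes <- c(notes, paste0("detected but not labeled: ",
                               paste(sort(uncovered), collapse = ", ")))
    return(mk("mismatch", notes))
  }
  if (refined)
    notes <- c(notes, "species-level label resolved to subspecies")
  mk(if (refined) "consistent_with_refinement" else "consistent", notes)
}

#' @export
print.label_comparison <- function(x, ...) {
  cat(sprintf("label claim {%s} vs detected {%s}: %s\n",
              paste(x$labeled, collapse = ", "),
              paste(x$detected, collapse = ", "), x$verdict))
  for (n in x$notes) cat("  - ", n, "\n", sep = "")
  invisible(x)
}
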