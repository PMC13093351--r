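#' Minor allele frequency filter
#'
#' Retains a locus iff its overall minor-allele frequency, computed from
#' called alleles only (missing entries excluded from the denominator), is
#' at least \code{threshold}.
#'
#' @param g a \linkS4class{GenotypeExperiment}
#' @param threshold MAF threshold in (0, 0.5]; default 0.05
#' @return the filtered \linkS4class{GenotypeExperiment}; the per-locus
#'   report (locus, maf, kept) is attached as \code{attr(, "report")}
#' @export
mafFilter <- function(g, threshold = 0.05) {
  stopifnot(threshold > 0, threshold <= 0.5)
  d <- dosage(g)
  called <- 2 * rowSums(!is.na(d))
  altFreq <- rowSums(d, na.rm = TRUE) / called
  maf <- pmin(altFreq, 1 - altFreq)
  keep <- !is.na(maf) & maf >= threshold
  report <- data.frame(locus = rownames(d), maf = maf, kept = keep,
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- g[keep, ]
  out <- as(out, "GenotypeExperiment")
  attr(out, "report") <- report
  out
}

## Per-area ALT allele frequencies: loci x areas matrix from called
## alleles only.  Errors on an area with zero individuals.
areaAltFreq <- function(g) {
  d <- dosage(g)
  area <- colData(g)$area_id
  areas <- sort(unique(area))
  if (length(areas) < 2) stop("at least 2 sampling areas are required")
  freq <- vapply(areas, function(a) {
    cols <- which(area == a)
    if (length(cols) == 0) stop("area ", a, " has zero individuals")
    sub <- d[, cols, drop = FALSE]
    rowSums(sub, na.rm = TRUE) / (2 * rowSums(!is.na(sub)))
  }, numeric(nrow(d)))
  colnames(freq) <- as.character(areas)
  freq
}

#' Locally common alleles per sampling area
#'
#' Counts, for each sampling area, the alleles whose frequency is at least
#' \code{threshold} (default 5\%) in that area and below it in every other
#' area.  Both the REF and the ALT allele of each locus are eligible.
#'
#' @param g a \linkS4class{GenotypeExperiment} with >= 2 areas
#' @param threshold local-commonness frequency threshold
#' @return data.frame: \code{area_id}, \code{locally_common}
#' @export
locallyCommonAlleles <- function(g, threshold = 0.05) {
  freqAlt <- areaAltFreq(g)
  counts <- integer(ncol(freqAlt))
  for (f in list(freqAlt, 1 - freqAlt)) {          # ALT then REF alleles
    hot <- !is.na(f) & f >= threshold
    one <- rowSums(hot, na.rm = TRUE) == 1L
    if (any(one))
      counts <- counts + colSums(hot[one, , drop = FALSE])
  }
  data.frame(area_id = as.integer(colnames(freqAlt)),
             locally_common = as.integer(counts))
}

#' Private alleles per sampling area
#'
#' Counts, for each area, the alleles observed (any frequency > 0) in that
#' area and in no other — presence/absence, with no frequency floor.
#'
#' @param g a \linkS4class{GenotypeExperiment} with >= 2 areas
#' @return data.frame: \code{area_id}, \code{private}
#' @export
privateAlleles <- function(g) {
  freqAlt <- areaAltFreq(g)
  counts <- integer(ncol(freqAlt))
  for (f in list(freqAlt, 1 - freqAlt)) {
    seen <- !is.na(f) & f > 0
    one <- rowSums(seen, na.rm = TRUE) == 1L
    if (any(one))
      counts <- counts + colSums(seen[one, , drop = FALSE])
  }
  data.frame(area_id = as.integer(colnames(freqAlt)),
             private = as.integer(counts))
}
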