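#' Read genotypes from VCF or dosage CSV
#'
#' VCF input keeps biallelic records only: multi-allelic or malformed
#' records are skipped and listed in the rejection report attached as
#' \code{attr(, "rejected")} (the run continues).  Dosage is the count of
#' the ALT allele from the GT field; \code{./.} becomes NA.  Dosage CSV
#' input is an individuals x loci table whose first column holds
#' individual ids.
#'
#' @param path file path
#' @param format \code{"vcf"} or \code{"dosage_csv"}
#' @param sampleInfo per-individual metadata data.frame with a
#'   \code{tree_id} (or rowname) key matching the file's sample ids, and
#'   \code{site_id}/\code{area_id} columns
#' @return a \linkS4class{GenotypeExperiment}
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage_csv"),
                          sampleInfo) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    alt <- fix[, "ALT"]; ref <- fix[, "REF"]
    ok <- !is.na(alt) & !grepl(",", alt) & nchar(ref) >= 1 & nzchar(alt)
    rejected <- data.frame(
      locus = paste0(fix[, "CHROM"], ":", fix[, "POS"]),
      reason = ifelse(grepl(",", alt), "multi-allelic", "malformed"),
      stringsAsFactors = FALSE)[!ok, , drop = FALSE]
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[ok, , drop = FALSE]
    ids <- fix[ok, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[ok, "CHROM"], ":", fix[ok, "POS"])[noid]
    cleaned <- gsub("\\|", "/", gt)
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = list(ids, colnames(gt)))
    dos[cleaned == "0/0"] <- 0L
    dos[cleaned %in% c("0/1", "1/0")] <- 1L
    dos[cleaned == "1/1"] <- 2L
    si <- resolveSamples(sampleInfo, colnames(dos))
    g <- GenotypeExperiment(dos, sampleInfo = si)
    attr(g, "rejected") <- rejected
    g
  } else {
    tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    mode(m) <- "integer"
    rownames(m) <- ids
    si <- resolveSamples(sampleInfo, ids)
    GenotypeExperiment(t(m), sampleInfo = si)
  }
}

resolveSamples <- function(sampleInfo, ids) {
  key <- if ("tree_id" %in% colnames(sampleInfo)) sampleInfo$tree_id
         else rownames(sampleInfo)
  idx <- match(ids, key)
  if (anyNA(idx))
    stop("sample id(s) not resolvable against metadata: ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "))
  si <- sampleInfo[idx, , drop = FALSE]
  rownames(si) <- ids
  si
}

#' Write genotypes as dosage CSV and/or minimal VCF
#'
#' The VCF writer emits a GT-only biallelic VCF on a single synthetic
#' contig with consecutive positions (dosage 1 becomes \code{0/1}, NA
#' becomes \code{./.}); the CSV writer emits the individuals x loci dosage
#' table with individual ids in the first column.
#'
#' @param g a \linkS4class{GenotypeExperiment}
#' @param path output file path
#' @param format \code{"dosage_csv"} or \code{"vcf"}
#' @return \code{path}, invisibly
#' @export
writeGenotypes <- function(g, path, format = c("dosage_csv", "vcf")) {
  format <- match.arg(format)
  d <- dosage(g)
  if (format == "dosage_csv") {
    out <- data.frame(tree_id = colnames(d), t(d), check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    lines <- c("##fileformat=VCFv4.2",
               "##contig=<ID=synth1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(d)),
                     collapse = "\t"))
    body <- vapply(seq_len(nrow(d)), function(i) {
      gt <- gtmap[as.character(d[i, ])]
      gt[is.na(gt)] <- "./."
      paste(c("synth1", i, rownames(d)[i], "A", "T", ".", "PASS", ".",
              "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}
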