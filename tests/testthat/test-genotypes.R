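smallGeno <- function(n = 6, L = 8, seed = 3, missing = 0) {
  set.seed(seed)
  dos <- matrix(rbinom(L * n, 2, 0.4), L, n)
  if (missing > 0) dos[runif(length(dos)) < missing] <- NA
  rownames(dos) <- sprintf("snp%05d", 1:L)
  si <- data.frame(tree_id = sprintf("tree%03d", 1:n),
                   site_id = rep(1:2, length.out = n),
                   area_id = rep(1:2, length.out = n))
  GenotypeExperiment(dos, sampleInfo = si)
}

test_that("dosage CSV and VCF round-trip the genotype matrix", {
  g <- smallGeno(missing = 0.1)
  si <- as.data.frame(sampleInfo(g))
  for (fmt in c("dosage_csv", "vcf")) {
    p <- tempfile(fileext = if (fmt == "vcf") ".vcf" else ".csv")
    writeGenotypes(g, p, format = fmt)
    g2 <- readGenotypes(p, format = if (fmt == "vcf") "vcf" else "dosage_csv",
                        sampleInfo = si)
    expect_equal(unname(dosage(g2)), unname(dosage(g)),
                 info = fmt)
  }
})

test_that("VCF reading keeps biallelic records and reports rejects", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
           paste("chr1", 100, "rs1", "A", "T", ".", "PASS", ".", "GT",
                 "0/0", "0/1", "1/1", sep = "\t"),
           paste("chr1", 200, "rs2", "G", "C,A", ".", "PASS", ".", "GT",
                 "0/1", "0/2", "1/1", sep = "\t"),
           paste("chr1", 300, "rs3", "C", "G", ".", "PASS", ".", "GT",
                 "./.", "0|1", "1/1", sep = "\t"))
  p <- tempfile(fileext = ".vcf")
  writeLines(vcf, p)
  si <- data.frame(tree_id = c("s1", "s2", "s3"), site_id = 1:3,
                   area_id = c(1, 1, 2))
  g <- readGenotypes(p, "vcf", sampleInfo = si)
  dos <- dosage(g)
  expect_equal(dim(dos), c(2, 3))           # multi-allelic rs2 dropped
  expect_equal(unname(dos["rs1", ]), c(0L, 1L, 2L))
  expect_equal(unname(dos["rs3", ]), c(NA_integer_, 1L, 2L))
  rej <- attr(g, "rejected")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "multi-allelic")
  ## unresolvable sample ids are an error
  expect_error(readGenotypes(p, "vcf",
                             sampleInfo = data.frame(tree_id = "sX",
                                                     site_id = 1,
                                                     area_id = 1)),
               "not resolvable")
})

test_that("MAF filtering matches brute-force allele frequencies", {
  ## locus at exactly the 5% boundary is retained; just below is removed
  dos <- rbind(c(1L, rep(0L, 9)),              # 1/20 alleles = 0.05
               rep(0L, 10),                    # monomorphic
               rep(1L, 10),                    # freq 0.5
               c(2L, rep(0L, 9)))              # 2/20 = 0.10
  rownames(dos) <- paste0("snp", 1:4)
  si <- data.frame(tree_id = paste0("t", 1:10), site_id = 1, area_id = 1)
  g <- GenotypeExperiment(dos, si)
  kept <- mafFilter(g, 0.05)
  expect_setequal(rownames(dosage(kept)), c("snp1", "snp3", "snp4"))
  rep05 <- attr(kept, "report")
  expect_equal(rep05$maf, c(0.05, 0, 0.5, 0.1))

  ## one extra individual drops the boundary locus below threshold
  dos2 <- cbind(dos, c(0L, 0L, 1L, 0L))
  si2 <- rbind(si, data.frame(tree_id = "t11", site_id = 1, area_id = 1))
  g2 <- GenotypeExperiment(dos2, si2)
  expect_false("snp1" %in% rownames(dosage(mafFilter(g2, 0.05))))

  ## brute force over random matrices with missingness
  set.seed(5)
  for (rep in 1:5) {
    g3 <- smallGeno(n = 12, L = 20, seed = rep, missing = 0.1)
    dos3 <- dosage(g3)
    maf <- apply(dos3, 1, function(x) {
      x <- x[!is.na(x)]
      f <- sum(x) / (2 * length(x))
      min(f, 1 - f)
    })
    got <- mafFilter(g3, 0.1)
    expect_setequal(rownames(dosage(got)),
                    rownames(dos3)[!is.na(maf) & maf >= 0.1])
  }
})

test_that("locally common and private alleles match exhaustive enumeration", {
  ## definitional cases: 3 areas x hand-placed alleles
  dos <- rbind(
    c(1L, 1L, 0L, 0L, 0L, 0L),    # ALT at 33% in area 1 only
    c(1L, 0L, 1L, 0L, 0L, 0L),    # ALT common in areas 1 and 2
    c(0L, 0L, 0L, 0L, 0L, 1L))    # singleton ALT in area 3
  rownames(dos) <- paste0("s", 1:3)
  si <- data.frame(tree_id = paste0("t", 1:6),
                   site_id = rep(1:3, each = 2),
                   area_id = rep(1:3, each = 2))
  g <- GenotypeExperiment(dos, si)
  lc <- locallyCommonAlleles(g)
  pr <- privateAlleles(g)
  oc <- oracleAlleleCounts(dos, si$area_id)
  expect_equal(lc$locally_common, unname(as.integer(oc$locally_common)))
  expect_equal(pr$private, unname(as.integer(oc$private)))
  ## allele common in one area only counts there; in two areas, nowhere
  expect_true(lc$locally_common[1] >= 1)
  expect_true(pr$private[3] >= 1)

  ## random fixtures against the oracle, and ordering invariance
  for (rep in 1:4) {
    g4 <- smallGeno(n = 12, L = 15, seed = 20 + rep, missing = 0.05)
    si4 <- as.data.frame(sampleInfo(g4))
    si4$area_id <- rep(1:3, each = 4)
    g4 <- GenotypeExperiment(dosage(g4), si4)
    oc4 <- oracleAlleleCounts(dosage(g4), si4$area_id)
    expect_equal(locallyCommonAlleles(g4)$locally_common,
                 unname(as.integer(oc4$locally_common)))
    expect_equal(privateAlleles(g4)$private,
                 unname(as.integer(oc4$private)))
    perm <- sample(ncol(dosage(g4)))
    permL <- sample(nrow(dosage(g4)))
    gp <- GenotypeExperiment(dosage(g4)[permL, perm], si4[perm, ])
    expect_equal(locallyCommonAlleles(gp), locallyCommonAlleles(g4))
    expect_equal(privateAlleles(gp), privateAlleles(g4))
  }
})

test_that("area statistics refuse degenerate inputs", {
  g <- smallGeno()
  si <- as.data.frame(sampleInfo(g))
  si$area_id <- 1
  g1 <- GenotypeExperiment(dosage(g), si)
  expect_error(locallyCommonAlleles(g1), "2 sampling areas")
})
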