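#' Per-locus association results with genomic-inflation calibration
#'
#' Matrices of z-scores and raw/calibrated p-values (loci x variables)
#' from latent-factor-adjusted regressions, plus the per-variable genomic
#' inflation factor (GIF) used for calibration.
#'
#' @slot z,p,pCalibrated numeric matrices, loci x variables.
#' @slot gif named numeric, per-variable genomic inflation factor.
#' @slot df residual degrees of freedom of the per-locus regressions.
#' @export
setClass("AssociationResult",
  representation(z = "matrix", p = "matrix", pCalibrated = "matrix",
                 gif = "numeric", df = "numeric"))

setValidity("AssociationResult", function(object) {
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
    return("p-values must lie in [0, 1]")
  if (any(object@gif <= 0)) return("GIF must be > 0")
  TRUE
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult: %d loci x %d variable(s)\n",
              nrow(object@z), ncol(object@z)))
  cat("  GIF:", paste(sprintf("%s=%.3f", names(object@gif), object@gif),
                      collapse = ", "), "\n")
})

## Scaled climate matrix from table or matrix input.
asEnvMatrix <- function(E) {
  if (is.data.frame(E))
    E <- as.matrix(E[vapply(E, is.numeric, logical(1))])
  stopifnot(is.numeric(E))
  E
}

#' Fit the ridge latent-factor model of genotypes on climate
#'
#' Estimates the decomposition \eqn{Y = E B + U V^T + \epsilon} for a
#' mean-imputed, column-centered dosage matrix \eqn{Y} (individuals x
#' loci) and scaled climate matrix \eqn{E}, under a ridge penalty
#' \eqn{\lambda} on B.  The latent factors come from the shrink-reinflate
#' SVD solution: the sample directions spanned by E are shrunk by
#' \eqn{\sqrt{\lambda/(\lambda + \sigma_i^2)}} (\eqn{\sigma_i} the
#' singular values of E), the top-K SVD of the shrunk matrix is taken,
#' and the truncated reconstruction is re-inflated, so that \eqn{U}
#' retains population structure even where it is collinear with climate
#' (removing the E directions outright would push the shared
#' structure into B and leave the tests confounded).  B is then the ridge
#' regression of \eqn{Y - U V^T} on E.  Factor signs follow a fixed
#' convention (the largest-magnitude score of each factor is positive) so
#' repeated fits are bitwise identical.  \code{K = 0} degenerates to
#' plain multivariate ridge regression.
#'
#' @param g a \linkS4class{GenotypeExperiment} (or an individuals x loci
#'   dosage matrix)
#' @param E scaled climate table or matrix, individuals x variables
#' @param K number of latent factors (0 <= K < min(n, L))
#' @param lambda ridge penalty (default 1e-5: numerical stabilization
#'   with negligible shrinkage)
#' @return a \linkS4class{LatentFactorModel}
#' @export
fitLatentModel <- function(g, E, K = 3, lambda = 1e-5) {
  Y <- if (is(g, "GenotypeExperiment")) t(dosage(g)) else as.matrix(g)
  loci <- colnames(Y)
  if (is.null(loci)) loci <- sprintf("snp%05d", seq_len(ncol(Y)))
  Y <- imputeDosage(Y, center = TRUE)
  X <- asEnvMatrix(E)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(Y); L <- ncol(Y); d <- ncol(X)
  if (K >= min(n, L)) stop("K must be < min(individuals, loci)")
  XtXl <- crossprod(X) + diag(lambda, d)
  ridge <- function(Ymat) solve(XtXl, crossprod(X, Ymat))
  if (K > 0) {
    svX <- svd(X)
    shr <- sqrt(lambda / (lambda + svX$d^2))
    Qx <- svX$u
    PY <- Y - Qx %*% ((1 - shr) * crossprod(Qx, Y))
    sv <- topSVD(PY, K)
    W <- sv$u %*% (sv$d * t(sv$v))
    W <- W + Qx %*% ((1 / shr - 1) * crossprod(Qx, W))   # re-inflate
    V <- sv$v
    U <- W %*% V
    sg <- fixSigns(U, V)
    U <- sg$u; V <- sg$v
    B <- ridge(Y - tcrossprod(U, V))
  } else {
    U <- matrix(0, n, 0); V <- matrix(0, L, 0)
    B <- ridge(Y)
  }
  vn <- colnames(X)
  if (is.null(vn)) vn <- sprintf("E%d", seq_len(d))
  new("LatentFactorModel", K = as.integer(K), U = U, V = V, B = B,
      lambda = lambda, variables = vn, loci = loci)
}

setMethod("show", "LatentFactorModel", function(object) {
  cat(sprintf("LatentFactorModel: K = %d | %d variable(s) x %d loci | lambda = %g\n",
              object@K, nrow(object@B), ncol(object@B), object@lambda))
})

#' Latent-factor-adjusted genotype-environment association tests
#'
#' Regresses each locus's (mean-imputed, centered) dosage on the scaled
#' climate variables with the latent factor scores as covariates; per
#' locus x variable t statistics are mapped to z-scores, the per-variable
#' genomic inflation factor \eqn{GIF = median(z^2) / \chi^2_{0.5}(1)} is
#' estimated, and calibrated p-values are \eqn{P(\chi^2_1 > z^2 / GIF)}.
#'
#' @param g a \linkS4class{GenotypeExperiment} or dosage matrix
#'   (individuals x loci)
#' @param E scaled climate matrix, individuals x variables
#' @param U latent factor scores (individuals x K), e.g.
#'   \code{model@U}; may have zero columns
#' @return an \linkS4class{AssociationResult}
#' @export
associationTest <- function(g, E, U) {
  Y <- if (is(g, "GenotypeExperiment")) t(dosage(g)) else as.matrix(g)
  loci <- colnames(Y)
  Y <- imputeDosage(Y, center = TRUE)
  X <- asEnvMatrix(E)
  d <- ncol(X)
  vn <- colnames(X)
  if (is.null(vn)) vn <- sprintf("E%d", seq_len(d))
  M <- cbind(`(Intercept)` = 1, X, U)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[seq(qrM$rank + 1, ncol(M))]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(M); df <- n - ncol(M)
  MtMi <- chol2inv(chol(crossprod(M)))
  coefs <- MtMi %*% crossprod(M, Y)
  res <- Y - M %*% coefs
  sigma2 <- colSums(res^2) / df
  envIdx <- 1 + seq_len(d)
  z <- matrix(NA_real_, ncol(Y), d, dimnames = list(loci, vn))
  p <- z
  for (j in seq_len(d)) {
    se <- sqrt(MtMi[envIdx[j], envIdx[j]] * sigma2)
    tstat <- coefs[envIdx[j], ] / se
    pj <- 2 * pt(-abs(tstat), df)
    z[, j] <- sign(tstat) * qnorm(pmax(pj / 2, 1e-300), lower.tail = FALSE)
    p[, j] <- pj
  }
  gif <- apply(z, 2, function(zz) median(zz^2, na.rm = TRUE)) /
    qchisq(0.5, 1)
  pc <- vapply(seq_len(d), function(j)
    pchisq(z[, j]^2 / gif[j], 1, lower.tail = FALSE),
    numeric(nrow(z)))
  dimnames(pc) <- dimnames(z)
  new("AssociationResult", z = z, p = p, pCalibrated = pc,
      gif = setNames(gif, vn), df = df)
}

#' Benjamini-Hochberg selection
#'
#' Step-up FDR selection at level \code{q}: the loci whose BH-adjusted
#' p-value is at most \code{q}.  Ties at the boundary p-value are all
#' included (adjusted p-values of tied raw p-values are equal).
#'
#' @param p numeric vector of p-values in [0, 1]
#' @param q FDR level (default 0.01)
#' @return integer indices of the selected entries
#' @export
bhSelect <- function(p, q = 0.01) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  which(p.adjust(p, method = "BH") <= q)
}

#' Merge candidate-locus sets with provenance
#'
#' Set union of a prior candidate list and a supplemental list; loci in
#' both keep the \code{"prior-list"} tag.
#'
#' @param prior,supplemental character vectors of locus ids, or
#'   data.frames with columns \code{locus} and \code{provenance}
#' @param validLoci optional universe of known locus ids; unknown ids
#'   raise an error
#' @return data.frame: \code{locus}, \code{provenance}
#' @export
mergeCandidates <- function(prior, supplemental, validLoci = NULL) {
  asSet <- function(x, tag) {
    if (is.data.frame(x)) data.frame(locus = as.character(x$locus),
                                     provenance = x$provenance,
                                     stringsAsFactors = FALSE)
    else data.frame(locus = as.character(x),
                    provenance = rep(tag, length(x)),
                    stringsAsFactors = FALSE)
  }
  pri <- asSet(prior, "prior-list")
  sup <- asSet(supplemental, "supplemental")
  if (!is.null(validLoci)) {
    unk <- setdiff(c(pri$locus, sup$locus), validLoci)
    if (length(unk))
      stop("unknown locus id(s): ", paste(head(unk, 5), collapse = ", "))
  }
  out <- rbind(pri, sup[!sup$locus %in% pri$locus, , drop = FALSE])
  stopifnot(!anyDuplicated(out$locus))
  rownames(out) <- NULL
  out
}

#' Choose the number of latent factors by held-out imputation
#'
#' Masks a fraction of the (observed) dosage entries and, for each
#' candidate K, fits the module's latent model \eqn{Y \approx E B + U V^T}
#' on the remaining entries by a few EM passes (masked cells are
#' re-imputed from the current reconstruction); the K minimizing held-out
#' RMSE is returned, ties breaking to the smallest K.  The fit is on the
#' \emph{uncentered} dosage matrix, so one factor is spent on the overall
#' allele-frequency profile: with \code{kPops} discrete ancestral pools
#' the expected dosage matrix has rank \code{kPops}, and the selector
#' recovers the generating pool count.  Because the climate term absorbs
#' environment-driven variance at every K, planted adaptive loci do not
#' inflate the choice; without \code{E} the selector measures total
#' structure instead.
#'
#' @param g a \linkS4class{GenotypeExperiment} or dosage matrix
#'   (individuals x loci)
#' @param E optional scaled climate matrix (individuals x variables)
#'   conditioned on during selection
#' @param KGrid candidate K values (default 1:8)
#' @param maskFraction fraction of entries held out (default 0.05)
#' @param seed integer seed for the mask
#' @param nIter EM passes per K (default 5)
#' @param lambda ridge penalty for the climate term
#' @return the chosen K (integer); the per-K RMSE profile is attached as
#'   \code{attr(, "rmse")}
#' @export
selectK <- function(g, E = NULL, KGrid = 1:8, maskFraction = 0.05,
                    seed = 1, nIter = 5, lambda = 1e-5) {
  stopifnot(length(KGrid) >= 1)
  Y <- if (is(g, "GenotypeExperiment")) t(dosage(g)) else as.matrix(g)
  Y <- imputeDosage(Y, center = FALSE)
  X <- if (!is.null(E)) asEnvMatrix(E) else NULL
  ridge <- if (!is.null(X))
    solve(crossprod(X) + diag(lambda, ncol(X)), t(X))
  withSeed(seed, {
    idx <- which(runif(length(Y)) < maskFraction)
    truth <- Y[idx]
    colMu <- colMeans(Y)
    rmse <- vapply(sort(unique(as.integer(KGrid))), function(K) {
      Z <- Y
      Z[idx] <- colMu[(idx - 1) %/% nrow(Y) + 1]
      for (it in seq_len(nIter)) {
        if (is.null(X)) {
          sv <- topSVD(Z, K)
          recon <- sv$u %*% (sv$d * t(sv$v))
        } else {
          B <- ridge %*% Z
          fitE <- X %*% B
          sv <- topSVD(Z - fitE, K)
          recon <- fitE + sv$u %*% (sv$d * t(sv$v))
        }
        Z[idx] <- recon[idx]
      }
      sqrt(mean((Z[idx] - truth)^2))
    }, numeric(1))
    grid <- sort(unique(as.integer(KGrid)))
    K <- grid[which.min(rmse)]
    attr(K, "rmse") <- setNames(rmse, grid)
    K
  })
}
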