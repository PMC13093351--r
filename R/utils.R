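## Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Great-circle distance between points
#'
#' Haversine distance in kilometers (sphere radius 6378.137 km, matching
#' the displacement convention used by the design generator).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees
#' @return numeric vector of distances in km
#' @export
greatCircleKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

## Top-K singular triplets of an n x L matrix via the smaller Gram matrix.
topSVD <- function(Y, K) {
  n <- nrow(Y); L <- ncol(Y)
  K <- min(K, n, L)
  if (n <= L) {
    G <- tcrossprod(Y)                 # n x n
    eg <- eigen(G, symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(K)], 0)
    d <- sqrt(d2)
    u <- eg$vectors[, seq_len(K), drop = FALSE]
    v <- crossprod(Y, u)
    v <- sweep(v, 2, ifelse(d > 1e-12, d, 1), "/")
  } else {
    G <- crossprod(Y)                  # L x L
    eg <- eigen(G, symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(K)], 0)
    d <- sqrt(d2)
    v <- eg$vectors[, seq_len(K), drop = FALSE]
    u <- Y %*% v
    u <- sweep(u, 2, ifelse(d > 1e-12, d, 1), "/")
  }
  list(u = u, d = d, v = v)
}

## Mean-impute missing dosages per locus and optionally center columns.
## Y is individuals x loci.
imputeDosage <- function(Y, center = FALSE) {
  cm <- colMeans(Y, na.rm = TRUE)
  idx <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(idx)) Y[idx] <- cm[idx[, 2]]
  if (center) Y <- sweep(Y, 2, colMeans(Y), "-")
  Y
}

## Deterministic SVD sign convention: per factor, the largest-magnitude
## score is made positive (U flips carry over to V).
fixSigns <- function(u, v) {
  for (k in seq_len(ncol(u))) {
    j <- which.max(abs(u[, k]))
    if (u[j, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  list(u = u, v = v)
}
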