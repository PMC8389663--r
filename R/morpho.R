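#' Preprocess a measurement table
#'
#' Applies the standard morphometric preprocessing sequence: specimens
#' with more than 50% missing measurements are excluded first, remaining
#' missing values are imputed with the per-variable mean of observed
#' values, and variables are then centred and scaled to unit variance.
#'
#' @param table Numeric matrix or data frame (rows = specimens, columns =
#'   measured variables, `NA` = missing).
#' @return List with `scaled` (the centred, unit-variance matrix),
#'   `imputed` (pre-scaling), `excluded` (row labels removed).
#' @export
preprocessMeasurements <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 specimens")
  missFrac <- rowMeans(is.na(m))
  excluded <- rownames(m)[missFrac > 0.5]
  m <- m[missFrac <= 0.5, , drop = FALSE]
  emptyVar <- colSums(!is.na(m)) == 0L
  if (any(emptyVar))
    stop("variable(s) with no observed values: ",
         paste(colnames(m)[emptyVar], collapse = ", "))
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j], na.rm = TRUE)
    m[is.na(m[, j]), j] <- mu
  }
  sds <- apply(m, 2L, sd)
  if (any(sds == 0))
    warning("constant variable(s) left unscaled: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  sds[sds == 0] <- 1
  scaled <- scale(m, center = TRUE, scale = sds)
  list(scaled = scaled[, , drop = FALSE], imputed = m, excluded = excluded)
}

#' Principal component analysis
#'
#' Eigendecomposition of the covariance of an (already scaled) data
#' matrix. With all axes retained, scores reproduce the pairwise
#' Euclidean geometry of the inputs and `scores %*% t(loadings)`
#' reconstructs the centred matrix.
#'
#' @param x Numeric matrix, rows = observations; no missing values.
#' @return List `scores`, `loadings` (orthonormal columns), `varfrac`
#'   (per-axis variance fractions, non-increasing), `center`.
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  if (anyNA(x)) stop("missing values not allowed; preprocess first")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  if (all(abs(xc) < 1e-300)) stop("rank-0 matrix")
  s <- svd(xc)
  keep <- s$d > max(s$d) * 1e-12
  ev <- s$d[keep]^2
  list(scores = s$u[, keep, drop = FALSE] %*% diag(s$d[keep],
                                                   nrow = sum(keep)),
       loadings = s$v[, keep, drop = FALSE],
       varfrac = ev / sum(s$d^2), center = ctr)
}

centroidSize <- function(cfg) {
  ctd <- sweep(cfg, 2L, colMeans(cfg))
  sqrt(sum(ctd^2))
}

# least-squares rotation of X onto Y (reflections disallowed)
optimalRotation <- function(X, Y) {
  M <- crossprod(X, Y)                  # 2x2
  s <- svd(M)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, d)) %*% t(s$v)      # X %*% R aligns X to Y
}

#' Generalized Procrustes analysis
#'
#' Full Procrustes superimposition under the least-squares criterion:
#' each configuration is centred and scaled to unit centroid size, then
#' iteratively rotated to the current mean shape (optimal rotation from
#' the cross-covariance decomposition, reflections disallowed) with the
#' mean re-estimated until it changes by less than `tol` or `max_iter`
#' iterations.
#'
#' @param dataset A [ShapeDataset-class].
#' @param tol Convergence tolerance on the mean (default 1e-10).
#' @param max_iter Maximum iterations (default 100).
#' @return The dataset with `aligned` coordinates and `centroidSizes`
#'   filled in.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  coords <- dataset@coords
  k <- dim(coords)[1L]; n <- dim(coords)[3L]
  if (n < 2L) stop("need at least 2 configurations")
  cs <- numeric(n)
  al <- array(NA_real_, dim(coords))
  for (i in seq_len(n)) {
    cfg <- coords[, , i]
    cfg <- sweep(cfg, 2L, colMeans(cfg))
    cs[[i]] <- sqrt(sum(cfg^2))
    if (cs[[i]] < 1e-12)
      stop("degenerate configuration (all landmarks coincident): ",
           dataset@ids[[i]])
    al[, , i] <- cfg / cs[[i]]
  }
  meanShape <- al[, , 1L]
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n))
      al[, , i] <- al[, , i] %*% optimalRotation(al[, , i], meanShape)
    newMean <- apply(al, c(1L, 2L), mean)
    newMean <- newMean - matrix(colMeans(newMean), k, 2L, byrow = TRUE)
    newMean <- newMean / sqrt(sum(newMean^2))
    delta <- sqrt(sum((newMean - meanShape)^2))
    meanShape <- newMean
    if (delta < tol) break
  }
  dataset@aligned <- al
  dataset@centroidSizes <- cs
  dataset
}

#' Procrustes mean shape of a superimposed dataset
#'
#' @param dataset A [ShapeDataset-class] after [gpa()].
#' @return `k x 2` matrix with unit centroid size, centroid at origin.
#' @export
meanShape <- function(dataset) {
  m <- apply(alignedCoords(dataset), c(1L, 2L), mean)
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

#' Procrustes distance between two superimposed configurations
#'
#' @param a,b `k x 2` aligned coordinate matrices.
#' @return Square root of the summed squared landmark differences.
#' @export
procrustesDistance <- function(a, b) sqrt(sum((a - b)^2))

# thin-plate-spline bending energy matrix of a 2-D reference (k x k)
bendingEnergyMatrix <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 == 0, 0, d2 * log(d2))  # U(r) = r^2 log r^2 (scale-free)
  Q <- cbind(1, ref)
  Lmat <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Linv <- solve(Lmat)
  Be <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  (Be + t(Be)) / 2
}

stackCoords <- function(cfg) as.vector(t(cfg))   # (x1,y1,x2,y2,...)

bendingEnergyOf <- function(cfg, ref, Be) {
  v <- stackCoords(cfg - ref)
  E2 <- kronecker(Be, diag(2))
  drop(t(v) %*% E2 %*% v)
}

#' Slide semilandmarks by bending-energy minimisation
#'
#' Each semilandmark slides along its local curve tangent (estimated from
#' its neighbouring landmarks) so as to minimise the thin-plate-spline
#' bending energy of the deformation from the reference shape (the
#' Procrustes mean unless supplied). Fixed landmarks do not move in the
#' sliding step. With `resuperimpose = TRUE` the slide is alternated with
#' re-superimposition and iterated until the total bending energy changes
#' by less than `tol` (relative) or `max_iter` cycles.
#'
#' @param dataset A [ShapeDataset-class] after [gpa()], with at least one
#'   `"semi"` role.
#' @param reference Optional `k x 2` reference shape.
#' @param resuperimpose Alternate sliding with GPA (default `TRUE`).
#' @param max_iter Maximum slide cycles (default 5).
#' @param tol Relative bending-energy convergence tolerance (1e-8).
#' @return The dataset with slid, superimposed coordinates; attribute
#'   `"bending_energy"` holds the per-cycle total bending energy (after
#'   each slide step), a non-increasing sequence within each cycle's
#'   minimisation.
#' @export
slideSemilandmarks <- function(dataset, reference = NULL,
                               resuperimpose = TRUE, max_iter = 5L,
                               tol = 1e-8) {
  semis <- which(dataset@roles == "semi")
  if (length(semis) == 0L) stop("no semilandmarks in dataset")
  al <- alignedCoords(dataset)
  k <- dim(al)[1L]; n <- dim(al)[3L]
  ref <- if (is.null(reference)) meanShape(dataset) else reference
  Be <- bendingEnergyMatrix(ref)
  E2 <- kronecker(Be, diag(2))
  energyTrace <- numeric(0)
  totalEnergy <- function(arr) {
    sum(vapply(seq_len(n), function(i) {
      v <- stackCoords(arr[, , i] - ref)
      drop(t(v) %*% E2 %*% v)
    }, numeric(1)))
  }
  ePrev <- totalEnergy(al)
  for (cycle in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      cfg <- al[, , i]
      # tangent directions from neighbours in landmark order
      Tm <- matrix(0, 2L * k, length(semis))
      for (ci in seq_along(semis)) {
        j <- semis[[ci]]
        lo <- if (j > 1L) j - 1L else j
        hi <- if (j < k) j + 1L else j
        if (lo == hi) stop("semilandmark ", j, " has no neighbours")
        tv <- cfg[hi, ] - cfg[lo, ]
        nv <- sqrt(sum(tv^2))
        if (nv < 1e-12) stop("degenerate tangent at semilandmark ", j)
        tv <- tv / nv
        Tm[2L * j - 1L, ci] <- tv[[1L]]
        Tm[2L * j, ci] <- tv[[2L]]
      }
      v <- stackCoords(cfg - ref)
      A <- crossprod(Tm, E2 %*% Tm)
      rhs <- crossprod(Tm, E2 %*% v)
      lam <- tryCatch(solve(A, -rhs), error = function(e)
        -MASS_ginv(A) %*% rhs)
      # move only the semilandmarks (fixed landmarks stay bit-identical)
      for (ci in seq_along(semis)) {
        j <- semis[[ci]]
        cfg[j, 1L] <- cfg[j, 1L] + Tm[2L * j - 1L, ci] * lam[[ci]]
        cfg[j, 2L] <- cfg[j, 2L] + Tm[2L * j, ci] * lam[[ci]]
      }
      al[, , i] <- cfg
    }
    eNow <- totalEnergy(al)
    energyTrace <- c(energyTrace, eNow)
    if (resuperimpose) {
      tmp <- dataset; tmp@coords <- al
      tmp <- gpa(tmp)
      al <- tmp@aligned
    }
    if (abs(ePrev - eNow) <= tol * max(ePrev, 1e-300)) break
    ePrev <- eNow
  }
  dataset@aligned <- al
  attr(dataset@aligned, "bending_energy") <- energyTrace
  dataset
}

# minimal pseudo-inverse (avoids importing MASS for one corner case)
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > max(s$d, 0) * tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

residualMatrix <- function(dataset) {
  al <- alignedCoords(dataset)
  n <- dim(al)[3L]
  X <- t(vapply(seq_len(n), function(i) stackCoords(al[, , i]),
                numeric(2L * dim(al)[1L])))
  sweep(X, 2L, colMeans(X))
}

#' Relative warp analysis
#'
#' Principal components of shape variation with bending-energy weighting
#' exponent `alpha`. With `alpha = 0` all partial warps receive equal
#' weight and the axes coincide with principal components of the aligned
#' Procrustes coordinates (up to axis sign). With `alpha != 0`, partial
#' warp scores are weighted by the bending-energy eigenvalues to the
#' power `-alpha/2` (positive `alpha` emphasises large-scale variation);
#' the affine (uniform) component is included unweighted when
#' `include_uniform = TRUE`.
#'
#' @param dataset A [ShapeDataset-class] after [gpa()] (>= 3 specimens).
#' @param alpha Weighting exponent (default 0).
#' @param include_uniform Include the affine subspace (default `TRUE`).
#' @return List of class `rwa`: `scores`, `alpha`, `varfrac`
#'   (non-increasing, sums to <= 1 of retained axes).
#' @export
relativeWarps <- function(dataset, alpha = 0, include_uniform = TRUE) {
  if (nSpecimens(dataset) < 3L) stop("need at least 3 specimens")
  X <- residualMatrix(dataset)
  if (alpha == 0) {
    p <- pca(X)
    return(structure(list(scores = p$scores, alpha = alpha,
                          varfrac = p$varfrac), class = "rwa"))
  }
  ref <- meanShape(dataset)
  Be <- bendingEnergyMatrix(ref)
  eg <- eigen(Be, symmetric = TRUE)
  nz <- eg$values > max(eg$values) * 1e-8
  W <- kronecker(eg$vectors[, nz, drop = FALSE], diag(2))  # partial warps
  lam <- rep(eg$values[nz], each = 2L)
  scoresPW <- X %*% W %*% diag(lam^(-alpha / 2))
  if (include_uniform) {
    U <- kronecker(eg$vectors[, !nz, drop = FALSE], diag(2))
    scoresPW <- cbind(scoresPW, X %*% U)
  }
  p <- pca(scoresPW)
  structure(list(scores = p$scores, alpha = alpha, varfrac = p$varfrac),
            class = "rwa")
}

goodallF <- function(X, groups) {
  g <- factor(groups)
  n <- nrow(X)
  grand <- colMeans(X)
  means <- rowsum(X, g) / as.vector(table(g))
  ssb <- sum(as.vector(table(g)) *
               rowSums(sweep(means, 2L, grand)^2))
  sst <- sum(sweep(X, 2L, grand)^2)
  ssw <- sst - ssb
  dfb <- nlevels(g) - 1L
  dfw <- n - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

#' Procrustes ANOVA with permutation test
#'
#' Goodall-style F statistic
#' `F = (between-group Procrustes SS/df_b) / (within-group SS/df_w)` on
#' the superimposed coordinates, with a group-label permutation p-value
#' `p = (1 + #{F* >= F}) / (1 + n_permutations)`.
#'
#' @param dataset A [ShapeDataset-class] after [gpa()].
#' @param groups Group labels (defaults to the dataset's groups).
#' @param n_permutations Number of permutations (default 10000, >= 10).
#' @param seed Integer seed.
#' @return List `F`, `p`, `df` (between, within).
#' @export
procrustesAnova <- function(dataset, groups = NULL,
                            n_permutations = 10000L, seed = 1L) {
  if (n_permutations < 10L) stop("n_permutations must be >= 10")
  if (is.null(groups)) groups <- shapeGroups(dataset)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("each group needs >= 2 members")
  X <- residualMatrix(dataset)
  Fobs <- goodallF(X, g)
  set.seed(seed)
  ge <- sum(vapply(seq_len(n_permutations), function(r)
    goodallF(X, sample(g)) >= Fobs - 1e-12, logical(1)))
  list(F = Fobs, p = (1 + ge) / (1 + n_permutations),
       df = c(between = nlevels(g) - 1L, within = nrow(X) - nlevels(g)))
}

#' Shape-size (allometry) regression with permutation test
#'
#' Multivariate regression of the superimposed coordinates on log
#' centroid size; `F = (explained SS/1) / (residual SS/(n-2))`, with a
#' permutation p-value over shuffles of the sizes.
#'
#' @param dataset A [ShapeDataset-class] after [gpa()].
#' @param n_permutations Number of permutations (default 10000, >= 10).
#' @param seed Integer seed.
#' @return List `F`, `p`, `r_squared`.
#' @export
shapeSizeRegression <- function(dataset, n_permutations = 10000L,
                                seed = 1L) {
  if (n_permutations < 10L) stop("n_permutations must be >= 10")
  cs <- centroidSizes(dataset)
  if (length(cs) == 0L) stop("run gpa() first")
  if (max(cs) - min(cs) < 1e-12 * max(cs))
    stop("constant centroid size: allometry undefined")
  z <- log(cs); z <- z - mean(z)
  X <- residualMatrix(dataset)
  n <- nrow(X)
  fstat <- function(zz) {
    proj <- crossprod(zz, X) / sqrt(sum(zz^2))    # 1 x 2k
    ssm <- sum(proj^2)
    sst <- sum(X^2)
    (ssm / 1) / ((sst - ssm) / (n - 2L))
  }
  Fobs <- fstat(z)
  set.seed(seed)
  ge <- sum(vapply(seq_len(n_permutations), function(r)
    fstat(sample(z)) >= Fobs - 1e-12, logical(1)))
  proj <- crossprod(z, X) / sqrt(sum(z^2))
  list(F = Fobs, p = (1 + ge) / (1 + n_permutations),
       r_squared = sum(proj^2) / sum(X^2))
}
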