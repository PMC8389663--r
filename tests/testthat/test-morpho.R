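test_that("measurement preprocessing excludes, imputes, then scales", {
  m <- matrix(rnorm(10 * 25), 10, 25,
              dimnames = list(paste0("sp", 1:10), paste0("v", 1:25)))
  m[1, 1:13] <- NA                       # 52% missing: excluded
  m[2, 1:12] <- NA                       # 48% missing: kept
  out <- preprocessMeasurements(m)
  expect_equal(out$excluded, "sp1")
  expect_equal(nrow(out$scaled), 9L)
  # imputed value equals the observed mean of that variable
  expect_equal(out$imputed["sp2", "v1"],
               mean(m[3:10, "v1"]))
  expect_false(anyNA(out$scaled))
  expect_equal(unname(colMeans(out$scaled)), rep(0, 25), tolerance = 1e-12)
  expect_equal(unname(apply(out$scaled, 2, sd)), rep(1, 25),
               tolerance = 1e-12)

  m2 <- m[3:10, ]; m2[, 3] <- NA
  expect_error(preprocessMeasurements(m2), "v3")

  # complete table passes through unchanged up to scaling
  m3 <- matrix(rnorm(40), 8, 5)
  out3 <- preprocessMeasurements(m3)
  expect_equal(out3$imputed, m3)
})

test_that("PCA reconstructs, conserves variance and separates clusters", {
  set.seed(140)
  x <- matrix(rnorm(30 * 6), 30, 6)
  p <- pca(x)
  expect_equal(sum(p$varfrac), 1, tolerance = 1e-12)
  expect_true(all(diff(p$varfrac) <= 1e-12))
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(p$scores %*% t(p$loadings), xc, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # pairwise distances preserved with all axes
  expect_equal(as.matrix(dist(p$scores)), as.matrix(dist(xc)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # two clusters offset along variable 3
  x2 <- matrix(rnorm(40 * 4, sd = 0.05), 40, 4)
  x2[21:40, 3] <- x2[21:40, 3] + 5
  p2 <- pca(x2)
  expect_gt(abs(p2$loadings[3, 1]), 0.99)
  expect_gt(min(abs(p2$scores[21:40, 1])), max(abs(p2$scores[1:20, 1])) - 3)

  expect_error(pca(matrix(0, 5, 3)), "rank-0")
})

test_that("GPA is invariant to similarity transforms of the inputs", {
  set.seed(141)
  ms <- circleShape(10)
  for (rep in 1:10) {
    base <- ms + matrix(rnorm(20, 0, 0.1), 10, 2)
    n <- 8
    coords <- array(NA_real_, c(10, 2, n))
    for (i in 1:n) {
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      coords[, , i] <- base %*% R * runif(1, 0.2, 5) +
        matrix(runif(2, -10, 10), 10, 2, byrow = TRUE)
    }
    al <- alignedCoords(gpa(ShapeDataset(coords)))
    expect_lt(max(abs(sweep(al, 1:2, al[, , 1]))), 1e-8)
  }
})

test_that("GPA output does not depend on specimen order", {
  ds <- simulateLandmarks(circleShape(9), list(matrix(0, 9, 2)),
                          noise_sd = 0.05, sizes = 10L, seed = 42)
  a1 <- gpa(ds)
  perm <- c(4, 1, 10, 3, 2, 9, 5, 8, 7, 6)
  ds2 <- ShapeDataset(ds@coords[, , perm], ids = ds@ids[perm])
  a2 <- gpa(ds2)
  # compare each specimen's aligned shape after removing the arbitrary
  # global rotation: optimal-rotate dataset 2's mean onto dataset 1's
  m1 <- meanShape(a1); m2 <- meanShape(a2)
  R <- svd(crossprod(m2, m1))
  rot <- R$u %*% t(R$v)
  al1 <- alignedCoords(a1); al2 <- alignedCoords(a2)
  for (i in seq_along(perm))
    expect_lt(max(abs(al2[, , i] %*% rot - al1[, , perm[i]])), 1e-6)
})

test_that("Procrustes distance is symmetric, positive and zero at identity", {
  ds <- simulateLandmarks(circleShape(8), list(matrix(0, 8, 2)),
                          noise_sd = 0.05, sizes = 6L, seed = 43)
  al <- alignedCoords(gpa(ds))
  d12 <- procrustesDistance(al[, , 1], al[, , 2])
  expect_gt(d12, 0)
  expect_equal(d12, procrustesDistance(al[, , 2], al[, , 1]))
  expect_equal(procrustesDistance(al[, , 1], al[, , 1]), 0)

  degenerate <- array(1, c(4, 2, 3))
  expect_error(gpa(ShapeDataset(degenerate)), "degenerate")
})

test_that("semilandmark sliding descends bending energy, fixes anchors", {
  roles <- c(rep("fixed", 4), rep("semi", 8))
  set.seed(144)
  for (rep in 1:50) {
    ds <- simulateLandmarks(circleShape(12), list(matrix(0, 12, 2)),
                            noise_sd = 0.04, sizes = 8L,
                            seed = 2000 + rep, roles = roles)
    ds <- gpa(ds)
    sl <- slideSemilandmarks(ds, resuperimpose = FALSE, max_iter = 4)
    e <- attr(sl@aligned, "bending_energy")
    expect_true(all(diff(e) <= 1e-10))
    # fixed landmarks unchanged by the slide-only iteration
    expect_identical(alignedCoords(sl)[1:4, , ],
                     alignedCoords(ds)[1:4, , ])
  }
})

test_that("sliding a dataset already at the reference does nothing", {
  roles <- c(rep("fixed", 3), rep("semi", 6))
  ds <- simulateLandmarks(circleShape(9), list(matrix(0, 9, 2)),
                          noise_sd = 0.02, sizes = 6L, seed = 45,
                          roles = roles)
  ds <- gpa(ds)
  ref <- alignedCoords(ds)[, , 3]
  one <- ds
  one@aligned <- array(rep(ref, 4), c(9, 2, 4))[, , 1:4]
  one@coords <- one@aligned
  one@ids <- one@ids[1:4]; one@groups <- one@groups[1:4]
  one@centroidSizes <- rep(1, 4)
  sl <- slideSemilandmarks(one, reference = ref, resuperimpose = FALSE,
                           max_iter = 2)
  expect_lt(max(abs(alignedCoords(sl) - one@aligned)), 1e-10)

  expect_error(slideSemilandmarks(gpa(simulateLandmarks(
    circleShape(5), list(matrix(0, 5, 2)), noise_sd = 0.01,
    sizes = 4L, seed = 46)), resuperimpose = FALSE), "no semilandmarks")
})

test_that("relative warps at alpha 0 equal PCA of aligned coordinates", {
  off <- matrix(0, 10, 2); off2 <- off; off2[2, 1] <- 0.12
  ds <- gpa(simulateLandmarks(circleShape(10), list(off, off2),
                              noise_sd = 0.03, sizes = c(9L, 9L),
                              seed = 47))
  rw <- relativeWarps(ds, alpha = 0)
  X <- t(apply(alignedCoords(ds), 3, function(m) as.vector(t(m))))
  p <- pca(X)
  nA <- min(5, ncol(rw$scores), ncol(p$scores))
  expect_equal(abs(rw$scores[, 1:nA]), abs(p$scores[, 1:nA]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(rw$varfrac) <= 1e-12))
  expect_lte(sum(rw$varfrac), 1 + 1e-12)
  # sign flips leave inter-specimen geometry unchanged
  expect_equal(as.matrix(dist(rw$scores[, 1:nA])),
               as.matrix(dist(p$scores[, 1:nA])), tolerance = 1e-8,
               ignore_attr = TRUE)
  # alpha != 0 runs and reweights
  rwA <- relativeWarps(ds, alpha = 1)
  expect_equal(nrow(rwA$scores), 18L)
  expect_error(relativeWarps(gpa(ShapeDataset(ds@coords[, , 1:2])),
                             alpha = 0), "3 specimens")
})

test_that("Procrustes ANOVA rejects constructed group differences", {
  off <- matrix(0, 10, 2); off2 <- off; off2[1, ] <- c(0.2, 0.1)
  ds <- gpa(simulateLandmarks(circleShape(10), list(off, off2),
                              noise_sd = 0.02, sizes = c(12L, 12L),
                              seed = 48))
  an <- procrustesAnova(ds, n_permutations = 999, seed = 1)
  expect_lte(an$p, 0.001)
  expect_error(procrustesAnova(ds, n_permutations = 5), ">= 10")
  expect_error(procrustesAnova(ds, groups = rep("a", 24),
                               n_permutations = 99), "2 groups")
})

test_that("allometry regression detects simulated size dependence", {
  slope <- matrix(rnorm(20, 0, 0.06), 10, 2)
  ds <- gpa(simulateLandmarks(circleShape(10), list(matrix(0, 10, 2)),
                              allometry_slope = slope, noise_sd = 0.01,
                              sizes = 30L, seed = 49))
  sr <- shapeSizeRegression(ds, n_permutations = 999, seed = 1)
  expect_lte(sr$p, 0.001)
  # F invariant to a global rescaling of all sizes
  ds2 <- ds
  ds2@centroidSizes <- ds@centroidSizes * 7.3
  sr2 <- shapeSizeRegression(ds2, n_permutations = 99, seed = 1)
  expect_equal(sr$F, sr2$F, tolerance = 1e-10)

  dsConst <- ds
  dsConst@centroidSizes <- rep(2, nSpecimens(ds))
  expect_error(shapeSizeRegression(dsConst), "constant centroid")
})

test_that("permutation p-values are reproducible under a fixed seed", {
  ds <- gpa(simulateLandmarks(circleShape(8), list(matrix(0, 8, 2),
                                                   matrix(0, 8, 2)),
                              noise_sd = 0.05, sizes = c(8L, 8L),
                              seed = 50))
  a1 <- procrustesAnova(ds, n_permutations = 499, seed = 7)
  a2 <- procrustesAnova(ds, n_permutations = 499, seed = 7)
  expect_identical(a1, a2)
})
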