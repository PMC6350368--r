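test_that("bandwidth normalization matches hand evaluation and is linear", {
  # A = [[1,0],[1,1]]: mean squared profile norm = (1 + 2)/2 = 3/2
  a <- tiny_assoc()
  expect_equal(gip_bandwidth(a, 1), 2 / 3)
  expect_equal(gip_bandwidth(a, 2), 2 * gip_bandwidth(a, 1))

  # every miRNA with exactly one association: mean squared norm 1
  one_each <- tibble::tibble(mirna = c("m1", "m2", "m3"),
                             disease = c("d1", "d2", "d3"))
  expect_equal(gip_bandwidth(one_each, 1), 1)
})

test_that("kernel matches hand evaluation, has unit diagonal, lies in (0,1]", {
  # profiles [1,0] and [0,1]: squared distance 2, gamma 0.5 -> exp(-1)
  a <- tibble::tibble(mirna = c("m1", "m2"), disease = c("d1", "d2"))
  gm <- gip_kernel(a, gamma = 0.5)
  expect_equal(gm["m1", "m2"], exp(-1), tolerance = 1e-12)
  expect_equal(unname(diag(unclass(gm))), c(1, 1))

  # identical profiles give similarity exactly 1
  a2 <- tibble::tibble(mirna = c("m1", "m2"), disease = c("d1", "d1"))
  expect_equal(gip_kernel(a2, gamma = 1)["m1", "m2"], 1)

  set.seed(7)
  A <- random_assoc_matrix(15, 8)
  gm2 <- gip_kernel(A)
  expect_true(all(gm2 > 0 & gm2 <= 1))
  expect_equal(unclass(gm2), t(unclass(gm2)))
})

test_that("kernel is positive semidefinite and monotone in the bandwidth", {
  set.seed(11)
  for (rep in 1:5) {
    A <- random_assoc_matrix(12, 6)
    ev <- eigen(unclass(gip_kernel(A)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  # strictly decreasing off-diagonal entries as gamma grows
  A <- random_assoc_matrix(8, 5)
  g1 <- unclass(gip_kernel(A, gamma = 0.5))
  g2 <- unclass(gip_kernel(A, gamma = 1.5))
  off <- upper.tri(g1)
  differ <- g1[off] < 1  # pairs with distinct profiles
  expect_true(all(g2[off][differ] < g1[off][differ]))
})

test_that("all-zero association matrix has no defined bandwidth", {
  A <- structure(matrix(0L, 2, 2, dimnames = list(c("m1", "m2"),
                                                  c("d1", "d2"))),
                 class = c("assoc_matrix", "matrix", "array"))
  expect_error(gip_bandwidth(A), "bandwidth undefined")
})

test_that("integration takes FS where defined and GM elsewhere (scalar oracle)", {
  set.seed(3)
  A <- random_assoc_matrix(10, 6)
  gm <- gip_kernel(A)
  for (rep in 1:5) {
    S <- matrix(runif(100), 10, 10)
    S <- (S + t(S)) / 2
    mask <- matrix(runif(100) < 0.5, 10, 10)
    mask <- mask & t(mask)
    S[!mask] <- NA
    dimnames(S) <- dimnames(unclass(gm))
    fs <- as_similarity_matrix(S)
    sm <- integrate_similarity(fs, gm)
    # entry-wise scalar oracle
    for (i in 1:10) for (j in 1:10) {
      expected <- if (mask[i, j]) S[i, j] else unclass(gm)[i, j]
      expect_identical(unclass(sm)[i, j], expected)
    }
    expect_true(all(unclass(sm) >= 0 & unclass(sm) <= 1))
  }
})

test_that("integration branch extremes: all-defined FS and all-undefined FS", {
  A <- random_assoc_matrix(6, 4)
  gm <- gip_kernel(A)
  n <- nrow(gm)
  S <- matrix(0.3, n, n); diag(S) <- 1
  dimnames(S) <- dimnames(unclass(gm))
  expect_equal(as.matrix(integrate_similarity(as_similarity_matrix(S), gm)), S)
  S_na <- matrix(NA_real_, n, n, dimnames = dimnames(unclass(gm)))
  sm_na <- integrate_similarity(as_similarity_matrix(S_na), gm)
  expect_equal(as.matrix(sm_na), as.matrix(gm))
  # misaligned shapes refuse to integrate
  gm_small <- gip_kernel(random_assoc_matrix(4, 3))
  expect_error(integrate_similarity(as_similarity_matrix(S_na), gm_small),
               "aligned")
})
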