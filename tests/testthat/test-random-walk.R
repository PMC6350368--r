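test_that("column normalization matches hand-computed examples", {
  S <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sm <- as_similarity_matrix(S, role = "SM")
  expect_equal(unname(transition_matrix(sm)), matrix(0.5, 2, 2))

  S2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  T2 <- transition_matrix(as_similarity_matrix(S2, role = "SM"))
  expect_equal(unname(T2[, 1]), c(2 / 3, 1 / 3))
  expect_equal(unname(T2[, 2]), c(1 / 3, 2 / 3))

  # an already column-stochastic matrix passes through unchanged
  expect_equal(transition_matrix(as_similarity_matrix(T2, role = "SM")), T2,
               ignore_attr = TRUE)
})

test_that("initial distribution is the normalized seed row", {
  S <- matrix(c(1, 0.5, 0.5,
                0.5, 1, 0,
                0.5, 0, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sm <- as_similarity_matrix(S, role = "SM")
  expect_equal(unname(initial_distribution(sm, 1)), c(0.5, 0.25, 0.25))
  expect_equal(sum(initial_distribution(sm, 2)), 1)
  expect_equal(unname(initial_distribution(sm, "a")), c(0.5, 0.25, 0.25))
  expect_error(initial_distribution(sm, "zz"), "unknown seed")
})

test_that("walk fixed points: identity transition and closed-form 2x2", {
  p0 <- c(0.3, 0.7)
  w <- random_walk(diag(2), p0, restart = 0.5)
  expect_equal(w$p_inf, p0)
  expect_equal(w$iterations, 1L)

  # T uniform 2x2, p0 = (1,0), r = 0.4: p_inf = (0.7, 0.3)
  T2 <- matrix(0.5, 2, 2)
  w2 <- random_walk(T2, c(1, 0), restart = 0.4, cutoff = 1e-12)
  expect_equal(w2$p_inf, c(0.7, 0.3), tolerance = 1e-10)
  expect_equal(sum(w2$p_inf), 1, tolerance = 1e-9)
})

test_that("power iteration agrees with the direct linear solve", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    T_mat <- random_transition(n)
    p0 <- random_prob_vector(n)
    r <- sample(seq(0.1, 0.9, 0.1), 1)
    w <- random_walk(T_mat, p0, restart = r, cutoff = 1e-8)
    exact <- stationary_solve(T_mat, p0, r)
    expect_lt(sum(abs(w$p_inf - exact)), 1e-5)
  }
})

test_that("restart limit: as r -> 1 the walk stays at the seed distribution", {
  set.seed(5)
  T_mat <- random_transition(8)
  p0 <- random_prob_vector(8)
  w <- random_walk(T_mat, p0, restart = 0.999, cutoff = 1e-10)
  expect_lt(sum(abs(w$p_inf - p0)), 5e-3)
})

test_that("non-convergence is flagged rather than silent", {
  T_mat <- random_transition(5)
  p0 <- random_prob_vector(5)
  expect_warning(
    w <- random_walk(T_mat, p0, restart = 0.1, cutoff = 1e-14, max_iter = 3L),
    "did not converge")
  expect_false(w$converged)
  expect_equal(w$iterations, 3L)
})

test_that("all_walks returns one converged profile per miRNA in seed order", {
  fx <- small_fixture(seed = 4)
  net_sm <- integrate_similarity(
    suppressMessages(align_inputs(fx$associations, fx$fs))$fs,
    gip_kernel(association_matrix(fx$associations)))
  walks <- all_walks(net_sm, restart = 0.7)
  expect_equal(nrow(walks$P), nrow(net_sm))
  expect_equal(rownames(walks$P), rownames(net_sm))
  expect_true(all(walks$diagnostics$converged))
  expect_equal(unname(rowSums(walks$P)), rep(1, nrow(walks$P)),
               tolerance = 1e-9)
})

test_that("structurally identical nodes get permuted profiles", {
  # nodes 1 and 2 are exchangeable by construction
  S <- matrix(c(1, 0.8, 0.3,
                0.8, 1, 0.3,
                0.3, 0.3, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  walks <- all_walks(as_similarity_matrix(S, role = "SM"), cutoff = 1e-12)
  p_a <- walks$P[1, ]
  p_b <- walks$P[2, ]
  expect_equal(unname(p_a[c(2, 1, 3)]), unname(p_b), tolerance = 1e-8)
})
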