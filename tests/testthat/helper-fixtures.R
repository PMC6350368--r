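# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk except through tempfiles written here.

tiny_assoc <- function() {
  tibble::tibble(mirna = c("m1", "m2", "m2"),
                 disease = c("d1", "d1", "d2"))
}

write_assoc_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Random column-stochastic matrix of size n.
random_transition <- function(n) {
  M <- matrix(stats::runif(n * n, 0.01, 1), n, n)
  sweep(M, 2, colSums(M), `/`)
}

random_prob_vector <- function(n) {
  p <- stats::runif(n)
  p / sum(p)
}

# Random binary association matrix guaranteed to have no all-zero row.
random_assoc_matrix <- function(n_mirna, n_disease, p = 0.3) {
  A <- matrix(stats::rbinom(n_mirna * n_disease, 1, p), n_mirna, n_disease)
  empty <- rowSums(A) == 0
  A[cbind(which(empty), sample(n_disease, sum(empty), replace = TRUE))] <- 1L
  dimnames(A) <- list(sprintf("m%03d", seq_len(n_mirna)),
                      sprintf("d%03d", seq_len(n_disease)))
  structure(A, class = c("assoc_matrix", "matrix", "array"))
}

# Small planted fixture reused across pipeline tests (matches the generator's
# documented example scale).
small_fixture <- function(seed = 1) {
  simulate_fixture(n_mirna = 60, n_disease = 12, n_blocks = 3,
                   within_assoc = 0.6, cross_assoc = 0.05,
                   fs_within = 0.8, fs_cross = 0.2,
                   fs_noise_sd = 0.05, fs_coverage = 0.7, seed = seed)
}

# Hand-built walk_profiles object for feature tests.
manual_profiles <- function(P) {
  ids <- sprintf("m%d", seq_len(nrow(P)))
  dimnames(P) <- list(ids, ids)
  structure(list(P = P,
                 diagnostics = tibble::tibble(
                   mirna = ids, iterations = 1L, final_delta = 0,
                   converged = TRUE),
                 restart = 0.7, cutoff = 1e-6),
            class = "walk_profiles")
}
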