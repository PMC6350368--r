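#' Simulate a planted-block miRNA-disease fixture
#'
#' Generates an association list and a functional similarity matrix with
#' aligned community structure, emulating the core assumption of
#' similarity-based association prediction: functionally similar miRNAs
#' tend to be associated with the same diseases. miRNAs and diseases are
#' partitioned into `n_blocks` communities; an association between miRNA
#' `i` and disease `j` is drawn with probability `within_assoc` when they
#' share a block and `cross_assoc` otherwise. Functional similarity is the
#' corresponding block mean plus Gaussian noise, clipped to \[0, 1\] and
#' symmetrized, with a fraction `1 - fs_coverage` of off-diagonal pairs
#' masked undefined (so the kernel fallback of the integration rule is
#' exercised).
#'
#' Defaults describe a clearly separable 3-block system at a desk-testable
#' size; see the methods vignette for the rationale behind each value.
#'
#' @param n_mirna,n_disease Numbers of miRNAs and diseases.
#' @param n_blocks Number of aligned communities.
#' @param within_assoc,cross_assoc Association probability within / across
#'   blocks.
#' @param fs_within,fs_cross Mean functional similarity within / across
#'   blocks.
#' @param fs_noise_sd Gaussian noise sd added to similarity means.
#' @param fs_coverage Fraction of off-diagonal miRNA pairs with a defined
#'   functional similarity value.
#' @param seed Integer seed; the fixture is fully reproducible from it.
#' @return A list with `associations` (pair tibble), `fs` (a
#'   `similarity_matrix`), and `truth` (tibble with `id`, `kind`, `block`).
#' @export
#' @examples
#' fx <- simulate_fixture(n_mirna = 30, n_disease = 6, seed = 1)
#' head(fx$associations)
simulate_fixture <- function(n_mirna = 150, n_disease = 30, n_blocks = 3,
                             within_assoc = 0.6, cross_assoc = 0.05,
                             fs_within = 0.8, fs_cross = 0.2,
                             fs_noise_sd = 0.05, fs_coverage = 0.7,
                             seed = NULL) {
  stopifnot(n_mirna >= n_blocks, n_disease >= n_blocks,
            within_assoc >= 0, within_assoc <= 1,
            cross_assoc >= 0, cross_assoc <= 1,
            fs_coverage >= 0, fs_coverage <= 1, fs_noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  m_ids <- sprintf("mir-%04d", seq_len(n_mirna))
  d_ids <- sprintf("disease-%03d", seq_len(n_disease))
  m_block <- sort(rep(seq_len(n_blocks), length.out = n_mirna))
  d_block <- sort(rep(seq_len(n_blocks), length.out = n_disease))

  same <- outer(m_block, d_block, `==`)
  prob <- ifelse(same, within_assoc, cross_assoc)
  A <- matrix(stats::rbinom(n_mirna * n_disease, 1, as.vector(prob)),
              n_mirna, n_disease)
  idx <- which(A == 1, arr.ind = TRUE)
  associations <- tibble::tibble(mirna = m_ids[idx[, 1]],
                                 disease = d_ids[idx[, 2]]) |>
    dplyr::arrange(.data$mirna, .data$disease)

  same_m <- outer(m_block, m_block, `==`)
  mu <- ifelse(same_m, fs_within, fs_cross)
  noise <- matrix(stats::rnorm(n_mirna^2, 0, fs_noise_sd), n_mirna, n_mirna)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  S <- pmin(pmax(mu + noise, 0), 1)
  diag(S) <- 1
  # symmetric coverage mask on off-diagonal pairs
  mask <- matrix(FALSE, n_mirna, n_mirna)
  up <- which(upper.tri(mask))
  covered <- up[stats::runif(length(up)) < fs_coverage]
  mask[covered] <- TRUE
  mask <- mask | t(mask)
  diag(mask) <- TRUE
  S[!mask] <- NA_real_
  dimnames(S) <- list(m_ids, m_ids)

  list(
    associations = associations,
    fs = as_similarity_matrix(S, role = "FS"),
    truth = tibble::tibble(
      id = c(m_ids, d_ids),
      kind = rep(c("mirna", "disease"), c(n_mirna, n_disease)),
      block = c(m_block, d_block)
    )
  )
}

#' Within-disease label permutation (null model)
#'
#' Destroys the alignment between the similarity network and the
#' association labels while preserving each disease's number of known
#' miRNAs: every disease's label column is independently permuted across
#' miRNAs. Used as the negative control for the planted-signal evaluation:
#' pass the result as `label_matrix` to [loocv_roc()] so the network (the
#' design) stays fixed while the response is randomized, as in a standard
#' permutation test; under this null the LOOCV AUC is near 0.5. (Rebuilding
#' the network from the permuted matrix instead is not a clean null: each
#' disease's label column also enters the interaction-profile kernel, and
#' that self-reinforcement alone lifts the AUC above 0.5.)
#'
#' miRNAs left with no association after permutation drop out of the pair
#' list (and hence of the network).
#'
#' @param assoc Association pair tibble or `assoc_matrix`.
#' @param seed Optional integer seed.
#' @return A permuted association pair tibble.
#' @export
permute_associations <- function(assoc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- unclass(association_matrix(assoc))
  for (j in seq_len(ncol(A))) {
    A[, j] <- A[sample(nrow(A)), j]
  }
  idx <- which(A == 1, arr.ind = TRUE)
  tibble::tibble(mirna = rownames(A)[idx[, 1]],
                 disease = colnames(A)[idx[, 2]]) |>
    dplyr::arrange(.data$mirna, .data$disease)
}

#' Write a simulated fixture to disk
#'
#' Writes the association TSV, the functional similarity TSV and the
#' ground-truth block table into `dir`.
#'
#' @param fixture Output of [simulate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fixture$associations,
                     file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_similarity(fixture$fs, file.path(dir, "functional_similarity.tsv"))
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
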