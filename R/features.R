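#' Top-K candidate miRNAs for one seed
#'
#' Ranks the candidate miRNAs (every miRNA except the seed itself) by their
#' stationary walk probability and returns the K best. Ties at the K-th
#' rank are broken by canonical (lexicographic) identifier order, so the
#' selection is deterministic. The seed is excluded: the surrounding
#' network, not the node itself, should carry its label information.
#'
#' @param profile A `walk_profile` from [random_walk()], or a bare numeric
#'   stationary vector.
#' @param seed Index of the seed miRNA within the vector.
#' @param k Number of candidates, `1 <= k < length(p_inf)`.
#' @return Integer vector of `k` candidate indices, best first.
#' @export
top_k_candidates <- function(profile, seed, k) {
  p <- if (inherits(profile, "walk_profile")) profile$p_inf else profile
  n <- length(p)
  if (k >= n) stop("k must be smaller than the number of miRNAs",
                   call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  cand <- setdiff(seq_len(n), seed)
  ord <- cand[order(-p[cand], cand)]
  ord[seq_len(k)]
}

#' Default candidate-list size
#'
#' K = 50 (about 10% of the miRNA universe at the scale the method was
#' designed for); for small networks with fewer than 51 miRNAs the 10% rule
#' itself is applied, `K = ceiling(0.1 * n)`.
#'
#' @param n_mirna Number of miRNAs in the network.
#' @return An integer K.
#' @export
default_top_k <- function(n_mirna) {
  if (n_mirna < 51) max(1L, as.integer(ceiling(0.1 * n_mirna)))
  else 50L
}

# Sparse top-K weight matrix: W[i, c] = p_inf(i)[c] if c is among seed i's
# top-K candidates, else 0. phi1 = W y and phi0 = rowSums(W) - phi1 for any
# label vector y, which makes per-fold label edits O(n).
topk_weights <- function(walks, k) {
  stopifnot(inherits(walks, "walk_profiles"))
  P <- walks$P
  n <- nrow(P)
  W <- matrix(0, n, n, dimnames = dimnames(P))
  for (i in seq_len(n)) {
    sel <- top_k_candidates(P[i, ], i, k)
    W[i, sel] <- P[i, sel]
  }
  W
}

#' Ternary walk features for one disease
#'
#' For each miRNA `i`, splits the stationary probability mass of its top-K
#' walk candidates by the disease's association label: `phi1` is the summed
#' stationary probability of candidates known to be associated with the
#' disease (label 1), `phi0` the summed probability of the unlabelled
#' candidates (label 0). Together with a constant term this gives the
#' ternary feature vector `(1, phi1, phi0)` used by the per-disease
#' classifier.
#'
#' @param walks A `walk_profiles` object from [all_walks()].
#' @param labels Binary 0/1 vector, one element per miRNA in canonical
#'   order (typically a disease's column of the association matrix).
#' @param k Candidate-list size; default [default_top_k()].
#' @return Tibble with columns `mirna`, `phi1`, `phi0`, `label`.
#' @export
build_features <- function(walks, labels, k = default_top_k(nrow(walks$P))) {
  stopifnot(inherits(walks, "walk_profiles"))
  n <- nrow(walks$P)
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") must equal the number of ",
         "miRNAs (", n, ")", call. = FALSE)
  }
  stopifnot(all(labels %in% c(0, 1)))
  W <- topk_weights(walks, k)
  # both sums computed the same way so that flipping every label swaps
  # phi1 and phi0 bit-for-bit
  phi1 <- unname(as.vector(W %*% labels))
  phi0 <- unname(as.vector(W %*% (1 - labels)))
  tibble::tibble(mirna = rownames(walks$P), phi1 = phi1, phi0 = phi0,
                 label = as.integer(labels))
}
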