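#' Interaction-profile kernel bandwidth
#'
#' The interaction profile of miRNA `i` is the i-th row of the binary
#' association matrix: its pattern of known disease associations. The kernel
#' bandwidth is obtained by normalizing a raw bandwidth `gamma_prime` by the
#' mean squared profile norm, i.e. the average number of known associations
#' per miRNA:
#' \deqn{\gamma_m = \gamma'_m / \left(\frac{1}{n_m}\sum_i \|IP(m_i)\|^2\right)}
#'
#' @param assoc Association pair tibble or `assoc_matrix`.
#' @param gamma_prime Raw bandwidth, positive; default 1.
#' @return The normalized bandwidth, a positive scalar.
#' @export
#' @examples
#' a <- tibble::tibble(mirna = c("m1", "m2", "m2"),
#'                     disease = c("d1", "d1", "d2"))
#' gip_bandwidth(a)  # 1 / ((1 + 2)/2) = 2/3
gip_bandwidth <- function(assoc, gamma_prime = 1) {
  stopifnot(is.numeric(gamma_prime), gamma_prime > 0)
  A <- association_matrix(assoc)
  sq_norms <- rowSums(unclass(A)^2)
  if (sum(sq_norms) == 0) {
    stop("no associations: bandwidth undefined", call. = FALSE)
  }
  gamma_prime / mean(sq_norms)
}

#' Gaussian interaction-profile kernel similarity
#'
#' Similarity between two miRNAs' disease-association patterns:
#' \deqn{GM(i, j) = \exp(-\gamma_m \|IP(m_i) - IP(m_j)\|^2)}
#' The result is a symmetric positive-semidefinite matrix with unit
#' diagonal and entries in (0, 1].
#'
#' @param assoc Association pair tibble or `assoc_matrix`.
#' @param gamma Bandwidth; by default derived from `gamma_prime` via
#'   [gip_bandwidth()].
#' @param gamma_prime Raw bandwidth used when `gamma` is not supplied.
#' @return A `similarity_matrix` with role `"GM"`, fully defined.
#' @export
gip_kernel <- function(assoc, gamma = NULL, gamma_prime = 1) {
  A <- association_matrix(assoc)
  if (is.null(gamma)) gamma <- gip_bandwidth(A, gamma_prime)
  stopifnot(is.numeric(gamma), gamma > 0)
  M <- unclass(A) * 1.0
  sq <- rowSums(M^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(M)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  G <- exp(-gamma * d2)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  dimnames(G) <- list(rownames(A), rownames(A))
  new_similarity_matrix(G, array(TRUE, dim(G)), "GM")
}

#' Integrated miRNA similarity
#'
#' Combines curated functional similarity with the interaction-profile
#' kernel: where a pair has a defined functional-similarity value that value
#' is used, otherwise the kernel value. The diagonal keeps the functional
#' value where defined and is 1 otherwise (both conventions give unit
#' self-similarity, and the random-walk normalization requires a positive
#' diagonal).
#'
#' @param fs `similarity_matrix` of role `"FS"` (may contain undefined
#'   entries).
#' @param gm Fully defined `similarity_matrix` of role `"GM"`, same miRNAs
#'   in the same order.
#' @return A fully defined `similarity_matrix` with role `"SM"`.
#' @export
integrate_similarity <- function(fs, gm) {
  stopifnot(inherits(fs, "similarity_matrix"),
            inherits(gm, "similarity_matrix"))
  if (!identical(dim(fs), dim(gm)) ||
      !identical(rownames(fs), rownames(gm))) {
    stop("functional and kernel similarity matrices are not aligned",
         call. = FALSE)
  }
  use_fs <- defined_mask(fs)
  S <- unclass(gm)
  S[use_fs] <- unclass(fs)[use_fs]
  diag(S)[!diag(use_fs)] <- 1
  new_similarity_matrix(S, array(TRUE, dim(S)), "SM")
}
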