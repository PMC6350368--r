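#' Column-stochastic transition matrix
#'
#' Normalizes each column of the integrated similarity matrix to sum to one,
#' so that the walk iteration preserves probability vectors. The unit
#' diagonal policy of [integrate_similarity()] guarantees positive column
#' sums on valid input.
#'
#' @param sm Fully defined `similarity_matrix` (role `"SM"` typically).
#' @return A column-stochastic numeric matrix with matching dimnames.
#' @export
transition_matrix <- function(sm) {
  S <- if (inherits(sm, "similarity_matrix")) as.matrix(sm) else sm
  if (anyNA(S)) stop("similarity matrix has undefined entries", call. = FALSE)
  cs <- colSums(S)
  if (any(cs <= 0)) {
    stop("zero similarity column for miRNA ",
         colnames(S)[which(cs <= 0)[1]], call. = FALSE)
  }
  sweep(S, 2, cs, `/`)
}

#' Initial distribution for a seeded walk
#'
#' The walk from seed miRNA `i` starts at the normalized i-th row of the
#' integrated similarity matrix, spreading the initial probability over the
#' seed's neighbourhood in proportion to similarity.
#'
#' @param sm Fully defined `similarity_matrix`.
#' @param seed Seed miRNA: an index or an identifier present in `sm`.
#' @return A probability vector over all miRNAs (named).
#' @export
initial_distribution <- function(sm, seed) {
  S <- unclass(sm)
  i <- if (is.character(seed)) match(normalize_id(seed), rownames(S)) else seed
  if (is.na(i) || i < 1 || i > nrow(S)) {
    stop("unknown seed miRNA: ", seed, call. = FALSE)
  }
  row <- S[i, ]
  rs <- sum(row)
  if (rs <= 0) stop("zero similarity row for miRNA ", rownames(S)[i],
                    call. = FALSE)
  row / rs
}

#' Random walk with restart to the stationary distribution
#'
#' Iterates
#' \deqn{p(t+1) = (1 - r)\,T\,p(t) + r\,p(0)}
#' from `p(0) = p0` until the L1 change between successive iterates drops
#' below `cutoff`. The restart probability `r` is the per-step chance of
#' jumping back to the seed distribution and controls how local the
#' diffusion stays. The iteration is a contraction with rate `1 - r`, so
#' the iteration count is bounded by about `log(cutoff)/log(1 - r)`.
#'
#' @param T_mat Column-stochastic transition matrix (see
#'   [transition_matrix()]).
#' @param p0 Initial probability vector (sums to 1).
#' @param restart Restart probability in (0, 1); default 0.7. No value is
#'   canonical for this method; the default is a common network-propagation
#'   choice and should be reported with any result.
#' @param cutoff L1 convergence threshold; default `1e-6`.
#' @param max_iter Safety bound on iterations; default `1e4`.
#' @return A list of class `walk_profile`: `p_inf` (stationary probability
#'   vector), `iterations`, `final_delta`, `converged`.
#' @export
random_walk <- function(T_mat, p0, restart = 0.7, cutoff = 1e-6,
                        max_iter = 10000L) {
  stopifnot(restart > 0, restart < 1, cutoff > 0, max_iter >= 1)
  stopifnot(abs(sum(p0) - 1) < 1e-8, all(p0 >= 0))
  p <- p0
  for (it in seq_len(max_iter)) {
    p_next <- (1 - restart) * as.vector(T_mat %*% p) + restart * p0
    delta <- sum(abs(p_next - p))
    p <- p_next
    if (delta < cutoff) {
      return(structure(list(p_inf = p, iterations = it, final_delta = delta,
                            converged = TRUE), class = "walk_profile"))
    }
  }
  warning("random walk did not converge within ", max_iter, " iterations",
          call. = FALSE)
  structure(list(p_inf = p, iterations = max_iter, final_delta = delta,
                 converged = FALSE), class = "walk_profile")
}

#' Stationary profiles for every miRNA seed
#'
#' Runs the restart walk once per miRNA (each miRNA in turn is the seed;
#' all others are candidates), collecting the stationary distributions into
#' one matrix. The computation is fully deterministic.
#'
#' @param sm Fully defined `similarity_matrix`.
#' @param restart,cutoff,max_iter Passed to [random_walk()].
#' @return An object of class `walk_profiles`: list with `P` (matrix, one
#'   row per seed miRNA, columns = miRNAs, rows sum to 1), `diagnostics`
#'   (tibble with per-seed `iterations`, `final_delta`, `converged`) and the
#'   walk parameters.
#' @export
all_walks <- function(sm, restart = 0.7, cutoff = 1e-6, max_iter = 10000L) {
  T_mat <- transition_matrix(sm)
  ids <- rownames(sm)
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  its <- integer(n); deltas <- numeric(n); conv <- logical(n)
  for (i in seq_len(n)) {
    w <- random_walk(T_mat, initial_distribution(sm, i),
                     restart = restart, cutoff = cutoff, max_iter = max_iter)
    P[i, ] <- w$p_inf
    its[i] <- w$iterations; deltas[i] <- w$final_delta; conv[i] <- w$converged
  }
  structure(list(
    P = P,
    diagnostics = tibble::tibble(mirna = ids, iterations = its,
                                 final_delta = deltas, converged = conv),
    restart = restart, cutoff = cutoff
  ), class = "walk_profiles")
}

#' @export
print.walk_profiles <- function(x, ...) {
  cat(sprintf("<walk_profiles: %d seeds, restart=%.3g, cutoff=%.1g, %s>\n",
              nrow(x$P), x$restart, x$cutoff,
              if (all(x$diagnostics$converged)) "all converged"
              else "NOT all converged"))
  invisible(x)
}

#' Tidy walk profiles into long format
#' @param x A `walk_profiles` object.
#' @param ... Unused.
#' @return Tibble with columns `seed`, `mirna`, `p_inf`.
#' @method tidy walk_profiles
#' @export
tidy.walk_profiles <- function(x, ...) {
  ids <- rownames(x$P)
  tibble::tibble(
    seed = rep(ids, each = ncol(x$P)),
    mirna = rep(colnames(x$P), times = nrow(x$P)),
    p_inf = as.vector(t(x$P))
  )
}

#' Exact stationary distribution by direct linear solve
#'
#' Solves the fixed-point equation `p = (1 - r) T p + r p0` directly as
#' `p = r (I - (1 - r) T)^{-1} p0`. Serves as an independent cross-check of
#' the power iteration in [random_walk()]; at realistic network sizes the
#' iteration is the practical route.
#'
#' @inheritParams random_walk
#' @return The stationary probability vector.
#' @export
stationary_solve <- function(T_mat, p0, restart) {
  n <- nrow(T_mat)
  restart * solve(diag(n) - (1 - restart) * T_mat, p0)
}
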