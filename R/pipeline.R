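#' Assemble the miRNA similarity network and walk profiles
#'
#' Runs the label-independent half of the pipeline once: builds the binary
#' association matrix, aligns the functional similarity matrix to it,
#' computes the interaction-profile kernel and the integrated similarity,
#' runs the restart walk from every miRNA, and caches the top-K stationary
#' weights. The returned object is the input to [predict_disease()],
#' [predict_all()] and [loocv_roc()].
#'
#' @param assoc Association pair tibble (columns `mirna`, `disease`) or an
#'   `assoc_matrix`.
#' @param fs Optional functional `similarity_matrix`; when `NULL` the
#'   integrated similarity is the kernel alone.
#' @param restart Restart probability of the walk, in (0, 1).
#' @param top_k Candidate-list size; default [default_top_k()] of the miRNA
#'   count.
#' @param gamma_prime Raw kernel bandwidth (normalized internally).
#' @param cutoff L1 convergence threshold of the walk.
#' @param max_iter Walk iteration cap.
#' @return An object of class `mda_network` bundling the association
#'   matrix, similarity matrices, walk profiles, top-K weights and
#'   parameters.
#' @export
mda_network <- function(assoc, fs = NULL, restart = 0.7, top_k = NULL,
                        gamma_prime = 1, cutoff = 1e-6, max_iter = 10000L) {
  al <- align_inputs(assoc, fs)
  A <- al$assoc
  gm <- gip_kernel(A, gamma_prime = gamma_prime)
  sm <- integrate_similarity(al$fs, gm)
  walks <- all_walks(sm, restart = restart, cutoff = cutoff,
                     max_iter = max_iter)
  k <- top_k %||% default_top_k(nrow(A))
  structure(list(
    A = A, fs = al$fs, gm = gm, sm = sm, walks = walks,
    W = topk_weights(walks, k),
    params = list(restart = restart, top_k = k, gamma_prime = gamma_prime,
                  cutoff = cutoff, max_iter = max_iter)
  ), class = "mda_network")
}

#' @export
print.mda_network <- function(x, ...) {
  cat(sprintf(paste0("<mda_network: %d miRNAs x %d diseases, %d associations, ",
                     "restart=%.3g, K=%d>\n"),
              nrow(x$A), ncol(x$A), sum(x$A), x$params$restart,
              x$params$top_k))
  invisible(x)
}

# Fit the per-disease logistic model from cached top-K weights and a label
# vector; returns scores for all miRNAs plus the fitted model.
score_labels <- function(net, y, tol = 1e-8, ridge = 1e-8) {
  phi1 <- as.vector(net$W %*% y)
  phi0 <- rowSums(net$W) - phi1
  X <- cbind(intercept = 1, phi1 = phi1, phi0 = phi0)
  model <- fit_logistic(X, y = y, tol = tol, ridge = ridge)
  list(scores = predict(model, X), model = model)
}

#' Rank candidate miRNAs for one disease
#'
#' Takes the disease's association column as the binary label vector,
#' builds the ternary walk features, fits the logistic model on all miRNAs
#' and scores the unlabelled ones. Candidates are ranked by descending
#' posterior probability, ties broken by identifier order; known positives
#' are returned flagged and unranked.
#'
#' @param net An `mda_network`.
#' @param disease Disease identifier (normalized against the association
#'   matrix columns).
#' @param tol,ridge Passed to [fit_logistic()].
#' @return A tibble of class `disease_prediction` with columns `disease`,
#'   `mirna`, `score`, `rank` (NA for known positives), `is_known`.
#' @export
predict_disease <- function(net, disease, tol = 1e-8, ridge = 1e-8) {
  stopifnot(inherits(net, "mda_network"))
  d <- normalize_id(disease)
  if (!d %in% colnames(net$A)) {
    stop("unknown disease id: ", disease, call. = FALSE)
  }
  y <- unclass(net$A)[, d]
  sc <- score_labels(net, y, tol = tol, ridge = ridge)
  ids <- rownames(net$A)
  cand <- which(y == 0)
  ord <- cand[order(-sc$scores[cand], cand)]
  out <- tibble::tibble(
    disease = d,
    mirna = c(ids[ord], ids[y == 1]),
    score = c(sc$scores[ord], sc$scores[y == 1]),
    rank = c(seq_along(ord), rep(NA_integer_, sum(y))),
    is_known = c(rep(FALSE, length(ord)), rep(TRUE, sum(y)))
  )
  class(out) <- c("disease_prediction", class(out))
  attr(out, "model") <- sc$model
  out
}

#' Rank candidates for every disease
#'
#' Maps [predict_disease()] over all diseases with at least one known
#' association; per-disease failures are reported and skipped.
#'
#' @inheritParams predict_disease
#' @return A combined long-format tibble (same columns as
#'   [predict_disease()]).
#' @export
predict_all <- function(net, tol = 1e-8, ridge = 1e-8) {
  stopifnot(inherits(net, "mda_network"))
  diseases <- colnames(net$A)[colSums(net$A) >= 1]
  res <- purrr::map(diseases, function(d) {
    tryCatch(predict_disease(net, d, tol = tol, ridge = ridge),
             error = function(e) {
               message("skipping disease ", d, ": ", conditionMessage(e))
               NULL
             })
  })
  dplyr::bind_rows(res)
}

#' Write ranked predictions to TSV
#'
#' Writes one TSV per disease plus a combined long-format table
#' (`predictions_all.tsv`) into `dir`.
#'
#' @param predictions Output of [predict_all()] or [predict_disease()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_predictions <- function(predictions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(predictions, file.path(dir, "predictions_all.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (d in unique(predictions$disease)) {
    sub <- predictions[predictions$disease == d, ]
    fn <- paste0("predictions_", gsub("[^a-z0-9._-]+", "_", d), ".tsv")
    utils::write.table(sub, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Leave-one-out cross-validation with rank-pooled ROC
#'
#' Each known association is removed in turn: the left-out miRNA's label is
#' set to 0 for its disease, the ternary features and the logistic model
#' are refitted, and the left-out miRNA is ranked among all unlabelled
#' miRNAs of that disease. By default the similarity network and the
#' stationary walk profiles are computed once from the full association
#' matrix and held fixed across folds (only the label-dependent half of the
#' pipeline is refitted); `strict = TRUE` rebuilds the kernel, integrated
#' similarity and walks for every fold and is only practical on small data.
#'
#' Folds are pooled into one ROC by sweeping a normalized rank threshold:
#' fold `f` contributes its per-fold false-positive fraction
#' `x_f = (#candidates scoring above the test + 0.5 * ties) / #candidates`,
#' and `TPR(t)` is the fraction of folds with `x_f <= t`. The trapezoid
#' area of this staircase equals the tie-corrected Mann-Whitney statistic
#' `mean(1 - x_f)` exactly.
#'
#' @param x An `mda_network`, or an association pair tibble (then `fs` and
#'   the network parameters apply).
#' @param fs Optional functional `similarity_matrix` (used when `x` is a
#'   pair tibble).
#' @param restart,top_k,gamma_prime,cutoff,max_iter Network parameters,
#'   see [mda_network()].
#' @param tol,ridge Passed to [fit_logistic()].
#' @param strict Recompute kernel, integrated similarity and walks within
#'   every fold.
#' @param label_matrix Optional replacement label set: a binary
#'   miRNA-by-disease matrix (or association pair tibble) evaluated against
#'   the fixed network in place of the network's own association matrix.
#'   This is the permutation-test hook: permuting the labels while holding
#'   the network (the design) fixed gives a proper null for the LOOCV AUC
#'   (see [permute_associations()]).
#' @return An object of class `roc_result`: `folds` (per-fold tibble),
#'   `curve` (fpr/tpr staircase), `auc` (trapezoid), `auc_pairwise`
#'   (Mann-Whitney form), `n_folds`, `n_skipped`.
#' @export
loocv_roc <- function(x, fs = NULL, restart = 0.7, top_k = NULL,
                      gamma_prime = 1, cutoff = 1e-6, max_iter = 10000L,
                      tol = 1e-8, ridge = 1e-8, strict = FALSE,
                      label_matrix = NULL) {
  net <- if (inherits(x, "mda_network")) x else {
    mda_network(x, fs, restart = restart, top_k = top_k,
                gamma_prime = gamma_prime, cutoff = cutoff,
                max_iter = max_iter)
  }
  A <- unclass(net$A)
  ids <- rownames(A)
  if (!is.null(label_matrix)) {
    if (is.data.frame(label_matrix)) {
      label_matrix <- association_matrix(label_matrix)
    }
    L <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
    keep_r <- intersect(rownames(label_matrix), ids)
    keep_c <- intersect(colnames(label_matrix), colnames(A))
    L[keep_r, keep_c] <- unclass(label_matrix)[keep_r, keep_c]
    if (strict) {
      stop("strict = TRUE rebuilds the network from its own labels and ",
           "cannot be combined with label_matrix", call. = FALSE)
    }
    A <- L
  }
  folds_idx <- which(A == 1, arr.ind = TRUE)
  recs <- vector("list", nrow(folds_idx))
  n_skipped <- 0L
  for (f in seq_len(nrow(folds_idx))) {
    i <- folds_idx[f, 1]; j <- folds_idx[f, 2]
    y <- A[, j]; y[i] <- 0
    if (sum(y) == 0) { n_skipped <- n_skipped + 1L; next }
    scores <- if (strict) {
      A_fold <- A; A_fold[i, j] <- 0L
      A_fold <- structure(A_fold, class = c("assoc_matrix", "matrix", "array"))
      net_fold <- suppressMessages(
        mda_network(A_fold, net$fs, restart = net$params$restart,
                    top_k = net$params$top_k,
                    gamma_prime = net$params$gamma_prime,
                    cutoff = net$params$cutoff,
                    max_iter = net$params$max_iter))
      score_labels(net_fold, y, tol = tol, ridge = ridge)$scores
    } else {
      score_labels(net, y, tol = tol, ridge = ridge)$scores
    }
    cand <- which(y == 0)           # unlabelled pool, test included
    others <- setdiff(cand, i)
    if (length(others) == 0) { n_skipped <- n_skipped + 1L; next }
    s_test <- scores[i]
    n_above <- sum(scores[others] > s_test)
    n_tied <- sum(scores[others] == s_test)
    recs[[f]] <- tibble::tibble(
      disease = colnames(A)[j], mirna = ids[i], score = s_test,
      rank = n_above + 1L, n_candidates = length(others),
      n_above = n_above, n_tied = n_tied
    )
  }
  folds <- dplyr::bind_rows(recs)
  if (nrow(folds) == 0) {
    stop("no usable LOOCV folds (every disease has fewer than 2 known ",
         "associations)", call. = FALSE)
  }
  if (n_skipped > 0) {
    message(n_skipped, " fold(s) skipped (disease left with no positives ",
            "or no candidates)")
  }
  xf <- (folds$n_above + 0.5 * folds$n_tied) / folds$n_candidates
  curve <- roc_staircase(xf)
  structure(list(
    folds = folds, curve = curve,
    auc = trapezoid_auc(curve),
    auc_pairwise = mean(1 - xf),
    n_folds = nrow(folds), n_skipped = n_skipped,
    params = net$params
  ), class = "roc_result")
}

# Pooled staircase ROC from per-fold false-positive fractions. Vertical
# jumps are encoded as duplicated x-coordinates so the trapezoid rule
# integrates the step function exactly.
roc_staircase <- function(xf) {
  n <- length(xf)
  xs <- sort(unique(xf))
  cdf <- vapply(xs, function(t) mean(xf <= t), numeric(1))
  fpr <- c(0, rep(xs, each = 2), 1)
  tpr <- c(0, as.vector(rbind(c(0, cdf[-length(cdf)]), cdf)), 1)
  keep <- !duplicated(cbind(fpr, tpr))
  tibble::tibble(fpr = fpr[keep], tpr = tpr[keep])
}

trapezoid_auc <- function(curve) {
  dx <- diff(curve$fpr)
  sum(dx * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.4f over %d folds (%d skipped)>\n",
              x$auc, x$n_folds, x$n_skipped))
  invisible(x)
}

#' Tidy the ROC curve points
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return Tibble with columns `fpr`, `tpr`.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' One-row LOOCV summary
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return Tibble with `auc`, `auc_pairwise`, `n_folds`, `n_skipped`.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_pairwise = x$auc_pairwise,
                 n_folds = x$n_folds, n_skipped = x$n_skipped)
}

#' Plot a LOOCV ROC curve
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("LOOCV ROC (AUC = %.4f, %d folds)",
                                  object$auc, object$n_folds)) +
    ggplot2::theme_minimal()
}

#' Plot top-ranked candidates for one disease
#' @param object A `disease_prediction`.
#' @param n_top Number of top candidates to show; default 20.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot disease_prediction
#' @export
autoplot.disease_prediction <- function(object, n_top = 20, ...) {
  sub <- object[!object$is_known, ]
  sub <- utils::head(sub[order(sub$rank), ], n_top)
  sub$mirna <- factor(sub$mirna, levels = rev(sub$mirna))
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$score, y = .data$mirna)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$mirna),
                          colour = "grey70") +
    ggplot2::geom_point(colour = "#b2182b") +
    ggplot2::labs(x = "Posterior association probability", y = NULL,
                  title = paste("Top candidates:", unique(object$disease))) +
    ggplot2::theme_minimal()
}
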