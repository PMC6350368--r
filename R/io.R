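#' Read a miRNA-disease association list
#'
#' Reads a two-column delimited file of (miRNA id, disease id) records and
#' returns one row per distinct association. Identifiers are normalized
#' (lower-cased, whitespace-trimmed) before matching, because the public
#' association and similarity resources capitalize miRNA names differently
#' and silent row misalignment is the dominant failure mode downstream.
#' Duplicate records (e.g. one row per supporting publication) collapse to a
#' single association; the number collapsed is reported via a message.
#'
#' A header line is tolerated: if the first line's fields look like column
#' names (`mirna`, `disease`, optionally suffixed `_id`/`_name`) it is
#' skipped.
#'
#' @param path Path to a delimited text file with at least two columns:
#'   miRNA identifier, disease identifier.
#' @param delim Field delimiter, default tab.
#' @return A tibble with columns `mirna` and `disease`, one row per distinct
#'   association, sorted by (`mirna`, `disease`).
#' @seealso [association_matrix()] to build the binary adjacency matrix.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("m1\td1", "m2\td1", "m2\td2", "m2\td2"), f)
#' read_associations(f)
read_associations <- function(path, delim = "\t") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("association file is empty: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, delim, fixed = TRUE)
  if (is_assoc_header(fields[[1]])) {
    fields <- fields[-1]
    offset <- 1L
    if (length(fields) == 0) {
      stop("association file has a header but no records: ", path, call. = FALSE)
    }
  } else {
    offset <- 0L
  }
  bad <- which(vapply(fields, function(f) {
    length(f) < 2 || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2]))
  }, logical(1)))
  if (length(bad) > 0) {
    stop("record with missing miRNA or disease field at line ",
         bad[1] + offset, call. = FALSE)
  }
  tbl <- tibble::tibble(
    mirna   = normalize_id(vapply(fields, `[`, character(1), 1)),
    disease = normalize_id(vapply(fields, `[`, character(1), 2))
  )
  n_raw <- nrow(tbl)
  tbl <- dplyr::distinct(tbl)
  if (n_raw > nrow(tbl)) {
    message(n_raw - nrow(tbl), " duplicate association record(s) collapsed")
  }
  dplyr::arrange(tbl, .data$mirna, .data$disease)
}

is_assoc_header <- function(fields) {
  length(fields) >= 2 &&
    all(grepl("^(mi?rna|mir|disease)([_ -]?(id|name))?$",
              tolower(trimws(fields[1:2]))))
}

normalize_id <- function(x) tolower(trimws(x))

#' Build the binary association matrix from a pair list
#'
#' Constructs the labelled adjacency matrix `A` with `A[i, j] = 1` iff miRNA
#' `i` is associated with disease `j`. Row (miRNA) and column (disease)
#' order is lexicographic over normalized identifiers; this canonical order
#' is shared by every downstream matrix.
#'
#' @param assoc A data frame with columns `mirna` and `disease` (as from
#'   [read_associations()]), or an already-built association matrix (returned
#'   unchanged).
#' @return A binary integer matrix of class `assoc_matrix` with miRNA row
#'   names and disease column names.
#' @export
association_matrix <- function(assoc) {
  if (inherits(assoc, "assoc_matrix")) return(assoc)
  stopifnot(is.data.frame(assoc), all(c("mirna", "disease") %in% names(assoc)))
  if (nrow(assoc) == 0) stop("no association records", call. = FALSE)
  mirna <- normalize_id(as.character(assoc$mirna))
  disease <- normalize_id(as.character(assoc$disease))
  mids <- sort(unique(mirna))
  dids <- sort(unique(disease))
  A <- matrix(0L, length(mids), length(dids), dimnames = list(mids, dids))
  A[cbind(match(mirna, mids), match(disease, dids))] <- 1L
  structure(A, class = c("assoc_matrix", class(A)))
}

#' Tidy an association matrix back into a pair list
#' @param x An `assoc_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `mirna`, `disease` for every unit entry.
#' @method tidy assoc_matrix
#' @export
tidy.assoc_matrix <- function(x, ...) {
  idx <- which(unclass(x) == 1L, arr.ind = TRUE)
  tibble::tibble(mirna = rownames(x)[idx[, 1]],
                 disease = colnames(x)[idx[, 2]]) |>
    dplyr::arrange(.data$mirna, .data$disease)
}

new_similarity_matrix <- function(S, defined, role) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S),
            identical(dim(S), dim(defined)))
  attributes(S) <- attributes(S)[c("dim", "dimnames")]
  attributes(defined) <- attributes(defined)[c("dim", "dimnames")]
  structure(S, defined = defined, role = role,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Extract the bare numeric values of a similarity matrix
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return A plain numeric matrix (undefined entries as `NA`).
#' @export
as.matrix.similarity_matrix <- function(x, ...) {
  y <- unclass(x)
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  y
}

#' Defined-entry mask of a similarity matrix
#'
#' Curated functional similarity covers only some miRNA pairs; entries
#' absent from the source are recorded as undefined (and fall back to the
#' interaction-profile kernel during integration).
#'
#' @param s A `similarity_matrix`.
#' @return A logical matrix, `TRUE` where the value is present.
#' @export
defined_mask <- function(s) {
  stopifnot(inherits(s, "similarity_matrix"))
  attr(s, "defined")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix role=%s, %d x %d, %.1f%% defined>\n",
              attr(x, "role") %||% "?", nrow(x), ncol(x),
              100 * mean(attr(x, "defined"))))
  invisible(x)
}

#' Read a labelled square similarity matrix
#'
#' Reads a delimited square matrix whose first row and first column carry
#' miRNA identifiers. Blank cells mark pairs with no curated similarity and
#' are recorded as undefined in the mask. Small numerical asymmetry (at most
#' `1e-6`) is repaired by averaging `S` with its transpose; larger asymmetry
#' is a data error.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, default tab.
#' @param role Role tag, one of `"FS"`, `"GM"`, `"SM"`; default `"FS"`.
#' @return A `similarity_matrix` with a defined-entry mask.
#' @export
read_similarity <- function(path, delim = "\t", role = "FS") {
  df <- utils::read.delim(path, sep = delim, header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          strip.white = TRUE)
  if (nrow(df) != ncol(df)) {
    stop("similarity matrix is not square: ", nrow(df), " rows, ",
         ncol(df), " columns", call. = FALSE)
  }
  ids <- normalize_id(rownames(df))
  col_ids <- normalize_id(colnames(df))
  if (!identical(sort(ids), sort(col_ids))) {
    stop("row and column labels of similarity matrix disagree", call. = FALSE)
  }
  df <- df[, match(ids, col_ids), drop = FALSE]
  raw <- as.matrix(df)
  blank <- raw == "" | is.na(raw)
  S <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (any(is.na(S) & !blank)) {
    bad <- which(is.na(S) & !blank, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric similarity value at (%s, %s)",
                 ids[bad[1]], ids[bad[2]]), call. = FALSE)
  }
  defined <- !is.na(S)
  if (!identical(defined, t(defined))) {
    stop("defined/blank pattern of similarity matrix is not symmetric",
         call. = FALSE)
  }
  asym <- abs(S - t(S))
  if (any(asym[defined] > 1e-6)) {
    stop("similarity matrix asymmetry exceeds 1e-6", call. = FALSE)
  }
  S <- (S + t(S)) / 2
  S[!defined] <- NA_real_
  if (any(S[defined] < 0 | S[defined] > 1)) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  dimnames(S) <- dimnames(defined) <- list(ids, ids)
  ord <- order(ids)
  new_similarity_matrix(S[ord, ord, drop = FALSE],
                        defined[ord, ord, drop = FALSE], role)
}

#' Write a similarity matrix as labelled TSV
#'
#' Round-trips through [read_similarity()] to 12 significant digits;
#' undefined entries are written as blank cells.
#'
#' @param s A `similarity_matrix`.
#' @param path Output path.
#' @param delim Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(s, path, delim = "\t") {
  stopifnot(inherits(s, "similarity_matrix"))
  out <- matrix(sprintf("%.12g", unclass(s)), nrow(s), ncol(s))
  out[!defined_mask(s)] <- ""
  df <- as.data.frame(out)
  colnames(df) <- colnames(s)
  df <- cbind(mirna = rownames(s), df)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a similarity matrix from numeric data
#'
#' @param S Square numeric matrix with miRNA dimnames; `NA` entries are
#'   treated as undefined.
#' @param role Role tag (`"FS"`, `"GM"` or `"SM"`).
#' @return A `similarity_matrix`.
#' @export
as_similarity_matrix <- function(S, role = "FS") {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), !is.null(rownames(S)))
  ids <- normalize_id(rownames(S))
  dimnames(S) <- list(ids, ids)
  defined <- !is.na(S)
  if (max(abs(S - t(S))[defined & t(defined)], 0) > 1e-12) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  ord <- order(ids)
  new_similarity_matrix(S[ord, ord, drop = FALSE],
                        defined[ord, ord, drop = FALSE], role)
}

#' Align association and functional-similarity inputs
#'
#' Restricts both inputs to a common canonical (lexicographic) miRNA order.
#' The association matrix defines the miRNA universe: miRNAs absent from the
#' functional-similarity matrix are retained with fully undefined similarity
#' rows, so that integration falls back to the interaction-profile kernel
#' for them; similarity rows for miRNAs with no recorded association are
#' dropped. Counts kept/dropped are reported via a message.
#'
#' @param assoc An association pair tibble or `assoc_matrix`.
#' @param fs A `similarity_matrix` (role FS), or `NULL` for none.
#' @return A list with elements `assoc` (an `assoc_matrix`) and `fs` (a
#'   `similarity_matrix` over the same miRNAs, in the same order).
#' @export
align_inputs <- function(assoc, fs = NULL) {
  A <- association_matrix(assoc)
  mids <- rownames(A)
  if (is.null(fs)) {
    S <- matrix(NA_real_, length(mids), length(mids),
                dimnames = list(mids, mids))
    fs_out <- new_similarity_matrix(S, !is.na(S), "FS")
    return(list(assoc = A, fs = fs_out))
  }
  stopifnot(inherits(fs, "similarity_matrix"))
  common <- intersect(mids, rownames(fs))
  if (length(common) == 0 && all(!defined_mask(fs))) {
    stop("no overlap between association and similarity miRNAs, and no ",
         "defined similarity entries: nothing to integrate", call. = FALSE)
  }
  S <- matrix(NA_real_, length(mids), length(mids),
              dimnames = list(mids, mids))
  if (length(common) > 0) {
    S[common, common] <- unclass(fs)[common, common]
  }
  message(length(common), " miRNA(s) shared with similarity matrix; ",
          length(mids) - length(common), " kept with undefined rows; ",
          nrow(fs) - length(common), " similarity-only miRNA(s) dropped")
  list(assoc = A,
       fs = new_similarity_matrix(S, !is.na(S), "FS"))
}
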