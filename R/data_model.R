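# Domain types, validation, and matrix I/O.
#
# Canonical orientations are fixed per type and asserted at construction:
#   feature views X(v)      features x drugs   (view 4: diseases x drugs)
#   associations  Y, F      drugs x diseases
#   similarities  R(v), D   entities x entities (square, symmetric)

#' Construct a drug feature view
#'
#' A feature view is a non-negative matrix with features in rows and drugs in
#' columns. Views 1-3 hold binary drug descriptors (chemical substructures,
#' target protein domains, target gene-ontology annotations); view 4 is the
#' associated-disease profile, a binary diseases x drugs matrix equal to the
#' transpose of the association matrix.
#'
#' @param values Numeric matrix, features x drugs, all entries >= 0 and binary
#'   (0/1).
#' @param view_id Integer in 1..4 identifying the view.
#' @param feature_ids,drug_ids Character identifiers for rows and columns;
#'   default to the dimnames of `values`.
#' @return An object of class `feature_matrix` with fields `values`,
#'   `view_id`, `feature_ids`, `drug_ids`.
#' @examples
#' x <- feature_matrix(matrix(c(1, 0, 1, 1, 0, 0), 3, 2,
#'   dimnames = list(paste0("f", 1:3), c("drugA", "drugB"))), view_id = 1)
#' @export
feature_matrix <- function(values, view_id,
                           feature_ids = rownames(values),
                           drug_ids = colnames(values)) {
  values <- as.matrix(values)
  obj <- structure(
    list(values = values, view_id = as.integer(view_id),
         feature_ids = as.character(feature_ids),
         drug_ids = as.character(drug_ids)),
    class = "feature_matrix"
  )
  validate_feature_matrix(obj)
}

#' @rdname feature_matrix
#' @param x A `feature_matrix`.
#' @export
validate_feature_matrix <- function(x) {
  v <- x$values
  if (!is.numeric(v) || !is.matrix(v)) {
    stop("feature_matrix values must be a numeric matrix", call. = FALSE)
  }
  if (!x$view_id %in% 1:4) {
    stop("view_id must be in 1..4", call. = FALSE)
  }
  if (length(x$feature_ids) != nrow(v) || length(x$drug_ids) != ncol(v)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(x$drug_ids)) {
    stop("duplicate drug identifiers", call. = FALSE)
  }
  if (anyNA(v) || any(v < 0)) {
    stop("feature matrix entries must be non-negative and non-missing",
         call. = FALSE)
  }
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("feature view %d must be binary {0,1}", x$view_id),
         call. = FALSE)
  }
  dimnames(x$values) <- list(x$feature_ids, x$drug_ids)
  x
}

#' Construct drug-disease association data
#'
#' Holds the binary association matrix Y (drugs x diseases) together with the
#' observation mask M over the known set Omega. The mask equals Y: only known
#' positive pairs are observed, all other pairs are unmarked.
#'
#' @param Y Binary numeric matrix, drugs x diseases.
#' @param drug_ids,disease_ids Character identifiers; default to dimnames.
#' @return An object of class `association_data` with fields `Y`, `M`
#'   (identical to `Y`), `drug_ids`, `disease_ids`.
#' @export
association_data <- function(Y, drug_ids = rownames(Y),
                             disease_ids = colnames(Y)) {
  Y <- as.matrix(Y)
  obj <- structure(
    list(Y = Y, M = Y, drug_ids = as.character(drug_ids),
         disease_ids = as.character(disease_ids)),
    class = "association_data"
  )
  validate_association_data(obj)
}

#' @rdname association_data
#' @param x An `association_data` object.
#' @export
validate_association_data <- function(x) {
  if (anyNA(x$Y) || !all(x$Y %in% c(0, 1))) {
    stop("association matrix must be binary {0,1}", call. = FALSE)
  }
  if (!identical(unname(x$M), unname(x$Y))) {
    stop("observation mask must equal the association matrix (M = Y)",
         call. = FALSE)
  }
  if (length(x$drug_ids) != nrow(x$Y) ||
      length(x$disease_ids) != ncol(x$Y)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(x$drug_ids) || anyDuplicated(x$disease_ids)) {
    stop("duplicate identifiers", call. = FALSE)
  }
  dimnames(x$Y) <- dimnames(x$M) <- list(x$drug_ids, x$disease_ids)
  x
}

#' Construct a similarity matrix
#'
#' A square symmetric matrix of pairwise similarities in \[0, 1\], either
#' drug-drug (one per feature view) or disease-disease (semantic similarity,
#' supplied as an input).
#'
#' @param values Square numeric matrix with entries in \[0, 1\], symmetric to
#'   within 1e-10.
#' @param entity_ids Character identifiers; default to rownames.
#' @param kind One of `"drug_view_1"` .. `"drug_view_4"`, `"disease"`.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, entity_ids = rownames(values),
                              kind = "disease") {
  values <- as.matrix(values)
  obj <- structure(
    list(values = values, entity_ids = as.character(entity_ids),
         kind = match.arg(kind, c(paste0("drug_view_", 1:4), "disease"))),
    class = "similarity_matrix"
  )
  validate_similarity_matrix(obj)
}

#' @rdname similarity_matrix
#' @param x A `similarity_matrix`.
#' @export
validate_similarity_matrix <- function(x) {
  v <- x$values
  if (nrow(v) != ncol(v)) stop("similarity matrix must be square", call. = FALSE)
  if (length(x$entity_ids) != nrow(v)) {
    stop("identifier length does not match matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(x$entity_ids)) stop("duplicate identifiers", call. = FALSE)
  if (anyNA(v) || any(v < 0) || any(v > 1)) {
    stop("similarity entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(v - t(v))) > 1e-10) {
    stop("similarity matrix must be symmetric (tolerance 1e-10)", call. = FALSE)
  }
  dimnames(x$values) <- list(x$entity_ids, x$entity_ids)
  x
}

#' Model hyperparameters
#'
#' Regularization weights and optimizer settings. Defaults are the weights at
#' which the model performs best in five-fold cross-validation on the original
#' 763-drug data: alpha1 = 1 (feature reconstruction), alpha2 = 10 (diversity),
#' alpha3 = 0.1 (score/projection consistency), alpha4 = 0.1 (graph
#' smoothness), alpha5 = 0.1 (l1 sparsity).
#'
#' @param alpha1,alpha2,alpha3,alpha4,alpha5 Non-negative regularization
#'   weights for, respectively, multi-view reconstruction, diversity,
#'   score-projection consistency, dual graph smoothness, and l1 sparsity.
#' @param k_neighbors Number of nearest neighbours for the affinity graphs
#'   (shared by the four drug graphs and the disease graph).
#' @param max_iter Maximum number of full update sweeps.
#' @param tol Convergence threshold on the relative objective change.
#' @param epsilon Small positive stabilizer added to every multiplicative
#'   update denominator.
#' @param seed Integer seed for the uniform(0,1) factor initialization.
#' @param literal_f_denominator If `TRUE`, use the bare `8F` term in the score
#'   update denominator as printed in the original update rule; the default
#'   `FALSE` uses `8*alpha3*F`, the form consistent with the KKT derivation of
#'   the score subproblem.
#' @return An object of class `hyperparameters`.
#' @export
hyperparameters <- function(alpha1 = 1, alpha2 = 10, alpha3 = 0.1,
                            alpha4 = 0.1, alpha5 = 0.1, k_neighbors = 5L,
                            max_iter = 500L, tol = 1e-6, epsilon = 1e-12,
                            seed = 1L, literal_f_denominator = FALSE) {
  obj <- structure(
    list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3, alpha4 = alpha4,
         alpha5 = alpha5, k_neighbors = as.integer(k_neighbors),
         max_iter = as.integer(max_iter), tol = tol, epsilon = epsilon,
         seed = as.integer(seed),
         literal_f_denominator = isTRUE(literal_f_denominator)),
    class = "hyperparameters"
  )
  validate_hyperparameters(obj)
}

#' @rdname hyperparameters
#' @param x A `hyperparameters` object.
#' @export
validate_hyperparameters <- function(x) {
  alphas <- unlist(x[paste0("alpha", 1:5)])
  if (anyNA(alphas) || any(alphas < 0)) {
    stop("alpha weights must be non-negative", call. = FALSE)
  }
  if (is.na(x$k_neighbors) || x$k_neighbors < 1L) {
    stop("k_neighbors must be a positive integer", call. = FALSE)
  }
  if (is.na(x$max_iter) || x$max_iter < 1L) {
    stop("max_iter must be a positive integer", call. = FALSE)
  }
  if (!is.finite(x$tol) || x$tol < 0) stop("tol must be >= 0", call. = FALSE)
  if (!is.finite(x$epsilon) || x$epsilon <= 0) {
    stop("epsilon must be a small positive real", call. = FALSE)
  }
  x
}

#' Read hyperparameters from a YAML key-value file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a YAML file whose keys are arguments of
#'   [hyperparameters()].
#' @return A `hyperparameters` object.
#' @export
load_hyperparameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(hyperparameters))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown hyperparameter keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(hyperparameters, cfg)
}

values_of <- function(m) {
  if (is.matrix(m)) return(m)
  if (inherits(m, "feature_matrix") || inherits(m, "similarity_matrix")) {
    return(m$values)
  }
  if (inherits(m, "association_data")) return(m$Y)
  stop("not a recognised matrix type", call. = FALSE)
}

# ---- file I/O --------------------------------------------------------------

# TSV dialect: tab-separated, UTF-8, "." decimal; first row holds column ids
# (leading empty cell), first column holds row ids. Reals are written with 17
# significant digits so that read(write(x)) is bitwise lossless.

read_tsv_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) {
    stop("parse error in ", path, ": need a header row and at least one data row",
         call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1L]])
  col_ids <- fields[[1L]][-1L]
  n <- length(lines) - 1L
  out <- matrix(NA_real_, n, ncols - 1L)
  row_ids <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncols) {
      stop(sprintf("parse error in %s at line %d: expected %d fields, found %d",
                   path, i + 1L, ncols, length(f)), call. = FALSE)
    }
    row_ids[i] <- f[1L]
    vals <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(vals)) {
      stop(sprintf("parse error in %s at line %d: non-numeric entry",
                   path, i + 1L), call. = FALSE)
    }
    out[i, ] <- vals
  }
  dimnames(out) <- list(row_ids, col_ids)
  out
}

write_tsv_matrix <- function(m, path) {
  header <- paste(c("", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(NULL)
}

sidecar_paths <- function(path) {
  list(rows = paste0(path, ".rownames"), cols = paste0(path, ".colnames"))
}

read_mtx_matrix <- function(path) {
  side <- sidecar_paths(path)
  if (!file.exists(side$rows) || !file.exists(side$cols)) {
    stop("missing identifier sidecar(s) for ", path, call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(path))
  # binary matrices round-trip through MatrixMarket "pattern" files
  storage.mode(m) <- "double"
  row_ids <- readLines(side$rows, encoding = "UTF-8")
  col_ids <- readLines(side$cols, encoding = "UTF-8")
  if (length(row_ids) != nrow(m) || length(col_ids) != ncol(m)) {
    stop("sidecar identifier counts do not match matrix dimensions",
         call. = FALSE)
  }
  dimnames(m) <- list(row_ids, col_ids)
  m
}

write_mtx_matrix <- function(m, path) {
  side <- sidecar_paths(path)
  Matrix::writeMM(Matrix::Matrix(unname(m), sparse = TRUE), path)
  writeLines(rownames(m), side$rows, useBytes = TRUE)
  writeLines(colnames(m), side$cols, useBytes = TRUE)
  invisible(NULL)
}

#' Read a typed matrix from TSV or Matrix Market
#'
#' Dense TSV files carry identifiers in the first row and column; sparse
#' Matrix Market files carry them in `<path>.rownames` / `<path>.colnames`
#' sidecars. The result is validated against the invariants of the requested
#' type; orientation is the canonical one for that type (features x drugs for
#' feature views, drugs x diseases for associations).
#'
#' @param path Input file.
#' @param format `"tsv"` or `"mtx"`.
#' @param what Target type: `"feature"`, `"association"`, or `"similarity"`.
#' @param view_id View index 1..4, required when `what = "feature"`.
#' @param kind Similarity kind, passed to [similarity_matrix()].
#' @return A validated `feature_matrix`, `association_data`, or
#'   `similarity_matrix`.
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"),
                        what = c("feature", "association", "similarity"),
                        view_id = NULL, kind = "disease") {
  format <- match.arg(format)
  what <- match.arg(what)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- switch(format, tsv = read_tsv_matrix(path), mtx = read_mtx_matrix(path))
  switch(what,
    feature = {
      if (is.null(view_id)) stop("view_id is required for feature views",
                                 call. = FALSE)
      feature_matrix(m, view_id = view_id)
    },
    association = association_data(m),
    similarity = similarity_matrix(m, kind = kind)
  )
}

#' Write a typed matrix to TSV or Matrix Market
#'
#' Inverse of [read_matrix()]: values and identifiers round-trip losslessly
#' (reals are written with 17 significant digits).
#'
#' @param m A `feature_matrix`, `association_data`, `similarity_matrix`, or a
#'   plain matrix with dimnames.
#' @param path Output file.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_matrix <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  v <- values_of(m)
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    stop("matrix must carry row and column identifiers", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, mode = 2L) != 0L) {
    stop("destination not writable: ", path, call. = FALSE)
  }
  switch(format, tsv = write_tsv_matrix(v, path), mtx = write_mtx_matrix(v, path))
  invisible(path)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix view %d: %d features x %d drugs, %d nonzeros>\n",
              x$view_id, nrow(x$values), ncol(x$values), sum(x$values != 0)))
  invisible(x)
}

#' @export
print.association_data <- function(x, ...) {
  cat(sprintf("<association_data: %d drugs x %d diseases, %d known associations>\n",
              nrow(x$Y), ncol(x$Y), sum(x$Y)))
  invisible(x)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix (%s): %d x %d>\n", x$kind,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.hyperparameters <- function(x, ...) {
  cat(sprintf(paste0("<hyperparameters: alpha = (%g, %g, %g, %g, %g), k = %d, ",
                     "max_iter = %d, tol = %g, seed = %d>\n"),
              x$alpha1, x$alpha2, x$alpha3, x$alpha4, x$alpha5, x$k_neighbors,
              x$max_iter, x$tol, x$seed))
  invisible(x)
}
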