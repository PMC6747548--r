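# Drug similarity views, k-NN affinity graphs, and graph Laplacians.

#' Cosine similarity between drugs of one feature view
#'
#' For each pair of drugs the similarity is the cosine of their feature
#' column vectors, x_i . x_j / (||x_i|| ||x_j||). For binary non-negative
#' features this lies in \[0, 1\] and equals the shared-feature overlap
#' normalized by the geometric mean of feature counts. Drugs with an all-zero
#' feature vector get similarity 0 to every drug, including themselves: a
#' featureless drug carries no information and the 0/0 case is defined away.
#'
#' @param X A `feature_matrix` (typically view 1, 2, or 3).
#' @return A `similarity_matrix` of kind `drug_view_<v>` over the drugs.
#' @export
cosine_similarity <- function(X) {
  V <- values_of(X)
  cp <- crossprod(V)
  nrm <- sqrt(diag(cp))
  R <- cp / outer(nrm, nrm)
  R[!is.finite(R)] <- 0
  # guard against rounding excursions above 1
  R[R > 1] <- 1
  view <- if (inherits(X, "feature_matrix")) X$view_id else 1L
  similarity_matrix(R, entity_ids = colnames(V),
                    kind = paste0("drug_view_", view))
}

#' Best-match set similarity between two disease sets
#'
#' Given the disease sets Di and Dj associated with two drugs and a
#' disease-disease semantic similarity matrix D, returns
#' \deqn{[\sum_{a \in Di} \max_{b \in Dj} D_{ab} +
#'        \sum_{b \in Dj} \max_{a \in Di} D_{ba}] / (|Di| + |Dj|),}
#' the symmetric best-match average: each disease is matched to its most
#' similar counterpart in the other set. Returns 0 if either set is empty
#' (a drug with no known diseases carries no association information).
#'
#' @param Di,Dj Integer indices (or character identifiers) of the two disease
#'   sets within `D`.
#' @param D A disease `similarity_matrix` or plain matrix.
#' @return A real in \[0, 1\].
#' @export
disease_set_similarity <- function(Di, Dj, D) {
  Dv <- values_of(D)
  if (length(Di) == 0L || length(Dj) == 0L) return(0)
  if (is.character(Di)) Di <- match(Di, rownames(Dv))
  if (is.character(Dj)) Dj <- match(Dj, rownames(Dv))
  if (anyNA(Di) || anyNA(Dj) || any(c(Di, Dj) < 1) ||
      any(c(Di, Dj) > nrow(Dv))) {
    stop("disease indices out of range", call. = FALSE)
  }
  sub <- Dv[Di, Dj, drop = FALSE]
  subT <- Dv[Dj, Di, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(subT, 1L, max))) /
    (length(Di) + length(Dj))
}

#' Association-profile similarity between all drug pairs (fourth view)
#'
#' Builds the fourth drug-drug similarity from the associated-disease profile
#' view: two drugs are similar when their associated diseases are semantically
#' similar, measured by [disease_set_similarity()] for every drug pair. The
#' diagonal is 1 for drugs with at least one association and 0 for drugs with
#' none; rows of association-free drugs are all zero.
#'
#' @param X4 The view-4 `feature_matrix` (diseases x drugs, binary).
#' @param D The disease `similarity_matrix`.
#' @return A `similarity_matrix` of kind `drug_view_4`.
#' @export
association_similarity <- function(X4, D) {
  V <- values_of(X4)
  Dv <- values_of(D)
  if (nrow(V) != nrow(Dv)) {
    stop("view-4 rows must match the disease similarity dimension",
         call. = FALSE)
  }
  n <- ncol(V)
  sets <- lapply(seq_len(n), function(j) which(V[, j] == 1))
  R <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (length(sets[[i]]) == 0L) next
    R[i, i] <- 1
    for (j in seq_len(n)) {
      if (j <= i || length(sets[[j]]) == 0L) next
      R[i, j] <- R[j, i] <- disease_set_similarity(sets[[i]], sets[[j]], Dv)
    }
  }
  dimnames(R) <- list(colnames(V), colnames(V))
  similarity_matrix(R, kind = "drug_view_4")
}

#' k-nearest-neighbour affinity graph and Laplacian
#'
#' Row i of the adjacency A has a 1 for each of the k entities most similar to
#' entity i (self excluded; ties broken by ascending index), so A is row-wise
#' and possibly asymmetric. U is the diagonal out-degree matrix with
#' U_ii = sum_j A_ij and L = U - A is the graph Laplacian used by the
#' smoothness penalties.
#'
#' @param S A `similarity_matrix` (or square numeric matrix).
#' @param k Number of neighbours, 1 <= k <= n - 1.
#' @return An object of class `graph_pair` with fields `A`, `U`, `L`, `k`.
#' @export
knn_graph <- function(S, k) {
  Sv <- values_of(S)
  n <- nrow(Sv)
  k <- as.integer(k)
  if (k < 1L || k >= n) {
    stop("k_neighbors must satisfy 1 <= k <= n - 1", call. = FALSE)
  }
  A <- matrix(0, n, n)
  idx <- seq_len(n)
  for (i in idx) {
    s <- Sv[i, ]
    s[i] <- -Inf
    nb <- order(-s, idx)[seq_len(k)]
    A[i, nb] <- 1
  }
  dimnames(A) <- dimnames(Sv)
  U <- diag(rowSums(A), n)
  dimnames(U) <- dimnames(A)
  structure(list(A = A, U = U, L = U - A, k = k), class = "graph_pair")
}

#' @export
print.graph_pair <- function(x, ...) {
  cat(sprintf("<graph_pair: %d nodes, k = %d, %s>\n", nrow(x$A), x$k,
              if (isTRUE(all.equal(x$A, t(x$A)))) "symmetric" else "asymmetric"))
  invisible(x)
}
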