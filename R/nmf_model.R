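# The multi-view NMF association model: objective, multiplicative updates,
# and the fitting loop.
#
# Minimized objective (all factors constrained non-negative):
#   ||M .* (F - Y)||_F^2                          masked reconstruction of Y
#   + a1 * sum_v ||X(v) - W(v) H(v)||_F^2         per-view factorization
#   + a2 * sum_{w != v} tr(H(v)' H(w))            diversity (12 ordered pairs)
#   + a3 * sum_v ||F - H(v)'||_F^2                score/projection consistency
#   + a4 * (sum_v tr(F' L(v) F) + tr(F Ld F'))    drug + disease smoothness
#   + a5 * ||F||_1                                sparsity
# F is Nr x Nd, H(v) is Nd x Nr, W(v) is d_v x Nd.

graphs_of <- function(g) {
  if (inherits(g, "graph_pair")) return(g)
  stop("expected a graph_pair", call. = FALSE)
}

#' Evaluate the model objective with a per-term breakdown
#'
#' @param F Score matrix, drugs x diseases, non-negative.
#' @param H List of latent matrices H(v), each diseases x drugs.
#' @param W List of basis matrices W(v), each d_v x diseases.
#' @param X List of feature views (matrices or `feature_matrix` objects),
#'   same length as `H`.
#' @param Y,M Association matrix and observation mask (drugs x diseases);
#'   `M` defaults to `Y`.
#' @param drug_graphs List of `graph_pair` objects over drugs, one per view.
#' @param disease_graph `graph_pair` over diseases.
#' @param hp A [hyperparameters()] object.
#' @return A list with `total` and a named numeric `terms` vector
#'   (`loss`, `reconstruction`, `diversity`, `consistency`, `smoothness`,
#'   `sparsity`).
#' @export
objective_value <- function(F, H, W, X, Y, M = Y, drug_graphs, disease_graph,
                            hp = hyperparameters()) {
  Xv <- lapply(X, values_of)
  nv <- length(Xv)
  stopifnot(length(H) == nv, length(W) == nv, length(drug_graphs) == nv)
  loss <- sum((M * (F - Y))^2)
  recon <- sum(vapply(seq_len(nv), function(v) {
    sum((Xv[[v]] - W[[v]] %*% H[[v]])^2)
  }, numeric(1)))
  dive <- 0
  for (v in seq_len(nv)) {
    for (w in seq_len(nv)) {
      if (w != v) dive <- dive + sum(H[[v]] * H[[w]])
    }
  }
  consist <- sum(vapply(seq_len(nv), function(v) sum((F - t(H[[v]]))^2),
                        numeric(1)))
  smooth <- sum(vapply(seq_len(nv), function(v) {
    sum(diag(crossprod(F, graphs_of(drug_graphs[[v]])$L %*% F)))
  }, numeric(1)))
  smooth <- smooth + sum(diag(F %*% graphs_of(disease_graph)$L %*% t(F)))
  sparsity <- sum(abs(F))
  terms <- c(loss = loss, reconstruction = hp$alpha1 * recon,
             diversity = hp$alpha2 * dive, consistency = hp$alpha3 * consist,
             smoothness = hp$alpha4 * smooth, sparsity = hp$alpha5 * sparsity)
  list(total = sum(terms), terms = terms)
}

#' Multiplicative update of the score matrix F
#'
#' Elementwise rule derived from the KKT conditions of the F-subproblem:
#' \deqn{F \leftarrow F \odot
#'   \frac{2 M \odot Y + 2\alpha_3 \sum_v H(v)^T + 2\alpha_4 \sum_v A(v) F
#'         + 2\alpha_4 F A_d}
#'        {2 M \odot F + 8\alpha_3 F + 2\alpha_4 \sum_v U(v) F
#'         + 2\alpha_4 F U_d + \alpha_5 B + \epsilon}}
#' with B the all-ones matrix. Non-negativity is preserved and zero entries
#' stay zero. With `hp$literal_f_denominator = TRUE` the consistency term in
#' the denominator is the bare `8F` of the printed rule instead of
#' `8*alpha3*F`.
#'
#' @inheritParams objective_value
#' @return The updated score matrix.
#' @export
update_F <- function(F, H, Y, M = Y, drug_graphs, disease_graph,
                     hp = hyperparameters()) {
  Ad <- graphs_of(disease_graph)$A
  Ud <- graphs_of(disease_graph)$U
  sumHt <- Reduce(`+`, lapply(H, t))
  sumAF <- Reduce(`+`, lapply(drug_graphs, function(g) graphs_of(g)$A %*% F))
  sumUF <- Reduce(`+`, lapply(drug_graphs, function(g) graphs_of(g)$U %*% F))
  num <- 2 * (M * Y) + 2 * hp$alpha3 * sumHt + 2 * hp$alpha4 * sumAF +
    2 * hp$alpha4 * (F %*% Ad)
  consist_den <- if (hp$literal_f_denominator) 8 * F else
    2 * length(H) * hp$alpha3 * F
  den <- 2 * (M * F) + consist_den + 2 * hp$alpha4 * sumUF +
    2 * hp$alpha4 * (F %*% Ud) + hp$alpha5 + hp$epsilon
  F * num / den
}

#' Multiplicative update of one latent matrix H(v)
#'
#' \deqn{H(v) \leftarrow H(v) \odot
#'   \frac{2\alpha_1 W(v)^T X(v) + 2\alpha_3 F^T}
#'        {2\alpha_1 W(v)^T W(v) H(v) + \alpha_2 \sum_{w \ne v} H(w)
#'         + 2\alpha_3 H(v) + \epsilon}}
#' The diversity term in the denominator pushes the view-v representation
#' away from the other views' representations.
#'
#' @inheritParams objective_value
#' @param v View index to update.
#' @return The updated H(v) matrix.
#' @export
update_H <- function(H, v, F, W, X, hp = hyperparameters()) {
  Xv <- values_of(X[[v]])
  sum_other <- if (length(H) > 1L) Reduce(`+`, H[-v]) else 0
  num <- 2 * hp$alpha1 * crossprod(W[[v]], Xv) + 2 * hp$alpha3 * t(F)
  den <- 2 * hp$alpha1 * (crossprod(W[[v]]) %*% H[[v]]) +
    hp$alpha2 * sum_other + 2 * hp$alpha3 * H[[v]] + hp$epsilon
  H[[v]] * num / den
}

#' Multiplicative update of one basis matrix W(v)
#'
#' The classical non-negative factorization basis update,
#' \deqn{W(v) \leftarrow W(v) \odot
#'   \frac{X(v) H(v)^T}{W(v) H(v) H(v)^T + \epsilon}.}
#'
#' @inheritParams update_H
#' @return The updated W(v) matrix.
#' @export
update_W <- function(W, v, H, X, hp = hyperparameters()) {
  Xv <- values_of(X[[v]])
  num <- Xv %*% t(H[[v]])
  den <- W[[v]] %*% tcrossprod(H[[v]]) + hp$epsilon
  W[[v]] * num / den
}

#' Fit the multi-view NMF association model
#'
#' Builds the four drug similarity views (cosine for views 1-3,
#' association-profile similarity for view 4), the k-NN graphs over drugs and
#' diseases, initializes all factors uniform(0,1) with `hp$seed`, and iterates
#' the multiplicative updates in the order F, then H(v) for v = 1..4, then
#' W(v) for v = 1..4, until the relative objective change drops below
#' `hp$tol` or `hp$max_iter` sweeps are reached.
#'
#' @param X List of four `feature_matrix` views with identical `drug_ids`;
#'   view 4 must be the transpose of the (training) association matrix.
#' @param Y An `association_data` object.
#' @param D The disease `similarity_matrix`.
#' @param hp A [hyperparameters()] object.
#' @param trace_terms If `TRUE`, record the per-term objective breakdown at
#'   every iteration in the fit trace.
#' @return An object of class `divepred_model` with fields `F` (score matrix
#'   with drug/disease dimnames), `H`, `W`, `hp`, `similarities` (R1..R4),
#'   `drug_graphs`, `disease_graph`, `Y` (training associations), and `trace`
#'   (class `fit_trace`: `objective_per_iter`, `term_values_per_iter`,
#'   `iterations_run`, `converged`).
#' @examples
#' dat <- generate_dataset(synthetic_spec(n_drugs = 15, n_diseases = 10,
#'   feature_dims = c(20, 25, 30), latent_rank = 2,
#'   association_density = 0.1, seed = 1))
#' fit <- divepred_fit(dat$X, dat$Y, dat$D,
#'   hyperparameters(max_iter = 50, k_neighbors = 3))
#' head(predict(fit, dat$Y$drug_ids[1]))
#' @export
divepred_fit <- function(X, Y, D, hp = hyperparameters(),
                         trace_terms = FALSE) {
  stopifnot(length(X) == 4L)
  X <- lapply(seq_along(X), function(v) {
    if (inherits(X[[v]], "feature_matrix")) X[[v]] else
      feature_matrix(X[[v]], view_id = v)
  })
  drug_ids <- X[[1L]]$drug_ids
  for (v in 2:4) {
    if (!identical(X[[v]]$drug_ids, drug_ids)) {
      stop("all feature views must share the same drug identifiers",
           call. = FALSE)
    }
  }
  if (!inherits(Y, "association_data")) Y <- association_data(Y)
  if (!identical(Y$drug_ids, drug_ids)) {
    stop("association drug identifiers must match the feature views",
         call. = FALSE)
  }
  if (!inherits(D, "similarity_matrix")) D <- similarity_matrix(D)
  if (!identical(D$entity_ids, Y$disease_ids)) {
    stop("disease similarity identifiers must match the association columns",
         call. = FALSE)
  }
  if (nrow(X[[4L]]$values) != length(Y$disease_ids)) {
    stop("view 4 must be diseases x drugs", call. = FALSE)
  }
  hp <- validate_hyperparameters(hp)
  Nr <- length(drug_ids)
  Nd <- length(Y$disease_ids)
  if (hp$k_neighbors >= min(Nr, Nd)) {
    stop("k_neighbors must be smaller than the number of drugs and diseases",
         call. = FALSE)
  }

  R <- vector("list", 4L)
  for (v in 1:3) R[[v]] <- cosine_similarity(X[[v]])
  R[[4L]] <- association_similarity(X[[4L]], D)
  drug_graphs <- lapply(R, knn_graph, k = hp$k_neighbors)
  disease_graph <- knn_graph(D, k = hp$k_neighbors)

  Xv <- lapply(X, function(x) x$values)
  set.seed(hp$seed)
  F <- matrix(stats::runif(Nr * Nd), Nr, Nd)
  H <- lapply(1:4, function(v) matrix(stats::runif(Nd * Nr), Nd, Nr))
  W <- lapply(1:4, function(v) {
    matrix(stats::runif(nrow(Xv[[v]]) * Nd), nrow(Xv[[v]]), Nd)
  })

  Ymat <- Y$Y
  Mmat <- Y$M
  objs <- numeric(hp$max_iter)
  terms <- if (trace_terms) matrix(NA_real_, hp$max_iter, 6L) else NULL
  prev <- objective_value(F, H, W, Xv, Ymat, Mmat, drug_graphs, disease_graph,
                          hp)$total
  converged <- FALSE
  it <- 0L
  while (it < hp$max_iter) {
    it <- it + 1L
    F <- update_F(F, H, Ymat, Mmat, drug_graphs, disease_graph, hp)
    for (v in 1:4) H[[v]] <- update_H(H, v, F, W, Xv, hp)
    for (v in 1:4) W[[v]] <- update_W(W, v, H, Xv, hp)
    ob <- objective_value(F, H, W, Xv, Ymat, Mmat, drug_graphs, disease_graph,
                          hp)
    objs[it] <- ob$total
    if (trace_terms) terms[it, ] <- ob$terms
    if (!is.finite(ob$total)) {
      stop("objective became non-finite at iteration ", it,
           "; check inputs and hyperparameters", call. = FALSE)
    }
    if (abs(prev - ob$total) < hp$tol * max(abs(prev), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- ob$total
  }
  objs <- objs[seq_len(it)]
  if (trace_terms) {
    terms <- terms[seq_len(it), , drop = FALSE]
    colnames(terms) <- c("loss", "reconstruction", "diversity", "consistency",
                         "smoothness", "sparsity")
  }
  dimnames(F) <- list(drug_ids, Y$disease_ids)
  trace <- structure(
    list(objective_per_iter = objs, term_values_per_iter = terms,
         iterations_run = it, converged = converged),
    class = "fit_trace"
  )
  structure(
    list(F = F, H = H, W = W, hp = hp, similarities = R,
         drug_graphs = drug_graphs, disease_graph = disease_graph, Y = Y,
         trace = trace),
    class = "divepred_model"
  )
}

#' Rank candidate diseases for one drug
#'
#' Diseases are ordered by their fitted association score, highest first;
#' ties are broken by ascending disease index. Diseases whose association
#' with the drug was in the training data are flagged in the `known` column.
#'
#' @param object A fitted `divepred_model`.
#' @param drug_id Drug identifier (or integer row index).
#' @param ... Unused.
#' @return A data frame with columns `rank`, `disease_id`, `score`, `known`.
#' @export
predict.divepred_model <- function(object, drug_id, ...) {
  i <- if (is.character(drug_id)) match(drug_id, rownames(object$F))
       else as.integer(drug_id)
  if (is.na(i) || i < 1L || i > nrow(object$F)) {
    stop("unknown drug identifier: ", drug_id, call. = FALSE)
  }
  scores <- object$F[i, ]
  ord <- order(-scores, seq_along(scores))
  data.frame(
    rank = seq_along(ord),
    disease_id = colnames(object$F)[ord],
    score = unname(scores[ord]),
    known = unname(object$Y$Y[i, ord] == 1),
    row.names = NULL
  )
}

#' @export
print.divepred_model <- function(x, ...) {
  cat(sprintf(paste0("<divepred_model: %d drugs x %d diseases, %d iterations",
                     " (%s), final objective %.6g>\n"),
              nrow(x$F), ncol(x$F), x$trace$iterations_run,
              if (x$trace$converged) "converged" else "max_iter reached",
              utils::tail(x$trace$objective_per_iter, 1)))
  invisible(x)
}

#' @export
print.fit_trace <- function(x, ...) {
  cat(sprintf("<fit_trace: %d iterations, converged = %s>\n",
              x$iterations_run, x$converged))
  invisible(x)
}
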