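# Independent brute-force oracles and small fixture builders. Oracles are
# written as plain loops, deliberately sharing no code with the package.

# Eq.-style best-match set similarity by exhaustive double loop over all
# (a, b) disease pairs.
oracle_set_similarity <- function(Di, Dj, D) {
  if (length(Di) == 0 || length(Dj) == 0) return(0)
  s1 <- 0
  for (a in Di) {
    best <- -Inf
    for (b in Dj) best <- max(best, D[a, b])
    s1 <- s1 + best
  }
  s2 <- 0
  for (b in Dj) {
    best <- -Inf
    for (a in Di) best <- max(best, D[b, a])
    s2 <- s2 + best
  }
  (s1 + s2) / (length(Di) + length(Dj))
}

# O(n^2) Mann-Whitney concordance with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold sweep over descending unique scores, step-interpolated
# precision-recall area.
oracle_aupr <- function(scores, labels) {
  P <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (th in thresholds) {
    keep <- scores >= th
    tp <- sum(labels[keep] == 1)
    fp <- sum(labels[keep] == 0)
    recall <- tp / P
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Top-k adjacency by explicit per-row sort (ties by ascending index).
oracle_knn <- function(S, k) {
  n <- nrow(S)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-S[i, others], others)]
    A[i, ord[seq_len(k)]] <- 1
  }
  A
}

# Naive elementwise evaluation of the full objective (scalar loops).
oracle_objective <- function(F, H, W, X, Y, M, A_list, Ad, hp) {
  n_views <- length(X)
  loss <- 0
  for (i in seq_len(nrow(F))) {
    for (j in seq_len(ncol(F))) {
      loss <- loss + (M[i, j] * (F[i, j] - Y[i, j]))^2
    }
  }
  recon <- 0
  for (v in seq_len(n_views)) {
    E <- X[[v]] - W[[v]] %*% H[[v]]
    recon <- recon + sum(E * E)
  }
  dive <- 0
  for (v in seq_len(n_views)) {
    for (w in seq_len(n_views)) {
      if (w == v) next
      dive <- dive + sum(diag(t(H[[v]]) %*% H[[w]]))
    }
  }
  consist <- 0
  for (v in seq_len(n_views)) consist <- consist + sum((F - t(H[[v]]))^2)
  smooth <- 0
  for (v in seq_len(n_views)) {
    A <- A_list[[v]]
    U <- diag(rowSums(A), nrow(A))
    smooth <- smooth + sum(diag(t(F) %*% (U - A) %*% F))
  }
  Ud <- diag(rowSums(Ad), nrow(Ad))
  smooth <- smooth + sum(diag(F %*% (Ud - Ad) %*% t(F)))
  loss + hp$alpha1 * recon + hp$alpha2 * dive + hp$alpha3 * consist +
    hp$alpha4 * smooth + hp$alpha5 * sum(abs(F))
}

# Classical multiplicative NMF updates (Lee-Seung), no stabilizer.
oracle_nmf_H <- function(X, W, H) H * crossprod(W, X) / (crossprod(W) %*% H)
oracle_nmf_W <- function(X, W, H) W * (X %*% t(H)) / (W %*% tcrossprod(H))

# Small random fitting problem with typed inputs and prebuilt graphs.
tiny_problem <- function(seed = 1, Nr = 8, Nd = 6, dims = c(10, 12, 14),
                         k = 2) {
  set.seed(seed)
  drug_ids <- sprintf("r%02d", seq_len(Nr))
  disease_ids <- sprintf("d%02d", seq_len(Nd))
  X <- lapply(1:3, function(v) {
    m <- matrix(rbinom(dims[v] * Nr, 1, 0.3), dims[v], Nr,
                dimnames = list(sprintf("f%d_%02d", v, seq_len(dims[v])),
                                drug_ids))
    feature_matrix(m, view_id = v)
  })
  Y <- matrix(0, Nr, Nd, dimnames = list(drug_ids, disease_ids))
  Y[sample(Nr * Nd, round(0.2 * Nr * Nd))] <- 1
  X[[4]] <- feature_matrix(t(Y), view_id = 4)
  P <- matrix(runif(3 * Nd), 3, Nd)
  D <- crossprod(P) / outer(sqrt(colSums(P^2)), sqrt(colSums(P^2)))
  D <- pmin((D + t(D)) / 2, 1)
  dimnames(D) <- list(disease_ids, disease_ids)
  D <- similarity_matrix(D, kind = "disease")
  R <- c(lapply(X[1:3], cosine_similarity),
         list(association_similarity(X[[4]], D)))
  list(
    X = X, Xv = lapply(X, function(x) x$values),
    Y = association_data(Y), Ymat = Y, D = D,
    drug_graphs = lapply(R, knn_graph, k = k),
    disease_graph = knn_graph(D, k = k),
    drug_ids = drug_ids, disease_ids = disease_ids
  )
}

# Random non-negative factors matching a tiny_problem.
tiny_factors <- function(prob, seed = 1) {
  Nr <- nrow(prob$Ymat)
  Nd <- ncol(prob$Ymat)
  set.seed(seed)
  list(
    F = matrix(runif(Nr * Nd), Nr, Nd),
    H = lapply(1:4, function(v) matrix(runif(Nd * Nr), Nd, Nr)),
    W = lapply(1:4, function(v) {
      matrix(runif(nrow(prob$Xv[[v]]) * Nd), nrow(prob$Xv[[v]]), Nd)
    })
  )
}

# Elementwise complementarity residuals of the three subproblems at the
# current factors (the quantities the multiplicative updates drive to zero).
kkt_residuals <- function(F, H, W, Xv, Y, M, drug_graphs, disease_graph, hp) {
  sumHt <- Reduce(`+`, lapply(H, t))
  sumLF <- Reduce(`+`, lapply(drug_graphs, function(g) g$L %*% F))
  rF <- max(abs((2 * (M * (F - Y)) + 2 * hp$alpha3 * (4 * F - sumHt) +
                   2 * hp$alpha4 * (sumLF + F %*% disease_graph$L) +
                   hp$alpha5) * F))
  rH <- rW <- 0
  for (v in seq_along(H)) {
    gH <- 2 * hp$alpha1 * (crossprod(W[[v]]) %*% H[[v]] -
                             crossprod(W[[v]], Xv[[v]])) +
      hp$alpha2 * Reduce(`+`, H[-v]) + 2 * hp$alpha3 * (H[[v]] - t(F))
    rH <- max(rH, max(abs(gH * H[[v]])))
    gW <- 2 * hp$alpha1 * (W[[v]] %*% tcrossprod(H[[v]]) -
                             Xv[[v]] %*% t(H[[v]]))
    rW <- max(rW, max(abs(gW * W[[v]])))
  }
  c(F = rF, H = rH, W = rW)
}
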