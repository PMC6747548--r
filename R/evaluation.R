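# Per-drug cross-validation protocol and ranking metrics.

#' Partition the known associations into cross-validation folds
#'
#' The known (drug, disease) pairs are randomly divided into `n_folds`
#' near-equal subsets (sizes differ by at most one), reproducibly by seed.
#'
#' @param Y An `association_data` object.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return An object of class `cv_folds`: a data frame with columns
#'   `drug`, `disease` (integer indices), `drug_id`, `disease_id`, `fold`,
#'   plus `n_folds` and `seed` attributes.
#' @export
make_cv_folds <- function(Y, n_folds = 5L, seed = 1L) {
  if (!inherits(Y, "association_data")) Y <- association_data(Y)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  pos <- which(Y$Y == 1)
  if (length(pos) < n_folds) {
    stop("fewer known associations than folds", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample(pos)
  fold <- rep(seq_len(n_folds), length.out = length(perm))
  drug <- ((perm - 1L) %% nrow(Y$Y)) + 1L
  dis <- ((perm - 1L) %/% nrow(Y$Y)) + 1L
  out <- data.frame(
    drug = drug, disease = dis,
    drug_id = Y$drug_ids[drug], disease_id = Y$disease_ids[dis],
    fold = fold, row.names = NULL
  )
  structure(out, n_folds = n_folds, seed = as.integer(seed),
            class = c("cv_folds", "data.frame"))
}

#' Area under the ROC curve of a ranked candidate list
#'
#' Computed as the Mann-Whitney statistic with half credit for tied scores,
#' equivalent to the trapezoidal area under the TPR-vs-FPR curve swept over
#' all score thresholds.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels, same length.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  check_score_labels(scores, labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0L || nn == 0L) {
    stop("AUC needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Built by a threshold sweep over descending unique scores with step
#' interpolation (each recall increment contributes at the precision reached
#' at that threshold); tied scores enter together.
#'
#' @inheritParams auc_roc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(scores, labels) {
  check_score_labels(scores, labels)
  P <- sum(labels == 1)
  if (P == 0L) stop("AUPR needs at least one positive", call. = FALSE)
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  # indices where a threshold group (tied scores) ends
  ends <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[ends]
  n_ret <- ends
  recall <- tp / P
  precision <- tp / n_ret
  sum(diff(c(0, recall)) * precision)
}

#' Recall among the top-k ranked candidates
#'
#' The fraction of all positives found in the top k positions when candidates
#' are sorted by descending score (ties broken by ascending index).
#'
#' @inheritParams auc_roc
#' @param k Cutoff, 1 <= k <= length(scores).
#' @return Recall at k, in \[0, 1\].
#' @export
recall_at_k <- function(scores, labels, k) {
  check_score_labels(scores, labels)
  n <- length(scores)
  if (k < 1L || k > n) stop("k must lie in 1..length(scores)", call. = FALSE)
  P <- sum(labels == 1)
  if (P == 0L) stop("recall@k needs at least one positive", call. = FALSE)
  top <- order(-scores, seq_len(n))[seq_len(k)]
  sum(labels[top] == 1) / P
}

check_score_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must be binary and scores non-missing", call. = FALSE)
  }
  invisible(NULL)
}

#' Run the per-drug cross-validation protocol
#'
#' For each fold, the fold's positive pairs are removed from the association
#' matrix, its mask, and the view-4 feature matrix (whose similarity is then
#' recomputed from the masked associations inside the fit); the model is
#' fitted on the training data only. For every drug with at least one test
#' positive, the test positives are ranked against all of that drug's
#' unmarked diseases (training positives are excluded from the candidate
#' set), and per-drug AUC and AUPR are computed from that ranking. The
#' overall metrics are means over all (drug, fold) evaluations pooled across
#' folds.
#'
#' @param X List of four `feature_matrix` views (view 4 is replaced
#'   internally by the masked training associations in every fold).
#' @param Y An `association_data` object with all known associations.
#' @param D Disease `similarity_matrix`.
#' @param hp A [hyperparameters()] object used for every fold's fit.
#' @param folds A `cv_folds` object from [make_cv_folds()].
#' @param ks Integer cutoffs for recall@k, evaluated per drug with k capped
#'   at the drug's candidate count. Default: multiples of 30 up to 240 that
#'   do not exceed the number of diseases, or `min(10, Nd - 1)` if none do.
#' @param scorer Scoring backend: a `function(X_train, Y_train, D, hp)`
#'   returning a drugs x diseases score matrix. Defaults to fitting the NMF
#'   model and returning its `F`. Injectable so the protocol can be audited
#'   with reference scorers.
#' @param verbose Print per-fold progress to stderr.
#' @return An object of class `ranking_metrics`: list with `per_drug` (data
#'   frame of drug, fold, auc, aupr), `mean_auc`, `mean_aupr`, `recall_at_k`
#'   (named vector averaged over drug evaluations), `leakage_violations`
#'   (count of test positives found unmasked during training; always 0), and
#'   `n_evaluations`.
#' @export
run_cv <- function(X, Y, D, hp = hyperparameters(), folds, ks = NULL,
                   scorer = NULL, verbose = FALSE) {
  if (!inherits(Y, "association_data")) Y <- association_data(Y)
  if (!inherits(folds, "cv_folds")) stop("folds must come from make_cv_folds",
                                         call. = FALSE)
  Nr <- nrow(Y$Y)
  Nd <- ncol(Y$Y)
  if (is.null(ks)) {
    ks <- seq(30L, 240L, by = 30L)
    ks <- ks[ks <= Nd]
    if (!length(ks)) ks <- min(10L, Nd - 1L)
  }
  ks <- sort(unique(as.integer(ks)))
  if (is.null(scorer)) {
    scorer <- function(X_train, Y_train, D, hp) {
      divepred_fit(X_train, Y_train, D, hp)$F
    }
  }
  disease_ids <- Y$disease_ids
  leakage <- 0L
  rows <- list()
  rec_rows <- list()
  for (f in sort(unique(folds$fold))) {
    test <- folds[folds$fold == f, , drop = FALSE]
    Ytr <- Y$Y
    Ytr[cbind(test$drug, test$disease)] <- 0
    Y_train <- association_data(Ytr, Y$drug_ids, Y$disease_ids)
    X_train <- X
    X_train[[4L]] <- feature_matrix(t(Ytr), view_id = 4L)
    # leakage audit: every test positive must be masked everywhere
    leakage <- leakage +
      sum(Y_train$Y[cbind(test$drug, test$disease)] != 0) +
      sum(Y_train$M[cbind(test$drug, test$disease)] != 0) +
      sum(X_train[[4L]]$values[cbind(test$disease, test$drug)] != 0)
    if (verbose) message("fold ", f, ": fitting on ",
                         sum(Ytr), " training associations")
    F <- scorer(X_train, Y_train, D, hp)
    stopifnot(is.matrix(F), nrow(F) == Nr, ncol(F) == Nd)
    for (u in sort(unique(test$drug))) {
      test_dis <- test$disease[test$drug == u]
      train_pos <- which(Ytr[u, ] == 1)
      cand <- setdiff(seq_len(Nd), train_pos)
      labels <- as.integer(cand %in% test_dis)
      if (length(cand) == 0L || all(labels == 1L)) {
        warning("drug ", Y$drug_ids[u], " has no negative candidates in fold ",
                f, "; skipped", call. = FALSE)
        next
      }
      scores <- F[u, cand]
      rows[[length(rows) + 1L]] <- data.frame(
        drug = u, drug_id = Y$drug_ids[u], fold = f,
        n_test_pos = length(test_dis), n_candidates = length(cand),
        auc = auc_roc(scores, labels), aupr = aupr(scores, labels)
      )
      rec_rows[[length(rec_rows) + 1L]] <- vapply(ks, function(k) {
        recall_at_k(scores, labels, min(k, length(cand)))
      }, numeric(1))
    }
  }
  per_drug <- do.call(rbind, rows)
  rec <- if (length(rec_rows)) colMeans(do.call(rbind, rec_rows)) else
    rep(NA_real_, length(ks))
  names(rec) <- paste0("k", ks)
  structure(
    list(per_drug = per_drug,
         mean_auc = mean(per_drug$auc), mean_aupr = mean(per_drug$aupr),
         recall_at_k = rec, leakage_violations = leakage,
         n_evaluations = nrow(per_drug)),
    class = "ranking_metrics"
  )
}

#' @export
print.ranking_metrics <- function(x, ...) {
  cat(sprintf(paste0("<ranking_metrics: %d drug evaluations, mean AUC %.4f, ",
                     "mean AUPR %.4f>\n"),
              x$n_evaluations, x$mean_auc, x$mean_aupr))
  rec <- sprintf("%s = %.3f", names(x$recall_at_k), x$recall_at_k)
  cat("  recall@k:", paste(rec, collapse = ", "), "\n")
  invisible(x)
}
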