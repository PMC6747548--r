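# Seeded generator of synthetic datasets with the multi-view low-rank
# structure the model assumes: shared latent drug factors expressed in every
# feature view, associations planted from the drug-disease latent product,
# and a disease similarity derived from the disease factors.

#' Specification for a synthetic dataset
#'
#' Defaults describe a desk-scale instance: 60 drugs x 40 diseases with three
#' binary feature views of 100/150/200 features (standing in for the
#' 881/1426/4447-dimensional real views), rank-4 planted structure, and an
#' association density of 0.006 matching the real data's sparsity (3051
#' associations among 763 x 681 pairs).
#'
#' @param n_drugs,n_diseases Numbers of drugs and diseases.
#' @param feature_dims Integer vector of length 3: feature counts of views
#'   1-3 (view 4 is always the diseases x drugs association profile).
#' @param latent_rank Rank of the planted structure; must be smaller than
#'   both `n_drugs` and `n_diseases`.
#' @param association_density Fraction of (drug, disease) pairs planted as
#'   known associations.
#' @param feature_density Fraction of ones per feature row in views 1-3.
#' @param noise_rate Independent bit-flip probability applied to each feature
#'   view (the associations themselves are placed exactly).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 60L, n_diseases = 40L,
                           feature_dims = c(100L, 150L, 200L),
                           latent_rank = 4L, association_density = 0.006,
                           feature_density = 0.1, noise_rate = 0.01,
                           seed = 1L) {
  obj <- structure(
    list(n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
         feature_dims = as.integer(feature_dims),
         latent_rank = as.integer(latent_rank),
         association_density = association_density,
         feature_density = feature_density, noise_rate = noise_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(obj)
}

#' @rdname synthetic_spec
#' @param x A `synthetic_spec`.
#' @export
validate_synthetic_spec <- function(x) {
  if (x$n_drugs < 2L || x$n_diseases < 2L) {
    stop("need at least 2 drugs and 2 diseases", call. = FALSE)
  }
  if (length(x$feature_dims) != 3L || any(x$feature_dims < 1L)) {
    stop("feature_dims must be 3 positive integers", call. = FALSE)
  }
  if (x$latent_rank < 1L ||
      x$latent_rank >= min(x$n_drugs, x$n_diseases)) {
    stop("latent_rank must be in 1..min(n_drugs, n_diseases) - 1",
         call. = FALSE)
  }
  if (x$association_density <= 0 || x$association_density >= 1 ||
      x$feature_density <= 0 || x$feature_density >= 1) {
    stop("densities must lie in (0, 1)", call. = FALSE)
  }
  if (x$noise_rate < 0 || x$noise_rate >= 1) {
    stop("noise_rate must lie in [0, 1)", call. = FALSE)
  }
  n_pos <- round(x$association_density * x$n_drugs * x$n_diseases)
  if (n_pos < 1L) {
    stop("association_density too low: no positive pairs would be planted",
         call. = FALSE)
  }
  x
}

# latent factors with block structure: entity i loads strongly on factor
# (i - 1) mod rank plus a small uniform baseline on all factors
block_factors <- function(rank, n, baseline = 0.2, signal = 1) {
  G <- matrix(stats::runif(rank * n, 0, baseline), rank, n)
  G[cbind(((seq_len(n) - 1L) %% rank) + 1L, seq_len(n))] <-
    G[cbind(((seq_len(n) - 1L) %% rank) + 1L, seq_len(n))] + signal
  G
}

#' Generate a synthetic multi-view drug-disease dataset
#'
#' Draws block-structured non-negative latent drug factors G (rank x drugs)
#' and disease factors P (rank x diseases); plants exactly
#' `round(density * n_drugs * n_diseases)` associations at the largest
#' entries of the latent product t(G) P (ties broken by index); generates
#' each binary feature view from a view-specific non-negative loading of G,
#' binarized row-wise at the top `feature_density` fraction and then flipped
#' independently with `noise_rate` (shared latent signal plus view-specific
#' loadings and noise — the structure the diversity penalty exploits); and
#' builds the disease similarity D as the cosine similarity of the columns of
#' P, which is in \[0, 1\] with unit diagonal.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `X` (four `feature_matrix` views, view 4 the
#'   transposed associations), `Y` (`association_data`), `D` (disease
#'   `similarity_matrix`), `truth` (list: latent `G`, `P`, the latent `scores`
#'   matrix, and the planted `Y` matrix), and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  spec <- validate_synthetic_spec(spec)
  set.seed(spec$seed)
  Nr <- spec$n_drugs
  Nd <- spec$n_diseases
  r <- spec$latent_rank
  drug_ids <- sprintf("drug_%03d", seq_len(Nr))
  disease_ids <- sprintf("disease_%03d", seq_len(Nd))

  G <- block_factors(r, Nr)
  P <- block_factors(r, Nd)
  scores <- crossprod(G, P)

  n_pos <- round(spec$association_density * Nr * Nd)
  Y <- matrix(0, Nr, Nd, dimnames = list(drug_ids, disease_ids))
  Y[order(-scores, seq_along(scores))[seq_len(n_pos)]] <- 1

  X <- vector("list", 4L)
  for (v in 1:3) {
    dv <- spec$feature_dims[v]
    Q <- matrix(stats::runif(dv * r), dv, r)
    raw <- Q %*% G
    m <- max(1L, round(spec$feature_density * Nr))
    Xv <- matrix(0, dv, Nr)
    for (i in seq_len(dv)) {
      Xv[i, order(-raw[i, ], seq_len(Nr))[seq_len(m)]] <- 1
    }
    if (spec$noise_rate > 0) {
      flip <- matrix(stats::runif(dv * Nr) < spec$noise_rate, dv, Nr)
      Xv <- abs(Xv - flip)
    }
    dimnames(Xv) <- list(sprintf("v%d_f%03d", v, seq_len(dv)), drug_ids)
    X[[v]] <- feature_matrix(Xv, view_id = v)
  }
  X[[4L]] <- feature_matrix(t(Y), view_id = 4L)

  Dcp <- crossprod(P)
  nrm <- sqrt(diag(Dcp))
  D <- Dcp / outer(nrm, nrm)
  D <- pmin(D, 1)
  D <- (D + t(D)) / 2
  dimnames(D) <- list(disease_ids, disease_ids)

  list(
    X = X,
    Y = association_data(Y),
    D = similarity_matrix(D, kind = "disease"),
    truth = list(G = G, P = P, scores = scores, Y = Y),
    spec = spec
  )
}

#' Hide a fraction of the known associations
#'
#' Uniformly removes `ceiling(fraction * #positives)` known associations from
#' `Y` (and its mask), returning both the masked data and the held-out pairs.
#' Mirrors the test-fold masking of the cross-validation protocol.
#'
#' @param Y An `association_data` object.
#' @param fraction Fraction of positives to hide, in (0, 1).
#' @param seed Integer seed.
#' @return A list with `Y` (masked `association_data`) and `held_out` (data
#'   frame with columns `drug`, `disease`, `drug_id`, `disease_id`).
#' @export
hide_associations <- function(Y, fraction, seed = 1L) {
  if (!inherits(Y, "association_data")) Y <- association_data(Y)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  pos <- which(Y$Y == 1)
  n_hide <- ceiling(fraction * length(pos))
  set.seed(seed)
  hide <- if (length(pos) == 1L) pos else sample(pos, n_hide)
  Ym <- Y$Y
  Ym[hide] <- 0
  if (all(rowSums(Ym) == 0)) {
    warning("every drug lost all of its known associations", call. = FALSE)
  }
  drug <- ((hide - 1L) %% nrow(Ym)) + 1L
  dis <- ((hide - 1L) %/% nrow(Ym)) + 1L
  list(
    Y = association_data(Ym, Y$drug_ids, Y$disease_ids),
    held_out = data.frame(
      drug = drug, disease = dis,
      drug_id = Y$drug_ids[drug], disease_id = Y$disease_ids[dis],
      row.names = NULL
    )
  )
}
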