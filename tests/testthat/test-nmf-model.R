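# Tests of the objective, the three multiplicative updates, and the fitting
# loop on small seeded instances.

test_that("objective reduces to the masked loss in degenerate limits", {
  prob <- tiny_problem(seed = 1)
  Nr <- nrow(prob$Ymat); Nd <- ncol(prob$Ymat)
  zeroF <- matrix(0, Nr, Nd)
  zeroH <- lapply(1:4, function(v) matrix(0, Nd, Nr))
  zeroW <- lapply(1:4, function(v) matrix(0, nrow(prob$Xv[[v]]), Nd))
  zeroX <- lapply(prob$Xv, function(x) x * 0)
  hp <- hyperparameters()
  ob <- objective_value(zeroF, zeroH, zeroW, zeroX, prob$Ymat, prob$Ymat,
                        prob$drug_graphs, prob$disease_graph, hp)
  expect_equal(ob$total, sum(prob$Ymat))  # only the masked loss survives
  expect_equal(unname(ob$terms["loss"]), sum(prob$Ymat))

  hp0 <- hyperparameters(alpha1 = 0, alpha2 = 0, alpha3 = 0, alpha4 = 0,
                         alpha5 = 0)
  fac <- tiny_factors(prob, seed = 2)
  ob0 <- objective_value(prob$Ymat, fac$H, fac$W, prob$Xv, prob$Ymat,
                         prob$Ymat, prob$drug_graphs, prob$disease_graph, hp0)
  expect_equal(ob0$total, 0)  # F = Y, M = Y, all penalties off
})

test_that("objective matches the naive elementwise oracle", {
  for (s in 1:5) {
    prob <- tiny_problem(seed = s)
    fac <- tiny_factors(prob, seed = s + 10)
    hp <- hyperparameters(alpha1 = 0.7, alpha2 = 2, alpha3 = 0.3,
                          alpha4 = 0.2, alpha5 = 0.05)
    got <- objective_value(fac$F, fac$H, fac$W, prob$Xv, prob$Ymat,
                           prob$Ymat, prob$drug_graphs, prob$disease_graph,
                           hp)$total
    want <- oracle_objective(fac$F, fac$H, fac$W, prob$Xv, prob$Ymat,
                             prob$Ymat,
                             lapply(prob$drug_graphs, function(g) g$A),
                             prob$disease_graph$A, hp)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("score update matches a scalar evaluation on a 1x1 system", {
  # single drug, single disease, no graph terms
  no_graph <- structure(list(A = matrix(0, 1, 1), U = matrix(0, 1, 1),
                             L = matrix(0, 1, 1), k = 0L),
                        class = "graph_pair")
  hp <- hyperparameters(alpha3 = 0.4, alpha4 = 0.3, alpha5 = 0.2,
                        epsilon = 1e-12)
  F <- matrix(0.7); Y <- matrix(1); M <- Y
  H <- lapply(1:4, function(v) matrix(0.2 * v))
  Fn <- update_F(F, H, Y, M, drug_graphs = rep(list(no_graph), 4),
                 disease_graph = no_graph, hp = hp)
  num <- 2 * 1 * 1 + 2 * 0.4 * sum(0.2 * (1:4))
  den <- 2 * 1 * 0.7 + 8 * 0.4 * 0.7 + 0.2 + 1e-12
  expect_equal(Fn[1, 1], 0.7 * num / den, tolerance = 1e-14)
})

test_that("all three updates preserve non-negativity and lock zeros", {
  prob <- tiny_problem(seed = 3)
  fac <- tiny_factors(prob, seed = 4)
  hp <- hyperparameters()
  F <- fac$F; H <- fac$H; W <- fac$W
  F[1, 2] <- 0
  H[[2]][3, 1] <- 0
  W[[3]][2, 2] <- 0
  for (it in 1:5) {
    F <- update_F(F, H, prob$Ymat, prob$Ymat, prob$drug_graphs,
                  prob$disease_graph, hp)
    for (v in 1:4) H[[v]] <- update_H(H, v, F, W, prob$Xv, hp)
    for (v in 1:4) W[[v]] <- update_W(W, v, H, prob$Xv, hp)
    expect_gte(min(F, unlist(H), unlist(W)), 0)
    expect_identical(unname(F[1, 2]), 0)
    expect_identical(unname(H[[2]][3, 1]), 0)
    expect_identical(unname(W[[3]][2, 2]), 0)
  }
})

test_that("repeated score updates reach a fixed point of the update map", {
  prob <- tiny_problem(seed = 5)
  fac <- tiny_factors(prob, seed = 6)
  hp <- hyperparameters()
  F <- fac$F
  for (it in 1:20000) {
    F <- update_F(F, fac$H, prob$Ymat, prob$Ymat, prob$drug_graphs,
                  prob$disease_graph, hp)
  }
  Fn <- update_F(F, fac$H, prob$Ymat, prob$Ymat, prob$drug_graphs,
                 prob$disease_graph, hp)
  expect_lt(max(abs(Fn - F)), 1e-6)
})

test_that("basis update is a fixed point on an exact factorization", {
  set.seed(7)
  W <- list(matrix(runif(12, 0.5, 1), 4, 3))
  H <- list(matrix(runif(15, 0.5, 1), 3, 5))
  X <- list(W[[1]] %*% H[[1]])
  Wn <- update_W(W, 1, H, X, hyperparameters())
  expect_lt(max(abs(Wn - W[[1]])), 1e-10)
})

test_that("with penalties off the updates coincide with classical NMF", {
  # alpha2 = alpha3 = alpha4 = alpha5 = 0: the H update must equal the
  # classical coefficient rule H * (W'X) / (W'WH) and W the basis rule
  set.seed(8)
  X <- list(matrix(runif(6 * 9, 0.1, 1), 6, 9))
  W <- list(matrix(runif(6 * 3, 0.1, 1), 6, 3))
  H <- list(matrix(runif(3 * 9, 0.1, 1), 3, 9))
  hp <- hyperparameters(alpha1 = 1, alpha2 = 0, alpha3 = 0, alpha4 = 0,
                        alpha5 = 0)
  F_dummy <- matrix(0, 9, 3)  # unused when alpha3 = 0
  recon <- function() sum((X[[1]] - W[[1]] %*% H[[1]])^2)
  prev <- recon()
  for (it in 1:50) {
    Hn <- update_H(H, 1, F_dummy, W, X, hp)
    expect_equal(Hn, oracle_nmf_H(X[[1]], W[[1]], H[[1]]), tolerance = 1e-10)
    H[[1]] <- Hn
    Wn <- update_W(W, 1, H, X, hp)
    expect_equal(Wn, oracle_nmf_W(X[[1]], W[[1]], H[[1]]), tolerance = 1e-10)
    W[[1]] <- Wn
    cur <- recon()
    expect_lte(cur, prev * (1 + 1e-12))  # classical NMF monotonicity
    prev <- cur
  }
})

test_that("fitting with penalties off reproduces observed associations", {
  prob <- tiny_problem(seed = 9)
  hp <- hyperparameters(alpha1 = 0, alpha2 = 0, alpha3 = 0, alpha4 = 0,
                        alpha5 = 0, max_iter = 200, k_neighbors = 2)
  fit <- divepred_fit(prob$X, prob$Y, prob$D, hp)
  obs <- prob$Ymat == 1
  expect_lt(max(abs(fit$F[obs] - 1)), 1e-3)
})

test_that("fitting is deterministic under a fixed seed", {
  prob <- tiny_problem(seed = 10)
  hp <- hyperparameters(max_iter = 40, k_neighbors = 2, seed = 77)
  f1 <- divepred_fit(prob$X, prob$Y, prob$D, hp, trace_terms = TRUE)
  f2 <- divepred_fit(prob$X, prob$Y, prob$D, hp, trace_terms = TRUE)
  expect_identical(f1$F, f2$F)
  expect_identical(f1$trace$objective_per_iter, f2$trace$objective_per_iter)
  expect_identical(f1$trace$term_values_per_iter, f2$trace$term_values_per_iter)
})

test_that("objective is non-increasing during a fit on a small instance", {
  prob <- tiny_problem(seed = 11)
  hp <- hyperparameters(max_iter = 100, tol = 0, k_neighbors = 2)
  fit <- divepred_fit(prob$X, prob$Y, prob$D, hp)
  obj <- fit$trace$objective_per_iter
  expect_true(all(diff(obj) <= 1e-8 * abs(obj[-length(obj)])))
})

test_that("subproblem residuals shrink by orders of magnitude at convergence", {
  # complementarity products of the three subproblems: they decay towards 0
  # (sublinearly for boundary-bound entries, so the absolute H level at an
  # objective-change stop stays above the F/W levels)
  prob <- tiny_problem(seed = 12)
  hp <- hyperparameters(max_iter = 30000, tol = 1e-9, k_neighbors = 2)
  fac0 <- tiny_factors(prob, seed = hp$seed)
  r0 <- kkt_residuals(fac0$F, fac0$H, fac0$W, prob$Xv, prob$Ymat, prob$Ymat,
                      prob$drug_graphs, prob$disease_graph, hp)
  fit <- divepred_fit(prob$X, prob$Y, prob$D, hp)
  r1 <- kkt_residuals(unname(fit$F), fit$H, fit$W, prob$Xv, prob$Ymat,
                      prob$Ymat, prob$drug_graphs, prob$disease_graph, hp)
  expect_lt(r1["F"], 1e-5)
  expect_lt(r1["W"], 1e-4)
  expect_lt(r1["H"], r0["H"] / 100)
})

test_that("prediction ranks diseases by score with index tie-breaking", {
  prob <- tiny_problem(seed = 13)
  hp <- hyperparameters(max_iter = 10, k_neighbors = 2)
  fit <- divepred_fit(prob$X, prob$Y, prob$D, hp)
  fit$F[1, ] <- c(0.1, 0.9, 0.5, 0.2, 0.05, 0.3)
  p <- predict(fit, prob$drug_ids[1])
  expect_identical(p$disease_id[1:3], prob$disease_ids[c(2, 3, 6)])
  fit$F[2, ] <- rep(0.4, 6)
  p2 <- predict(fit, prob$drug_ids[2])
  expect_identical(p2$disease_id, prob$disease_ids)  # ties -> index order
  set.seed(99)
  fit$F[3, ] <- runif(6)
  p3 <- predict(fit, 3)
  expect_identical(match(p3$disease_id, prob$disease_ids),
                   order(-fit$F[3, ], seq_len(6)))
  expect_error(predict(fit, "nonexistent_drug"), "unknown drug")
  # known training associations are flagged
  pk <- predict(fit, prob$drug_ids[4])
  expect_identical(pk$known,
                   unname(prob$Ymat[4, match(pk$disease_id,
                                             prob$disease_ids)] == 1))
})

test_that("fit validates identifier consistency across inputs", {
  prob <- tiny_problem(seed = 14)
  Xbad <- prob$X
  v <- Xbad[[2]]$values
  colnames(v) <- rev(colnames(v))
  Xbad[[2]] <- feature_matrix(v, 2)
  expect_error(divepred_fit(Xbad, prob$Y, prob$D, hyperparameters()),
               "drug identifiers")
})
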