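test_that("pairwise-deletion correlations match a per-pair loop oracle", {
  q <- simulate_questionnaire(n_participants = 200, missing_rate = 0.1,
                              seed = 60)
  R <- pairwise_correlation(q$items)
  x <- q$items
  for (a in c(1, 5, 12)) for (b in c(2, 9, 24)) {
    ok <- !is.na(x[, a]) & !is.na(x[, b])
    expect_equal(R[a, b], cor(x[ok, a], x[ok, b]), tolerance = 1e-12)
  }
  # no missingness: identical to the full-sample correlation
  q0 <- simulate_questionnaire(n_participants = 100, missing_rate = 0,
                               seed = 61)
  expect_equal(unclass(pairwise_correlation(q0$items)), cor(q0$items),
               ignore_attr = TRUE)
  # a duplicated item correlates 1 with its copy
  dup <- cbind(q0$items, copy = q0$items[, 1])
  expect_equal(pairwise_correlation(dup)[1, 25], 1)
  # a pair with too few joint observations is an error naming the pair
  bad <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, paste0("it", 1:4)))
  bad[1:8, 1] <- NA; bad[9:10, 2] <- NA
  expect_error(pairwise_correlation(bad), "it1~it2")
})

test_that("graphical lasso handles the closed-form trivial cases", {
  # diagonal input: empty network
  net0 <- glasso_network(diag(8), n_effective = 100)
  expect_true(all(net0$weights == 0))
  # 2-block correlation: no between-block edges at any selected penalty
  S <- diag(10)
  S[1:5, 1:5] <- 0.6; S[6:10, 6:10] <- 0.6; diag(S) <- 1
  net <- glasso_network(S, n_effective = 500)
  expect_true(all(net$weights[1:5, 6:10] == 0))
  expect_gt(sum(net$weights[1:5, 1:5] != 0), 0)
})

test_that("the glasso solution satisfies the KKT optimality conditions", {
  # independent oracle: at the optimum of the L1-penalized likelihood,
  # W = Theta^{-1} with |W - S| <= rho off-diagonal, equality with matching
  # sign wherever Theta != 0
  q <- simulate_questionnaire(n_participants = 400, missing_rate = 0,
                              seed = 62)
  S <- unclass(pairwise_correlation(q$items))
  attributes(S)[c("n_pairwise", "n_effective", "repaired")] <- NULL
  rho <- 0.08
  f <- socialcpm:::glasso_cd(S, rho, S, matrix(0, 24, 24), FALSE, 1000, 1e-7)
  W <- f$w; Th <- f$theta
  expect_true(f$converged)
  # W inverts Theta
  expect_lt(max(abs(W %*% Th - diag(24))), 1e-3)
  off <- upper.tri(S)
  resid <- (W - S)[off]
  expect_true(all(abs(resid) <= rho + 1e-4))
  nz <- Th[off] != 0
  # active entries sit on the penalty boundary with the sign of Theta
  expect_true(all(abs(abs(resid[nz]) - rho) < 1e-4))
  expect_true(all(sign(resid[nz]) == sign(Th[off][nz])))
  # diagonal unpenalized: W matches S there
  expect_equal(unname(diag(W)), unname(diag(S)), tolerance = 1e-10)
})

test_that("Louvain communities respect obvious graph structure", {
  # two disconnected cliques
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 0.5; w[4:6, 4:6] <- 0.5; diag(w) <- 0
  memb <- louvain_communities(w, seed = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:3])), 1)
  expect_equal(length(unique(memb[4:6])), 1)
  # a single clique is one community
  w1 <- matrix(0.5, 4, 4); diag(w1) <- 0
  expect_equal(length(unique(louvain_communities(w1, seed = 1))), 1)
  # empty network: singletons, warned
  expect_warning(m0 <- louvain_communities(matrix(0, 3, 3), seed = 1),
                 "empty network")
  expect_equal(unname(m0), 1:3)
  # planted 3-community partial-correlation network
  q <- simulate_questionnaire(n_participants = 1000, missing_rate = 0,
                              seed = 63)
  net <- glasso_network(pairwise_correlation(q$items))
  memb3 <- louvain_communities(net, seed = 2)
  expect_gte(ari(memb3, q$membership), 0.9)
  # with orthogonal communities the glasso support concentrates within
  # communities (correlated latents induce true cross-community
  # conditional dependencies, so independence is needed for this check)
  q0 <- simulate_questionnaire(n_participants = 1000,
                               community_correlations = diag(3),
                               missing_rate = 0, seed = 63)
  net0 <- glasso_network(pairwise_correlation(q0$items))
  nz <- net0$weights != 0 & upper.tri(net0$weights)
  within <- outer(q0$membership, q0$membership, "==")
  expect_lt(sum(nz & !within) / max(sum(nz & within), 1), 0.2)
})

test_that("bootstrap EGA is reproducible and aggregates by medians", {
  q <- simulate_questionnaire(n_participants = 300, missing_rate = 0.05,
                              seed = 64)
  # n_boot = 1: the typical network is that replicate's network
  b1 <- bootega(q$items, n_boot = 1, seed = 7)
  set.seed((7 + 1) %% 2147483647)
  xb <- MASS::mvrnorm(300, mu = rep(0, 24),
                      Sigma = pairwise_correlation(q$items))
  net1 <- glasso_network(cor(xb), n_effective = 300)
  expect_equal(b1$typical_network, net1$weights, ignore_attr = TRUE)
  # determinism
  b2 <- bootega(q$items, n_boot = 5, seed = 7)
  b3 <- bootega(q$items, n_boot = 5, seed = 7)
  expect_identical(b2$typical_network, b3$typical_network)
  expect_identical(b2$membership, b3$membership)
  # typical network symmetric with zero diagonal; stability rows bounded
  expect_true(isSymmetric(b2$typical_network))
  expect_true(all(diag(b2$typical_network) == 0))
  expect_true(all(rowSums(b2$item_stability) <= 1 + 1e-12))
})

test_that("bootEGA recovers the planted community structure", {
  q <- simulate_questionnaire(n_participants = 1000, missing_rate = 0.1,
                              seed = 65)
  bg <- bootega(q$items, n_boot = 20, seed = 8)
  expect_equal(bg$n_communities, 3)
  expect_gte(ari(bg$membership, q$membership), 0.9)
  st <- bg$item_stability[cbind(seq_along(bg$membership), bg$membership)]
  expect_true(all(st >= 0.9))
  # item-stability rows sum to 1 up to replicate-failure mass
  expect_true(all(abs(rowSums(bg$item_stability) - 1) <= bg$n_failed / 20))
})

test_that("network scores weight items and standardize as specified", {
  q <- simulate_questionnaire(n_participants = 500, missing_rate = 0.1,
                              seed = 66)
  bg <- bootega(q$items, n_boot = 10, seed = 9)
  sc <- network_scores(q$items, bg)
  expect_equal(dim(sc), c(500, bg$n_communities))
  expect_equal(unname(colMeans(sc, na.rm = TRUE)), rep(0, 3),
               tolerance = 1e-10)
  expect_equal(unname(apply(sc, 2, sd, na.rm = TRUE)), rep(1, 3),
               tolerance = 1e-10)
  # uniform weighting with no missingness is the standardized item mean
  q0 <- simulate_questionnaire(n_participants = 400, missing_rate = 0,
                               seed = 67)
  bg0 <- bootega(q0$items, n_boot = 10, seed = 10)
  sc0 <- network_scores(q0$items, bg0, weighting = "uniform")
  for (c in seq_len(bg0$n_communities)) {
    m <- rowMeans(q0$items[, bg0$membership == c, drop = FALSE])
    expect_equal(sc0[, c], (m - mean(m)) / sd(m), tolerance = 1e-10)
  }
  # a participant missing a whole community is flagged NA
  x <- q$items
  comm1 <- which(bg$membership == 1)
  x[1, comm1] <- NA
  scNA <- network_scores(x, bg)
  expect_true(is.na(scNA[1, 1]))
  expect_false(anyNA(scNA[1, -1]))
  # scores invariant to item relabeling within a community
  perm <- order(q$membership, rev(seq_along(q$membership)))
  bgp <- bg
  bgp$membership <- bg$membership[perm]
  names(bgp$membership) <- names(bg$membership)[perm]
  bgp$typical_network <- bg$typical_network[perm, perm]
  scp <- network_scores(q$items[, perm], bgp)
  expect_equal(scp, sc, ignore_attr = TRUE)
  # scores recover the generating latents
  cc <- abs(cor(sc, q$latents, use = "pairwise.complete.obs"))
  expect_true(all(apply(cc, 2, max) >= 0.8))
})
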