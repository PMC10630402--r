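test_that("residualization matches the normal-equations oracle", {
  set.seed(20)
  y <- rnorm(40)
  C <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("fdrms", "age")))
  r <- residualize(y, C)
  b <- ols_normal_equations(C, y)
  expect_equal(as.numeric(r), unname(y - cbind(1, C) %*% b)[, 1],
               tolerance = 1e-10)
  # residuals orthogonal to each confound
  expect_lt(abs(sum(r * C[, 1])), 1e-8)
  expect_lt(abs(sum(r * C[, 2])), 1e-8)
  # intercept only: mean centering
  expect_equal(as.numeric(residualize(y)), y - mean(y))
  # exactly linear target: residuals vanish
  expect_equal(as.numeric(residualize(2 * C[, 1] + 3, C)), rep(0, 40),
               tolerance = 1e-10)
  # collinear confounds named
  expect_error(residualize(y, cbind(C, fdrms2 = 2 * C[, 1])), "fdrms2")
})

test_that("edge selection obeys the strict threshold and the analytic null", {
  set.seed(21)
  n <- 200
  y <- rnorm(n)
  X <- matrix(rnorm(n * 3000), n)
  # planted edge with near-perfect correlation lands in the positive set
  X[, 1] <- 0.9 * y + sqrt(1 - 0.81) * rnorm(n)
  mask <- select_edges(X, y, threshold = 0.2)
  expect_true(1 %in% mask$positive)
  # null selected fraction matches the analytic Pearson tail
  phat <- (length(mask$positive) + length(mask$negative) - 1) / 2999
  p0 <- pearson_tail(0.2, n)
  expect_lt(abs(phat - p0), 3.5 * sqrt(p0 * (1 - p0) / 2999))
  # extreme threshold on noise selects nothing
  m2 <- select_edges(X[, -1], y, threshold = 0.999)
  expect_length(m2$positive, 0)
  expect_length(m2$negative, 0)
  # zero-variance edges are unselectable
  X[, 2] <- 1
  m3 <- select_edges(X, X[, 1], threshold = 0.2)
  expect_false(2 %in% c(m3$positive, m3$negative))
})

test_that("network strength is the per-tail sum of edge values", {
  set.seed(22)
  v <- rnorm(50)
  mask <- edge_mask(positive = c(3, 10, 41), negative = c(1, 7))
  s <- network_strength(v, mask)
  expect_equal(unname(s), c(sum(v[c(3, 10, 41)]), sum(v[c(1, 7)])))
  expect_equal(unname(network_strength(v, edge_mask())), c(0, 0))
  expect_equal(unname(network_strength(v, edge_mask(positive = 5)))[1], v[5])
  # matrix form against a brute-force loop
  X <- matrix(rnorm(6 * 50), 6)
  S <- network_strength(X, mask)
  for (i in 1:6)
    expect_equal(unname(S[i, ]), unname(network_strength(X[i, ], mask)))
})

test_that("the strength model is ordinary least squares per mode", {
  set.seed(23)
  s <- cbind(positive = rnorm(30), negative = rnorm(30))
  # exact fit: target = 2 * positive strength + 1, negative tail absent
  s0 <- cbind(positive = s[, 1], negative = 0)
  m <- fit_strength_model(s0, 2 * s[, 1] + 1)
  expect_equal(unname(m$coefficients),
               c(1, 2, 0), tolerance = 1e-10)
  # random data matches the normal-equations oracle
  y <- rnorm(30)
  m2 <- fit_strength_model(s, y)
  expect_equal(unname(m2$coefficients), unname(ols_normal_equations(s, y)),
               tolerance = 1e-10)
  expect_equal(unname(predict(m2, s)),
               unname(cbind(1, s) %*% ols_normal_equations(s, y))[, 1],
               tolerance = 1e-10)
  # separate-tails mode fits one simple regression per tail
  m3 <- fit_strength_model(s, y, mode = "separate_tails")
  expect_equal(unname(m3$positive),
               unname(ols_normal_equations(s[, 1, drop = FALSE], y)),
               tolerance = 1e-10)
})

test_that("cross-validated predictions never use held-out behavior", {
  d <- simulate_cpm_dataset(40, 15, signal_edges = 1:10,
                            effect_size = 0.6, seed = 24)
  k <- 5
  fit <- cpm(d, k_folds = k, n_iterations = 1, seed = 100)
  fold <- socialcpm:::make_folds(40, k, seed = 101)  # iteration 1 = seed + 1
  # replace fold-2 subjects' behavior with arbitrary values and refit
  y2 <- d$behavior
  y2[fold == 2] <- rev(y2[fold == 2]) * 10 + 3
  fit2 <- cpm(d$edges, y2, d$confounds, k_folds = k, n_iterations = 1,
              seed = 100)
  expect_equal(fit$predictions[fold == 2, 1], fit2$predictions[fold == 2, 1])
})

test_that("fold sizes differ by at most one", {
  fold <- socialcpm:::make_folds(67, 10, seed = 1)
  sizes <- as.integer(table(fold))
  expect_equal(sum(sizes), 67)
  expect_true(all(sizes %in% c(6, 7)))
  expect_error(socialcpm:::make_folds(5, 10, seed = 1), "fewer subjects")
})

test_that("per-fold selection, strength and model match brute force", {
  # 20-subject fixture, one CV pass recomputed by hand
  d <- simulate_cpm_dataset(20, 12, signal_edges = 1:8,
                            effect_size = 0.6, seed = 25)
  k <- 4
  fit <- cpm(d, k_folds = k, n_iterations = 1, threshold = 0.3, seed = 50)
  fold <- socialcpm:::make_folds(20, k, seed = 51)
  C <- as.matrix(d$confounds)
  for (f in 1:k) {
    tr <- fold != f; te <- fold == f
    b <- ols_normal_equations(C[tr, , drop = FALSE], d$behavior[tr])
    ytr <- d$behavior[tr] - cbind(1, C[tr, , drop = FALSE]) %*% b
    yte <- d$behavior[te] - cbind(1, C[te, , drop = FALSE]) %*% b
    r <- apply(d$edges[tr, ], 2, function(e) pearson_twopass(e, ytr))
    pos <- which(r > 0.3); neg <- which(r < -0.3)
    str_tr <- cbind(rowSums(d$edges[tr, pos, drop = FALSE]),
                    rowSums(d$edges[tr, neg, drop = FALSE]))
    str_te <- cbind(rowSums(d$edges[te, pos, drop = FALSE]),
                    rowSums(d$edges[te, neg, drop = FALSE]))
    use <- apply(str_tr, 2, var) > 1e-12
    bb <- ols_normal_equations(str_tr[, use, drop = FALSE], drop(ytr))
    pred <- drop(cbind(1, str_te[, use, drop = FALSE]) %*% bb)
    expect_equal(unname(fit$predictions[te, 1]), unname(pred),
                 tolerance = 1e-8)
    expect_equal(unname(fit$observed[te, 1]), unname(drop(yte)),
                 tolerance = 1e-10)
  }
})

test_that("masked CPM uses no edge outside the mask", {
  d <- simulate_cpm_dataset(50, 15, signal_edges = 1:10,
                            effect_size = 0.6, seed = 26)
  mask <- edge_mask(positive = 1:10)
  fit <- cpm(d, mask = mask, n_iterations = 2, k_folds = 5, seed = 9)
  # zero out every out-of-mask edge: identical predictions
  edges0 <- d$edges
  edges0[, -(1:10)] <- 0
  fit0 <- cpm(edges0, d$behavior, d$confounds, mask = mask,
              n_iterations = 2, k_folds = 5, seed = 9)
  expect_equal(fit$predictions, fit0$predictions)
  expect_equal(fit$accuracies, fit0$accuracies)
  # a mask excluding all planted edges drops accuracy to null level
  miss <- edge_mask(positive = 20:40)
  acc_miss <- vapply(1:5, function(s) {
    ds <- simulate_cpm_dataset(50, 15, signal_edges = 1:10,
                               effect_size = 0.6, seed = 25 + s)
    cpm(ds, mask = miss, n_iterations = 5, k_folds = 5, seed = 9)$median_accuracy
  }, numeric(1))
  expect_lt(mean(acc_miss), 0.25)
})

test_that("median accuracy grows with planted effect size", {
  meds <- sapply(c(0, 0.2, 0.4, 0.6), function(eff) {
    median(vapply(1:5, function(s) {
      d <- simulate_cpm_dataset(80, 20, signal_edges = 1:15,
                                effect_size = eff, seed = 200 + s)
      cpm(d, n_iterations = 5, k_folds = 10, seed = 1)$median_accuracy
    }, numeric(1)))
  })
  expect_true(all(diff(meds) >= 0))
  expect_lt(abs(meds[1]), 0.25)  # null centered near zero
  expect_gt(meds[4], 0.5)
})

test_that("permutation p-values behave at the boundaries", {
  d <- simulate_cpm_dataset(40, 10, signal_edges = 1:20,
                            effect_size = 0.8, seed = 27)
  fit <- cpm(d, n_iterations = 3, k_folds = 5, seed = 2)
  expect_warning(pt <- permutation_test(fit, d, n_permutations = 19, seed = 3),
                 "resolution")
  # strong signal beats every null accuracy: guarded minimum
  expect_equal(pt$p_value, 1 / 20)
  pt0 <- suppressWarnings(permutation_test(fit, d, n_permutations = 19,
                                           seed = 3, guard = FALSE))
  expect_equal(pt0$p_value, 0)
  # an unbeatable median gives p = 1 under the guard
  fit_bad <- fit
  fit_bad$median_accuracy <- -2
  ptb <- suppressWarnings(permutation_test(fit_bad, d, n_permutations = 19,
                                           seed = 3))
  expect_equal(ptb$p_value, 1)
})

test_that("robust edges respect the frequency cutoff", {
  d <- simulate_cpm_dataset(60, 12, signal_edges = 1:5,
                            effect_size = 0.85, seed = 28)
  fit <- cpm(d, n_iterations = 5, k_folds = 6, seed = 4)
  # fraction 0 returns every ever-selected edge
  all_sel <- robust_edges(fit, fraction = 0)
  expect_setequal(all_sel$positive, which(fit$selection_freq$positive > 0))
  # an edge selected in every fold of every iteration survives fraction 1
  always <- which(fit$selection_freq$positive == 1)
  expect_true(length(always) > 0)
  r1 <- robust_edges(fit, fraction = 1)
  expect_setequal(r1$positive, always)
  # strong planted edges are recovered at the 0.97 default
  r97 <- robust_edges(fit)
  expect_true(all(1:5 %in% r97$positive))
})

test_that("lobewise summaries count edges between macroscale regions", {
  atlas4 <- data.frame(node_id = 1:4, lobe = c("A", "A", "B", "B"))
  # edges (1,2) within A and (1,3) between A and B
  em <- edge_index_map(4)
  k12 <- em$k[em$i == 1 & em$j == 2]
  k13 <- em$k[em$i == 1 & em$j == 3]
  ls <- lobewise_summary(edge_mask(positive = c(k12, k13)), atlas4)
  got <- setNames(ls$pairs$positive, paste(ls$pairs$lobe_a, ls$pairs$lobe_b))
  expect_equal(got[["A A"]], 1)
  expect_equal(got[["A B"]], 1)
  expect_equal(got[["B B"]], 0)
  expect_equal(ls$degree$positive, c(2, 1, 1, 0))
  # empty mask: all zeros
  ls0 <- lobewise_summary(edge_mask(), atlas4)
  expect_true(all(ls0$pairs$positive == 0) && all(ls0$pairs$negative == 0))
  # random 20-node mask equals brute-force enumeration
  set.seed(29)
  atlas20 <- data.frame(node_id = 1:20,
                        lobe = sample(c("occipital", "cerebellum",
                                        "prefrontal"), 20, replace = TRUE))
  em20 <- edge_index_map(20)
  pos <- sample(em20$k, 25); neg <- sample(setdiff(em20$k, pos), 15)
  ls20 <- lobewise_summary(edge_mask(pos, neg), atlas20)
  for (row in seq_len(nrow(ls20$pairs))) {
    la <- ls20$pairs$lobe_a[row]; lb <- ls20$pairs$lobe_b[row]
    in_pair <- function(k) {
      li <- atlas20$lobe[em20$i[k]]; lj <- atlas20$lobe[em20$j[k]]
      (li == la & lj == lb) | (li == lb & lj == la)
    }
    expect_equal(ls20$pairs$positive[row], sum(in_pair(pos)))
    expect_equal(ls20$pairs$negative[row], sum(in_pair(neg)))
    expect_equal(ls20$pairs$possible[row], sum(in_pair(em20$k)))
  }
  # standardization divides by possible edges
  expect_equal(ls20$pairs$positive_std,
               ls20$pairs$positive / ls20$pairs$possible)
  expect_error(lobewise_summary(edge_mask(), data.frame(node_id = 1:2,
                                                        lobe = c("A", NA))),
               "without lobe")
})

test_that("fitted cpm objects expose the standard model interface", {
  d <- simulate_cpm_dataset(50, 12, signal_edges = 1:8,
                            effect_size = 0.7, seed = 30)
  fit <- cpm(d, n_iterations = 3, k_folds = 5, seed = 5)
  expect_s3_class(fit, "cpm")
  expect_output(print(fit), "median Spearman accuracy")
  sm <- summary(fit)
  expect_output(print(sm), "robust edges")
  co <- coef(fit)
  expect_named(co, c("(Intercept)", "positive", "negative"))
  # predictions on new data from the same generator correlate with truth
  d2 <- simulate_cpm_dataset(50, 12, signal_edges = 1:8,
                             effect_size = 0.7, seed = 31)
  p <- predict(fit, d2)
  expect_length(p, 50)
  expect_gt(cor(p, d2$behavior, method = "spearman"), 0.3)
  expect_length(residuals(fit), 50)
})
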