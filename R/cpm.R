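#' Construct an edge mask
#'
#' An edge mask is the pair of disjoint edge-index sets selected by CPM:
#' the positive tail (edges whose strength predicts higher behavior) and the
#' negative tail (edges predicting lower behavior). Indices are 1-based flat
#' edge indices under the shared row-major upper-triangle convention
#' ([edge_index_map()]).
#'
#' @param positive,negative integer vectors of edge indices.
#' @return list of class `edge_mask`.
#' @export
edge_mask <- function(positive = integer(0), negative = integer(0)) {
  positive <- sort(unique(as.integer(positive)))
  negative <- sort(unique(as.integer(negative)))
  if (length(intersect(positive, negative)))
    stop("positive and negative tails must be disjoint")
  structure(list(positive = positive, negative = negative),
            class = "edge_mask")
}

#' @export
#' @method print edge_mask
print.edge_mask <- function(x, ...) {
  cat(sprintf("edge_mask: %d positive, %d negative edge(s)\n",
              length(x$positive), length(x$negative)))
  invisible(x)
}

#' Residualize a target on confound covariates
#'
#' Fits ordinary least squares of the target on the confounds (with an
#' intercept) and returns the residuals; with no confounds the target is
#' mean-centered. Inside [cpm()] this is done per fold on training subjects
#' only, and the training coefficients are applied to held-out subjects.
#'
#' @param target numeric vector.
#' @param confounds numeric matrix/data.frame of covariates, or NULL.
#' @return residual vector with attribute `coefficients`.
#' @export
residualize <- function(target, confounds = NULL) {
  b <- confound_coef(target, confounds)
  r <- apply_confound(target, confounds, b)
  attr(r, "coefficients") <- b
  r
}

# OLS coefficients of target on [1, confounds]; errors on rank deficiency
confound_coef <- function(target, confounds = NULL) {
  X <- cbind(`(Intercept)` = 1, as_confound_matrix(confounds, length(target)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("confound matrix is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  drop(qr.coef(qx, target))
}

apply_confound <- function(target, confounds, coef) {
  X <- cbind(1, as_confound_matrix(confounds, length(target)))
  drop(target - X %*% coef)
}

as_confound_matrix <- function(confounds, n) {
  if (is.null(confounds)) return(matrix(numeric(0), n, 0))
  m <- as.matrix(confounds)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  m
}

# Pearson correlation of every column of X with y, NA for zero-variance
# columns; computed from sufficient statistics to avoid per-column overhead.
edge_correlations <- function(X, y) {
  n <- length(y)
  sx <- colSums(X)
  sxx <- colSums(X * X)
  sxy <- drop(crossprod(X, y))
  sy <- sum(y)
  syy <- sum(y * y)
  vx <- n * sxx - sx^2
  vy <- n * syy - sy^2
  r <- (n * sxy - sx * sy) / sqrt(pmax(vx, 0) * max(vy, 0))
  r[vx <= 1e-12 * pmax(sxx, 1)] <- NA_real_
  if (vy <= 0) r[] <- NA_real_
  r
}

#' Select edges correlated with behavior in a training set
#'
#' Mass-univariate Pearson correlation of each edge with the target; edges
#' with r strictly above `threshold` enter the positive tail, strictly below
#' `-threshold` the negative tail. Zero-variance edges are unselectable
#' (their correlation is undefined). Sample correlations exactly at the
#' threshold are excluded (strict inequality).
#'
#' @param edges training subjects x edges matrix.
#' @param target training target (typically confound-residualized).
#' @param threshold |r| cutoff, in (0, 1); default 0.2.
#' @param candidates optional integer vector restricting selection to a
#'   subset of edge indices (masked mode).
#' @return an [edge_mask()].
#' @export
select_edges <- function(edges, target, threshold = 0.2, candidates = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (nrow(edges) < 3) stop("need at least 3 training subjects")
  if (is.null(candidates)) {
    r <- edge_correlations(edges, target)
    edge_mask(positive = which(!is.na(r) & r > threshold),
              negative = which(!is.na(r) & r < -threshold))
  } else {
    candidates <- as.integer(candidates)
    r <- edge_correlations(edges[, candidates, drop = FALSE], target)
    edge_mask(positive = candidates[!is.na(r) & r > threshold],
              negative = candidates[!is.na(r) & r < -threshold])
  }
}

#' Positive and negative network strength
#'
#' A subject's network strength in a tail is the sum of that subject's edge
#' values over the tail's edge set; the empty tail has strength 0.
#'
#' @param edges edge vector, or subjects x edges matrix.
#' @param mask an [edge_mask()].
#' @return for a vector, named numeric `c(positive, negative)`; for a
#'   matrix, subjects x 2 matrix with columns `positive`, `negative`.
#' @export
network_strength <- function(edges, mask) {
  if (is.null(dim(edges))) {
    c(positive = sum(edges[mask$positive]),
      negative = sum(edges[mask$negative]))
  } else {
    cbind(positive = rowSums(edges[, mask$positive, drop = FALSE]),
          negative = rowSums(edges[, mask$negative, drop = FALSE]))
  }
}

#' Fit the network-strength linear model
#'
#' Ordinary least squares of the behavioral target on network strength.
#' In `"combined"` mode one model uses positive and negative strength as
#' two predictors, yielding a single predicted score per subject; in
#' `"separate_tails"` mode one simple regression is fit per tail. A tail
#' that is empty or has constant strength across training subjects drops
#' out of the model (it degenerates to the intercept).
#'
#' @param strengths training subjects x 2 strength matrix (from
#'   [network_strength()]).
#' @param target training target values.
#' @param mode `"combined"` (default) or `"separate_tails"`.
#' @return object of class `strength_model` with elements `coefficients`
#'   (combined) or `positive`/`negative` coefficient vectors (separate),
#'   `mode` and `used` (which tails entered).
#' @export
fit_strength_model <- function(strengths, target,
                               mode = c("combined", "separate_tails")) {
  mode <- match.arg(mode)
  strengths <- as.matrix(strengths)
  if (is.null(colnames(strengths)))
    colnames(strengths) <- c("positive", "negative")
  if (nrow(strengths) < 3) stop("need at least 3 training subjects")
  used <- apply(strengths, 2L, function(s) stats::var(s) > 1e-12)
  fit1 <- function(X) {
    X1 <- cbind(`(Intercept)` = 1, X)
    drop(qr.coef(qr(X1), target))
  }
  if (mode == "combined") {
    co <- numeric(3)
    names(co) <- c("(Intercept)", "positive", "negative")
    if (any(used)) {
      b <- fit1(strengths[, used, drop = FALSE])
      co["(Intercept)"] <- b[1]
      co[names(used)[used]] <- b[-1]
    } else co["(Intercept)"] <- mean(target)
    out <- list(coefficients = co, mode = mode, used = used)
  } else {
    one <- function(tail) {
      co <- c("(Intercept)" = mean(target), slope = 0)
      if (used[tail]) {
        b <- fit1(strengths[, tail, drop = FALSE])
        co <- c(b[1], slope = unname(b[2]))
        names(co)[1] <- "(Intercept)"
      }
      co
    }
    out <- list(positive = one("positive"), negative = one("negative"),
                mode = mode, used = used)
  }
  class(out) <- "strength_model"
  out
}

#' @export
predict.strength_model <- function(object, newdata, ...) {
  s <- as.matrix(newdata)
  if (is.null(colnames(s))) colnames(s) <- c("positive", "negative")
  if (object$mode == "combined") {
    co <- object$coefficients
    drop(co[1] + s[, "positive"] * co["positive"] +
           s[, "negative"] * co["negative"])
  } else {
    cbind(positive = object$positive[1] + object$positive[2] * s[, "positive"],
          negative = object$negative[1] + object$negative[2] * s[, "negative"])
  }
}

# fold assignment: seeded uniform shuffle then contiguous chunks whose sizes
# differ by at most one
make_folds <- function(n, k, seed) {
  if (k < 2) stop("k_folds must be >= 2")
  if (n < k) stop("fewer subjects (", n, ") than folds (", k, ")")
  set.seed(seed %% 2147483647)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

# One k-fold CV pass. Returns per-subject out-of-fold predictions and
# observed residualized targets, plus per-tail selection counts per edge.
cpm_cv <- function(edges, y, confounds, threshold, k_folds, mode,
                   candidates, fold_seed, count_edges = TRUE) {
  n <- nrow(edges)
  E <- ncol(edges)
  fold <- make_folds(n, k_folds, fold_seed)
  pred <- numeric(n)
  obs <- numeric(n)
  pos_count <- if (count_edges) integer(E) else NULL
  neg_count <- if (count_edges) integer(E) else NULL
  for (f in seq_len(k_folds)) {
    test <- fold == f
    train <- !test
    b <- confound_coef(y[train],
                       if (is.null(confounds)) NULL
                       else confounds[train, , drop = FALSE])
    y_tr <- apply_confound(y[train],
                           if (is.null(confounds)) NULL
                           else confounds[train, , drop = FALSE], b)
    y_te <- apply_confound(y[test],
                           if (is.null(confounds)) NULL
                           else confounds[test, , drop = FALSE], b)
    mask <- select_edges(edges[train, , drop = FALSE], y_tr,
                         threshold = threshold, candidates = candidates)
    if (count_edges) {
      pos_count[mask$positive] <- pos_count[mask$positive] + 1L
      neg_count[mask$negative] <- neg_count[mask$negative] + 1L
    }
    s_tr <- network_strength(edges[train, , drop = FALSE], mask)
    s_te <- network_strength(edges[test, , drop = FALSE], mask)
    model <- fit_strength_model(s_tr, y_tr, mode = mode)
    p <- predict(model, s_te)
    if (mode == "separate_tails") p <- rowMeans(p)
    pred[test] <- p
    obs[test] <- y_te
  }
  list(pred = pred, obs = obs, pos_count = pos_count, neg_count = neg_count,
       fold = fold)
}

spearman <- function(a, b) stats::cor(a, b, method = "spearman")

#' Connectome-based predictive modeling
#'
#' Cross-validated prediction of a behavioral target from functional
#' connectivity edges. For each of `n_iterations` random fold splits,
#' subjects are shuffled into `k_folds` folds (sizes differing by at most
#' one); within each fold the target is residualized on the confounds using
#' training subjects only, edges whose training-set Pearson correlation
#' with the residualized target exceeds |r| > `threshold` are split into
#' positive and negative tails, per-subject network strengths are summed
#' over each tail, a linear model of target on strength is fit on training
#' subjects and applied to the held-out fold. Prediction accuracy per
#' iteration is the Spearman rank correlation between observed
#' (residualized) and predicted scores across all subjects.
#'
#' With a `mask`, edge selection is restricted to the mask's indices
#' (second-stage "masked" CPM, e.g. predicting trait scores from a
#' previously identified network).
#'
#' @param x a `subject_dataset` from [simulate_cpm_dataset()], or a
#'   subjects x edges numeric matrix.
#' @param behavior per-subject target; taken from `x` if a dataset.
#' @param confounds per-subject covariate matrix/data.frame or NULL; taken
#'   from `x` if a dataset and not overridden.
#' @param mask optional [edge_mask()] (or integer vector of edge indices)
#'   restricting the feature set.
#' @param threshold selection cutoff |r|, default 0.2.
#' @param k_folds folds, default 10.
#' @param n_iterations fold-split repetitions, default 100.
#' @param model `"combined"` (one model, positive + negative strength as two
#'   predictors; the default) or `"separate_tails"` (one model per tail,
#'   predictions averaged).
#' @param seed RNG seed; iteration i uses seed + i for its fold split.
#' @return object of class `cpm`: `accuracies` (per iteration),
#'   `median_accuracy`, `predictions` and `observed` (subjects x iterations),
#'   `selection_freq` (data.frame: edge, positive, negative — mean selection
#'   fraction over folds then iterations), `config`, `n_nodes` (if known)
#'   and `call`.
#' @seealso [permutation_test()], [robust_edges()], [lobewise_summary()]
#' @export
cpm <- function(x, behavior = NULL, confounds = NULL, mask = NULL,
                threshold = 0.2, k_folds = 10, n_iterations = 100,
                model = c("combined", "separate_tails"), seed = 1) {
  model <- match.arg(model)
  cl <- match.call()
  n_nodes <- NA_integer_
  if (inherits(x, "subject_dataset")) {
    if (is.null(behavior)) behavior <- x$behavior
    if (missing(confounds)) confounds <- x$confounds
    n_nodes <- x$n_nodes
    edges <- x$edges
  } else edges <- as.matrix(x)
  n <- nrow(edges)
  if (length(behavior) != n) stop("behavior must have one value per subject")
  if (!is.null(confounds)) {
    confounds <- as_confound_matrix(confounds, n)
    if (nrow(confounds) != n) stop("confounds must have one row per subject")
    if (anyNA(confounds) || anyNA(behavior))
      stop("behavior and confounds must be complete")
  }
  if (n < 2 * k_folds)
    stop("need at least 2 * k_folds subjects (", 2 * k_folds, ")")
  candidates <- mask_candidates(mask)
  E <- ncol(edges)
  pos_freq <- numeric(E)
  neg_freq <- numeric(E)
  preds <- matrix(NA_real_, n, n_iterations)
  obs <- matrix(NA_real_, n, n_iterations)
  acc <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    cv <- cpm_cv(edges, behavior, confounds, threshold, k_folds, model,
                 candidates, fold_seed = seed + i)
    preds[, i] <- cv$pred
    obs[, i] <- cv$obs
    acc[i] <- spearman(cv$obs, cv$pred)
    pos_freq <- pos_freq + cv$pos_count / k_folds
    neg_freq <- neg_freq + cv$neg_count / k_folds
  }
  sel <- data.frame(edge = seq_len(E),
                    positive = pos_freq / n_iterations,
                    negative = neg_freq / n_iterations)
  if (!is.null(colnames(edges))) sel$label <- colnames(edges)
  # full-sample refit backing predict()/coef(): same pipeline, no held-out set
  fb <- confound_coef(behavior, confounds)
  y_res <- apply_confound(behavior, confounds, fb)
  fmask <- select_edges(edges, y_res, threshold = threshold,
                        candidates = candidates)
  fmodel <- fit_strength_model(network_strength(edges, fmask), y_res,
                               mode = model)
  final <- list(mask = fmask, model = fmodel, confound_coef = fb)
  out <- list(accuracies = acc,
              median_accuracy = stats::median(acc),
              predictions = preds, observed = obs,
              selection_freq = sel,
              config = list(threshold = threshold, k_folds = k_folds,
                            n_iterations = n_iterations, model = model,
                            seed = seed,
                            masked = !is.null(candidates),
                            n_candidates = if (is.null(candidates)) E
                                           else length(candidates)),
              n_subjects = n, n_edges = E, n_nodes = n_nodes,
              candidates = candidates, final = final, call = cl)
  class(out) <- "cpm"
  out
}

mask_candidates <- function(mask) {
  if (is.null(mask)) return(NULL)
  if (inherits(mask, "edge_mask")) return(sort(c(mask$positive, mask$negative)))
  sort(unique(as.integer(mask)))
}

#' Permutation significance test for a CPM model
#'
#' Generates a null distribution of prediction accuracies by shuffling
#' behavioral scores with respect to connectivity matrices and re-running
#' one full k-fold cross-validation per randomization under the fitted
#' model's configuration. Confound rows stay attached to the shuffled
#' behavior (the behavior-confound relation is a property of the behavioral
#' variable; only the brain-behavior link is broken). The non-parametric
#' p-value counts null accuracies at or above the median observed accuracy;
#' by default the guarded convention p = (1 + count) / (1 + n_permutations)
#' is used so p is never 0, with the raw count / n_permutations rule
#' available via `guard = FALSE`.
#'
#' @param fit a fitted [cpm()] object.
#' @param x the same dataset (or edges matrix) the model was fit on.
#' @param behavior,confounds as in [cpm()]; taken from `x` if a dataset.
#' @param n_permutations number of randomizations, default 1000.
#' @param seed RNG seed for the shuffles and fold splits.
#' @param guard use the (1 + count) / (1 + N) convention (default TRUE).
#' @return object of class `cpm_permtest`: `null_accuracies`, `p_value`,
#'   `median_observed`, `n_permutations`.
#' @export
permutation_test <- function(fit, x, behavior = NULL, confounds = NULL,
                             n_permutations = 1000, seed = 1, guard = TRUE) {
  stopifnot(inherits(fit, "cpm"))
  if (n_permutations < 20)
    warning("fewer than 20 permutations gives very coarse p-value resolution")
  if (inherits(x, "subject_dataset")) {
    if (is.null(behavior)) behavior <- x$behavior
    if (missing(confounds)) confounds <- x$confounds
    edges <- x$edges
  } else edges <- as.matrix(x)
  if (!is.null(confounds)) confounds <- as_confound_matrix(confounds,
                                                           length(behavior))
  cfg <- fit$config
  n <- nrow(edges)
  candidates <- fit$candidates
  null_acc <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    set.seed((seed + 7919L * p) %% 2147483647)
    perm <- sample.int(n)
    cv <- cpm_cv(edges, behavior[perm],
                 if (is.null(confounds)) NULL
                 else confounds[perm, , drop = FALSE],
                 cfg$threshold, cfg$k_folds, cfg$model, candidates,
                 fold_seed = seed + 104729L + p, count_edges = FALSE)
    null_acc[p] <- spearman(cv$obs, cv$pred)
  }
  cnt <- sum(null_acc >= fit$median_accuracy)
  pval <- if (guard) (1 + cnt) / (1 + n_permutations) else cnt / n_permutations
  out <- list(null_accuracies = null_acc, p_value = pval,
              median_observed = fit$median_accuracy,
              n_permutations = n_permutations, guard = guard, seed = seed)
  class(out) <- "cpm_permtest"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print cpm_permtest
print.cpm_permtest <- function(x, ...) {
  cat(sprintf(
    "CPM permutation test: median observed accuracy %.3f, p = %.4g (%d permutations)\n",
    x$median_observed, x$p_value, x$n_permutations))
  invisible(x)
}

#' Robust edges across cross-validation models
#'
#' Edges selected in at least `fraction` of all cross-validation models
#' (mean selection fraction over folds, then over iterations), per tail.
#' The default 0.97 keeps only edges that were predictive in essentially
#' every fold split.
#'
#' @param fit a fitted [cpm()] object.
#' @param fraction robustness cutoff in (0, 1]; default 0.97.
#' @param pooled if TRUE, tails are pooled (an edge qualifies when its
#'   positive + negative frequency reaches the cutoff; it is assigned to the
#'   tail where it was selected more often).
#' @return an [edge_mask()].
#' @export
robust_edges <- function(fit, fraction = 0.97, pooled = FALSE) {
  stopifnot(inherits(fit, "cpm"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  sf <- fit$selection_freq
  if (pooled) {
    tot <- sf$positive + sf$negative
    keep <- if (fraction == 0) which(tot > 0) else which(tot >= fraction)
    pos <- keep[sf$positive[keep] >= sf$negative[keep]]
    neg <- setdiff(keep, pos)
    return(edge_mask(positive = pos, negative = neg))
  }
  pos <- if (fraction == 0) which(sf$positive > 0)
         else which(sf$positive >= fraction)
  neg <- if (fraction == 0) which(sf$negative > 0)
         else which(sf$negative >= fraction)
  neg <- setdiff(neg, pos)
  edge_mask(positive = pos, negative = neg)
}

#' Lobewise edge counts and node degrees for an edge mask
#'
#' Aggregates a mask's edges between pairs of anatomically defined
#' macroscale regions (lobes) and computes each node's degree (number of
#' mask edges incident to it) within each tail. Counts are also
#' standardized by the number of possible edges between each lobe pair.
#'
#' @param mask an [edge_mask()].
#' @param atlas data.frame with at least `node_id` (1-based, contiguous) and
#'   `lobe`; see [read_atlas()].
#' @param n_nodes total node count (default: number of atlas rows).
#' @param top_m how many highest-degree "key nodes" to report per tail.
#' @return list of class `lobewise_summary`: `pairs` (data.frame: lobe_a,
#'   lobe_b, possible, positive, negative, positive_std, negative_std),
#'   `degree` (node_id, positive, negative), `key_nodes` (per tail, the
#'   top_m nodes by degree joined with atlas metadata).
#' @export
lobewise_summary <- function(mask, atlas, n_nodes = nrow(atlas), top_m = 12) {
  if (!all(c("node_id", "lobe") %in% names(atlas)))
    stop("atlas must have node_id and lobe columns")
  if (anyNA(atlas$lobe) || any(atlas$lobe == ""))
    stop("node(s) without lobe label: ",
         paste(atlas$node_id[is.na(atlas$lobe) | atlas$lobe == ""],
               collapse = ", "))
  atlas <- atlas[order(atlas$node_id), , drop = FALSE]
  if (!identical(as.integer(atlas$node_id), seq_len(n_nodes)))
    stop("atlas node_id must be contiguous 1..n_nodes")
  map <- edge_index_map(n_nodes)
  lobes <- sort(unique(atlas$lobe))
  lp <- expand.grid(a = seq_along(lobes), b = seq_along(lobes))
  lp <- lp[lp$a <= lp$b, ]
  lobe_of <- atlas$lobe[map$i]
  lobe_of_j <- atlas$lobe[map$j]
  pair_key <- paste(pmin(lobe_of, lobe_of_j), pmax(lobe_of, lobe_of_j),
                    sep = "||")
  all_keys <- paste(lobes[lp$a], lobes[lp$b], sep = "||")
  possible <- table(factor(pair_key, levels = all_keys))
  count_tail <- function(idx)
    table(factor(pair_key[idx], levels = all_keys))
  pos_ct <- count_tail(mask$positive)
  neg_ct <- count_tail(mask$negative)
  pairs <- data.frame(lobe_a = lobes[lp$a], lobe_b = lobes[lp$b],
                      possible = as.integer(possible),
                      positive = as.integer(pos_ct),
                      negative = as.integer(neg_ct),
                      stringsAsFactors = FALSE)
  pairs$positive_std <- ifelse(pairs$possible > 0,
                               pairs$positive / pairs$possible, 0)
  pairs$negative_std <- ifelse(pairs$possible > 0,
                               pairs$negative / pairs$possible, 0)
  deg_tail <- function(idx)
    tabulate(c(map$i[idx], map$j[idx]), nbins = n_nodes)
  degree <- data.frame(node_id = seq_len(n_nodes),
                       positive = deg_tail(mask$positive),
                       negative = deg_tail(mask$negative))
  key <- function(tail) {
    d <- degree[[tail]]
    ord <- order(-d, degree$node_id)[seq_len(min(top_m, n_nodes))]
    cbind(atlas[ord, , drop = FALSE], K = d[ord])
  }
  out <- list(pairs = pairs, degree = degree,
              key_nodes = list(positive = key("positive"),
                               negative = key("negative")))
  class(out) <- "lobewise_summary"
  out
}

#' @export
#' @method print lobewise_summary
print.lobewise_summary <- function(x, ...) {
  cat("Lobewise edge counts (per tail):\n")
  print(x$pairs[x$pairs$positive + x$pairs$negative > 0, ], row.names = FALSE)
  invisible(x)
}
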