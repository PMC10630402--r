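#' Pairwise-deletion Pearson correlation matrix
#'
#' Each entry is the Pearson correlation over participants observed on both
#' items (pairwise deletion). Because pairwise deletion can produce an
#' indefinite matrix, the nearest positive-semidefinite correlation matrix
#' is substituted when needed (and reported via the `repaired` attribute).
#'
#' @param data participants x items numeric matrix (NA = missing), or an
#'   `item_response_matrix` from [simulate_questionnaire()].
#' @param min_joint minimum jointly observed participants per item pair.
#' @return items x items correlation matrix with attributes `n_pairwise`
#'   (matrix of joint-observation counts), `n_effective` (mean pairwise n,
#'   used as the sample size for model selection downstream) and `repaired`.
#' @export
pairwise_correlation <- function(data, min_joint = 3) {
  x <- item_matrix(data)
  if (any(colSums(!is.na(x)) < 2))
    stop("item(s) with fewer than 2 observed values")
  obs <- !is.na(x)
  njoint <- crossprod(obs)
  if (any(njoint < min_joint)) {
    bad <- which(njoint < min_joint, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("item pair(s) with fewer than ", min_joint,
         " joint observations: ",
         paste(apply(bad, 1L, function(r)
           paste(colnames(x)[r], collapse = "~")), collapse = ", "))
  }
  r <- stats::cor(x, use = "pairwise.complete.obs")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  repaired <- FALSE
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    r <- as.matrix(Matrix::nearPD(r, corr = TRUE)$mat)
    repaired <- TRUE
    message("pairwise-deletion correlation matrix was indefinite; ",
            "nearest positive-semidefinite repair applied")
  }
  off <- upper.tri(njoint)
  attr(r, "n_pairwise") <- njoint
  attr(r, "n_effective") <- mean(njoint[off])
  attr(r, "repaired") <- repaired
  r
}

item_matrix <- function(data) {
  x <- if (inherits(data, "item_response_matrix")) data$items else data
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- sprintf("item%02d", seq_len(ncol(x)))
  x
}

#' Sparse regularized partial-correlation network (graphical lasso)
#'
#' Estimates a sparse inverse covariance by L1-penalized Gaussian
#' likelihood (graphical lasso, blockwise coordinate descent) over a
#' descending 100-point logarithmic penalty path, selects the penalty by the
#' extended Bayesian information criterion (EBIC) with tuning `gamma`, and
#' returns the standardized negative off-diagonal of the selected precision
#' matrix — the regularized partial correlations. Exact zeros from the L1
#' penalty are preserved.
#'
#' @param corr items x items correlation (or covariance) matrix, positive
#'   semidefinite.
#' @param n_effective effective sample size behind `corr` (drives the EBIC
#'   likelihood term); taken from the attribute set by
#'   [pairwise_correlation()] when present.
#' @param gamma EBIC hyperparameter, default 0.5 (stronger sparsity than
#'   plain BIC; the conventional network-psychometrics default).
#' @param n_lambda points on the penalty path, default 100.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#'   absolute off-diagonal correlation, default 0.01.
#' @param penalize_diagonal whether the L1 penalty also shrinks the
#'   diagonal; default FALSE.
#' @param maxit,tol optimizer controls.
#' @return object of class `ega_network`: `weights` (partial-correlation
#'   matrix, zero diagonal), `lambda` (selected penalty), `ebic`, `path`
#'   (data.frame of lambda, edges, ebic), `n_effective`.
#' @export
glasso_network <- function(corr, n_effective = NULL, gamma = 0.5,
                           n_lambda = 100, lambda_min_ratio = 0.01,
                           penalize_diagonal = FALSE,
                           maxit = 500, tol = 1e-5) {
  S <- as.matrix(corr)
  p <- ncol(S)
  if (is.null(n_effective)) n_effective <- attr(corr, "n_effective")
  if (is.null(n_effective))
    stop("n_effective must be supplied (or present as an attribute of corr)")
  n <- as.numeric(n_effective)
  if (max(abs(S - t(S))) > 1e-10) stop("corr must be symmetric")
  offmax <- max(abs(S[upper.tri(S)]), 0)
  items <- colnames(S) %||% sprintf("item%02d", seq_len(p))
  if (offmax < 1e-12) {
    w <- matrix(0, p, p, dimnames = list(items, items))
    out <- list(weights = w, lambda = 0, ebic = NA_real_,
                path = data.frame(lambda = 0, edges = 0L, ebic = NA_real_),
                n_effective = n)
    class(out) <- "ega_network"
    return(out)
  }
  lambdas <- exp(seq(log(offmax), log(offmax * lambda_min_ratio),
                     length.out = n_lambda))
  W <- S + diag(if (penalize_diagonal) lambdas[1] else 0, p)
  B <- matrix(0, p, p)
  best <- NULL
  path <- data.frame(lambda = lambdas, edges = NA_integer_,
                     ebic = NA_real_, converged = NA)
  for (l in seq_along(lambdas)) {
    fit <- glasso_cd(S, lambdas[l], W, B, penalize_diagonal, maxit, tol)
    W <- fit$w
    B <- fit$beta
    theta <- fit$theta
    ld <- determinant(theta, logarithm = TRUE)
    if (ld$sign <= 0) next  # not a valid precision; skip this penalty
    ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * theta))
    E <- sum(theta[upper.tri(theta)] != 0)
    ebic <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
    path$edges[l] <- E
    path$ebic[l] <- ebic
    path$converged[l] <- fit$converged
    if (is.null(best) || ebic < best$ebic)
      best <- list(theta = theta, lambda = lambdas[l], ebic = ebic)
  }
  if (is.null(best))
    stop("graphical lasso failed to produce a valid precision matrix at ",
         "any penalty; path diagnostics:\n",
         paste(utils::capture.output(print(path)), collapse = "\n"))
  d <- sqrt(diag(best$theta))
  pc <- -best$theta / tcrossprod(d)
  diag(pc) <- 0
  dimnames(pc) <- list(items, items)
  out <- list(weights = pc, lambda = best$lambda, ebic = best$ebic,
              path = path, n_effective = n)
  class(out) <- "ega_network"
  out
}

#' @export
#' @method print ega_network
print.ega_network <- function(x, ...) {
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf(
    "ega_network: %d items, %d nonzero edges (lambda = %.4g, EBIC = %.4g)\n",
    ncol(x$weights), E, x$lambda, x$ebic))
  invisible(x)
}

#' Louvain community detection on a partial-correlation network
#'
#' Runs the Louvain modularity heuristic on the network's absolute edge
#' weights (modularity is defined for nonnegative weights; the sign of a
#' partial correlation is kept in the network itself, not in the community
#' structure). Deterministic given the seed. An empty network puts every
#' item in its own community, with a warning.
#'
#' @param network an `ega_network` from [glasso_network()], or a symmetric
#'   weight matrix.
#' @param seed RNG seed for the Louvain heuristic.
#' @return integer community membership vector (named by item).
#' @export
louvain_communities <- function(network, seed = 1) {
  w <- if (inherits(network, "ega_network")) network$weights
       else as.matrix(network)
  p <- ncol(w)
  items <- colnames(w) %||% sprintf("item%02d", seq_len(p))
  if (all(w[upper.tri(w)] == 0)) {
    warning("empty network: every item forms its own community")
    return(stats::setNames(seq_len(p), items))
  }
  g <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed %% 2147483647)
  cl <- igraph::cluster_louvain(g)
  stats::setNames(as.integer(igraph::membership(cl)), items)
}

# one-to-one (Hungarian) alignment of a replicate membership onto the
# reference labels by maximum item overlap; surplus replicate communities
# map to their best-overlap reference community
align_membership <- function(reference, membership) {
  kr <- max(reference)
  kb <- max(membership)
  ov <- table(factor(membership, seq_len(kb)), factor(reference, seq_len(kr)))
  ov <- matrix(as.numeric(ov), kb, kr)
  k <- max(kr, kb)
  M <- matrix(0, k, k)
  M[seq_len(kb), seq_len(kr)] <- ov
  asg <- as.integer(clue::solve_LSAP(M, maximum = TRUE))[seq_len(kb)]
  for (b in which(asg > kr)) asg[b] <- which.max(ov[b, ])
  asg[membership]
}

#' Bootstrap exploratory graph analysis
#'
#' Parametric bootstrap around EGA: the pairwise-deletion correlation matrix
#' of the item responses is estimated, `n_boot` replicate samples of the
#' original size are drawn from a multivariate normal with that correlation,
#' and EGA (graphical lasso + Louvain) is run on each replicate. The typical
#' network is the entrywise median of the replicate weights; final community
#' membership is Louvain on the typical network; item stability is the
#' proportion of replicates in which each item lands in each (label-aligned)
#' community.
#'
#' @param data participants x items matrix (NA = missing) or an
#'   `item_response_matrix`.
#' @param n_boot bootstrap replicates, default 500.
#' @param gamma,n_lambda,lambda_min_ratio passed to [glasso_network()].
#' @param seed RNG seed; replicate b uses seed + b.
#' @param max_fail_frac error out if more than this fraction of replicates
#'   fail (default 0.05).
#' @return object of class `bootega`: `typical_network` (median
#'   partial-correlation matrix), `membership` (final), `n_communities`
#'   (final count), `replicate_counts` (community count per replicate),
#'   `item_stability` (items x communities proportions), `correlation`
#'   (the estimated item correlation matrix), `n_boot`, `n_failed`, `seed`.
#' @export
bootega <- function(data, n_boot = 500, gamma = 0.5, n_lambda = 100,
                    lambda_min_ratio = 0.01, seed = 1,
                    max_fail_frac = 0.05) {
  x <- item_matrix(data)
  n <- nrow(x)
  p <- ncol(x)
  R0 <- pairwise_correlation(x)
  n_eff <- attr(R0, "n_effective")
  weights <- array(NA_real_, c(p, p, n_boot))
  members <- matrix(NA_integer_, p, n_boot)
  counts <- rep(NA_integer_, n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    res <- tryCatch({
      set.seed((seed + b) %% 2147483647)
      xb <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R0)
      Rb <- stats::cor(xb)
      net <- glasso_network(Rb, n_effective = n, gamma = gamma,
                            n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
      memb <- suppressWarnings(louvain_communities(net, seed = seed + b))
      list(w = net$weights, memb = memb)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    weights[, , b] <- res$w
    members[, b] <- res$memb
    counts[b] <- max(res$memb)
  }
  if (n_failed > max_fail_frac * n_boot)
    stop(n_failed, " of ", n_boot, " bootstrap replicates failed")
  ok <- which(!is.na(counts))
  typical <- apply(weights[, , ok, drop = FALSE], c(1, 2), stats::median)
  dimnames(typical) <- dimnames(R0)
  membership <- suppressWarnings(louvain_communities(typical, seed = seed))
  kf <- max(membership)
  stab <- matrix(0, p, kf,
                 dimnames = list(colnames(x), paste0("community", seq_len(kf))))
  for (b in ok) {
    al <- align_membership(membership, members[, b])
    keep <- !is.na(al) & al <= kf
    stab[cbind(which(keep), al[keep])] <-
      stab[cbind(which(keep), al[keep])] + 1
  }
  stab <- stab / length(ok)
  out <- list(typical_network = typical, membership = membership,
              n_communities = kf, replicate_counts = counts,
              item_stability = stab, correlation = R0,
              n_effective = n_eff, n_boot = n_boot, n_failed = n_failed,
              gamma = gamma, seed = seed)
  class(out) <- "bootega"
  out
}

#' @export
#' @method print bootega
print.bootega <- function(x, ...) {
  tab <- table(x$replicate_counts)
  cat(sprintf("bootega: %d items, %d bootstrap replicates (%d failed)\n",
              ncol(x$typical_network), x$n_boot, x$n_failed))
  cat(sprintf("  final communities: %d; replicate community counts: %s\n",
              x$n_communities,
              paste(names(tab), tab, sep = ":", collapse = " ")))
  cat(sprintf("  median item stability in assigned community: %.3f\n",
              stats::median(x$item_stability[cbind(seq_along(x$membership),
                                                   x$membership)])))
  invisible(x)
}

#' @export
#' @method summary bootega
summary.bootega <- function(object, ...) {
  st <- object$item_stability[cbind(seq_along(object$membership),
                                    object$membership)]
  out <- list(n_communities = object$n_communities,
              membership = object$membership,
              stability = stats::setNames(st, names(object$membership)),
              replicate_counts = table(object$replicate_counts),
              n_failed = object$n_failed)
  class(out) <- "summary.bootega"
  out
}

#' @export
#' @method print summary.bootega
print.summary.bootega <- function(x, ...) {
  cat("bootEGA summary:", x$n_communities, "communities\n")
  cat("replicate community-count distribution:\n")
  print(x$replicate_counts)
  cat("item membership and stability:\n")
  print(data.frame(community = x$membership,
                   stability = round(x$stability, 3)))
  invisible(x)
}

#' Plot the typical EGA network
#'
#' Draws the typical (median bootstrap) partial-correlation network with
#' items colored by community; positive edges solid, negative dashed, width
#' proportional to |weight|.
#'
#' @param x a `bootega` object.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.bootega <- function(x, ...) {
  w <- x$typical_network
  g <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)
  esign <- sign(w[ends])
  igraph::plot.igraph(
    g, vertex.color = x$membership,
    edge.width = 4 * igraph::E(g)$weight / max(igraph::E(g)$weight),
    edge.lty = ifelse(esign < 0, 2, 1), ...)
  invisible(x)
}

#' Standardized community network scores
#'
#' Per community, each member item's weight is its within-community strength
#' (sum of absolute typical-network weights to the other members),
#' normalized to sum to 1 (`weighting = "strength"`), or uniform
#' (`weighting = "uniform"`). A participant's raw score is the weighted sum
#' of their observed member-item responses, with missing entries mean-imputed
#' within item; a participant missing all of a community's items gets NA.
#' Scores are then standardized to mean 0, sd 1 over scored participants.
#'
#' @param data the original participants x items responses (NA = missing) or
#'   `item_response_matrix`.
#' @param result a `bootega` object (typical network + membership).
#' @param weighting `"strength"` (default) or `"uniform"`.
#' @return participants x communities matrix of standardized scores, with
#'   attribute `weights` (the per-item weight list).
#' @export
network_scores <- function(data, result,
                           weighting = c("strength", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(result, "bootega"))
  x <- item_matrix(data)
  memb <- result$membership
  if (ncol(x) != length(memb))
    stop("data has ", ncol(x), " items but the EGA result has ", length(memb))
  k <- result$n_communities
  scores <- matrix(NA_real_, nrow(x), k,
                   dimnames = list(NULL, paste0("community", seq_len(k))))
  wts <- vector("list", k)
  for (c in seq_len(k)) {
    idx <- which(memb == c)
    if (length(idx) == 1L)
      warning("community ", c, " has a single item; weight 1 on that item")
    w <- if (weighting == "uniform" || length(idx) == 1L)
      rep(1, length(idx))
    else rowSums(abs(result$typical_network[idx, idx, drop = FALSE]))
    if (sum(w) <= 0) w <- rep(1, length(idx))
    w <- w / sum(w)
    wts[[c]] <- stats::setNames(w, colnames(x)[idx])
    xc <- x[, idx, drop = FALSE]
    all_missing <- rowSums(!is.na(xc)) == 0
    for (jj in seq_along(idx)) {
      col <- xc[, jj]
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      xc[, jj] <- col
    }
    raw <- drop(xc %*% w)
    raw[all_missing] <- NA_real_
    scores[, c] <- (raw - mean(raw, na.rm = TRUE)) /
      stats::sd(raw, na.rm = TRUE)
  }
  attr(scores, "weights") <- wts
  scores
}
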