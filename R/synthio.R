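#' Simulate a subjects x edges dataset with planted edge-behavior signal
#'
#' Generates the input that connectome-based predictive modeling consumes:
#' a matrix of Fisher-z edge values for `n_subjects` subjects over the
#' n(n-1)/2 edges of an `n_nodes` atlas, a continuous behavioral target, and
#' a motion-like confound. Behavior is standard normal. Each planted signal
#' edge e is constructed as
#'
#'   edge_e = noise_sd * (effect_size * behavior + sqrt(1 - effect_size^2) * eps)
#'
#' with eps standard normal, so its population correlation with behavior is
#' exactly `effect_size`; non-signal edges are independent noise. The
#' confound is built the same way against behavior at `confound_r`,
#' emulating a head-motion summary (mean framewise displacement) that
#' covaries with task performance.
#'
#' The signal is planted directly on edge values rather than via node
#' timecourses: CPM consumes edge vectors, and direct planting gives exact,
#' controllable ground truth. See [simulate_node_timeseries()] for a
#' timecourse-level generator.
#'
#' @param n_subjects number of subjects (>= 3). Default 67, a typical
#'   single-site imaging sample.
#' @param n_nodes atlas size. Default 268 (whole-brain functional atlas
#'   covering cortex, subcortex and cerebellum).
#' @param signal_edges integer vector of 1-based edge indices (see
#'   [edge_index_map()]) carrying signal; default none.
#' @param effect_size target per-edge Pearson correlation with behavior,
#'   in (-1, 1).
#' @param noise_sd edge scale.
#' @param confound_r target confound-behavior correlation, in (-1, 1).
#'   Default -0.30, the size of motion-performance correlation typical of
#'   attention tasks.
#' @param seed RNG seed; output is bit-reproducible given the seed.
#' @return list of class `subject_dataset`: `edges` (subjects x edges matrix
#'   with "n{i}_n{j}" column names), `behavior`, `confounds` (data.frame
#'   with column `fdrms`), `subject` ids, `n_nodes`, and `signal_edges`
#'   (the planted truth, for recovery checks).
#' @export
simulate_cpm_dataset <- function(n_subjects = 67, n_nodes = 268,
                                 signal_edges = integer(0),
                                 effect_size = 0.5, noise_sd = 1,
                                 confound_r = -0.30, seed = 1) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (abs(effect_size) >= 1) stop("effect_size must lie in (-1, 1)")
  if (abs(confound_r) >= 1) stop("confound_r must lie in (-1, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  E <- n_edges(n_nodes)
  signal_edges <- as.integer(signal_edges)
  if (length(signal_edges) &&
      (any(signal_edges < 1) || any(signal_edges > E)))
    stop("signal_edges out of range 1..", E)
  set.seed(seed)
  y <- stats::rnorm(n_subjects)
  edges <- matrix(stats::rnorm(n_subjects * E), n_subjects, E)
  if (length(signal_edges)) {
    k <- length(signal_edges)
    edges[, signal_edges] <- effect_size * y +
      sqrt(1 - effect_size^2) * edges[, signal_edges, drop = FALSE]
  }
  edges <- noise_sd * edges
  colnames(edges) <- edge_labels(n_nodes)
  conf <- confound_r * y + sqrt(1 - confound_r^2) * stats::rnorm(n_subjects)
  out <- list(edges = edges, behavior = y,
              confounds = data.frame(fdrms = conf),
              subject = sprintf("sub%03d", seq_len(n_subjects)),
              n_nodes = n_nodes, signal_edges = sort(signal_edges))
  class(out) <- "subject_dataset"
  out
}

#' @export
#' @method print subject_dataset
print.subject_dataset <- function(x, ...) {
  cat(sprintf(
    "subject_dataset: %d subjects x %d edges (%d nodes), %d planted signal edge(s)\n",
    nrow(x$edges), ncol(x$edges), x$n_nodes, length(x$signal_edges)))
  invisible(x)
}

#' Simulate node timecourses with shared latent signals
#'
#' Timecourse-level companion to [simulate_cpm_dataset()] for integration
#' tests of the connectivity stage: nodes are grouped onto latent signals,
#' so nodes sharing a latent are positively correlated while nodes in
#' different groups are independent.
#'
#' @param n_nodes,n_frames dimensions.
#' @param n_latents number of shared latent signals.
#' @param loading correlation of each node with its latent, in (0, 1).
#' @param seed RNG seed.
#' @return nodes x frames matrix with attribute `group` (latent assignment
#'   per node).
#' @export
simulate_node_timeseries <- function(n_nodes = 20, n_frames = 200,
                                     n_latents = 3, loading = 0.6, seed = 1) {
  if (loading <= 0 || loading >= 1) stop("loading must lie in (0, 1)")
  if (n_frames < 3) stop("n_frames must be >= 3")
  set.seed(seed)
  lat <- matrix(stats::rnorm(n_latents * n_frames), n_latents, n_frames)
  group <- rep_len(seq_len(n_latents), n_nodes)
  ts <- loading * lat[group, , drop = FALSE] +
    sqrt(1 - loading^2) * matrix(stats::rnorm(n_nodes * n_frames),
                                 n_nodes, n_frames)
  attr(ts, "group") <- group
  ts
}

#' Simulate one-back task trials from a Gaussian observer
#'
#' Builds a block sequence for a one-back matching task with alternating
#' attend-faces / attend-houses blocks of `images_per_block` images, where
#' each block contains 4 or 5 "same" trials (configurable) among its
#' scorable trials. The first image of each block has no predecessor, so it
#' generates no scorable trial (truth is NA there). Responses come from an
#' equal-variance Gaussian observer with sensitivity `true_sensitivity` and
#' an unbiased criterion midway between the signal and noise distributions:
#' evidence is N(d', 1) on "same" trials and N(0, 1) on "different" trials,
#' and the observer responds "same" when evidence exceeds d'/2.
#'
#' @param n_blocks_per_condition blocks per condition (default 6).
#' @param images_per_block images per block (default 10, i.e. 9 scorable
#'   trials).
#' @param same_per_block allowed counts of "same" trials per block; one is
#'   drawn uniformly for each block (default 4 or 5).
#' @param true_sensitivity generating d' of the observer.
#' @param seed RNG seed.
#' @return data.frame of class `task_trials` with columns `block`,
#'   `condition`, `trial`, `truth` and `response` (truth/response NA on the
#'   first image of each block).
#' @export
simulate_task_trials <- function(n_blocks_per_condition = 6,
                                 images_per_block = 10,
                                 same_per_block = c(4, 5),
                                 true_sensitivity = 1.5, seed = 1) {
  if (!is.finite(true_sensitivity)) stop("true_sensitivity must be finite")
  if (images_per_block < 2) stop("images_per_block must be >= 2")
  n_scorable <- images_per_block - 1L
  if (any(same_per_block >= images_per_block) || any(same_per_block < 0))
    stop("same_per_block must lie in [0, images_per_block - 1]")
  set.seed(seed)
  n_blocks <- 2L * n_blocks_per_condition
  conds <- rep(c("attend_faces", "attend_houses"), n_blocks_per_condition)
  crit <- true_sensitivity / 2
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    n_same <- if (length(same_per_block) > 1L)
      sample(same_per_block, 1L) else same_per_block
    truth <- rep("different", n_scorable)
    truth[sample.int(n_scorable, n_same)] <- "same"
    evidence <- stats::rnorm(n_scorable,
                             mean = ifelse(truth == "same",
                                           true_sensitivity, 0))
    resp <- ifelse(evidence > crit, "same", "different")
    rows[[b]] <- data.frame(
      block = b, condition = conds[b], trial = seq_len(images_per_block),
      truth = c(NA_character_, truth), response = c(NA_character_, resp),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("task_trials", "data.frame")
  out
}

#' Build a simple-structure loading matrix
#'
#' @param n_communities number of latent communities.
#' @param items_per_community items loading on each community.
#' @param loading the dominant loading; cross-loadings are 0.
#' @return items x communities matrix.
#' @export
make_loadings <- function(n_communities = 3, items_per_community = 8,
                          loading = 0.65) {
  L <- matrix(0, n_communities * items_per_community, n_communities)
  for (c in seq_len(n_communities))
    L[(c - 1) * items_per_community + seq_len(items_per_community), c] <- loading
  rownames(L) <- sprintf("item%02d", seq_len(nrow(L)))
  L
}

#' Simulate ordinal questionnaire responses from correlated latent communities
#'
#' Latent community scores are drawn from a multivariate normal with the
#' given community correlation matrix; continuous item responses are
#' loadings x latents plus unique normal noise scaled so each item has unit
#' variance; items are then discretized into `n_categories` ordinal levels
#' by equal-probability thresholds, and entries are deleted completely at
#' random at `missing_rate`. This emulates questionnaire batteries whose
#' items load on a few correlated trait communities (e.g. social skills,
#' behavioral inflexibility, social anxiety).
#'
#' @param n_participants sample size. Default 1357, a large online
#'   questionnaire sample.
#' @param loading_matrix items x communities loading matrix (see
#'   [make_loadings()]); implied item communalities must be < 1.
#' @param community_correlations symmetric positive-definite correlation
#'   matrix of the latent communities. Default: 3 communities with pairwise
#'   r = 0.5 (trait communities within one phenotype are not orthogonal).
#' @param n_categories ordinal levels per item (default 5).
#' @param missing_rate MCAR deletion probability in [0, 1).
#' @param seed RNG seed.
#' @return list of class `item_response_matrix`: `items` (participants x
#'   items, integer categories 1..n_categories, NA = missing), `latents`
#'   (participants x communities, the generating truth), `membership`
#'   (true community of each item) and the generator settings.
#' @export
simulate_questionnaire <- function(n_participants = 1357,
                                   loading_matrix = make_loadings(),
                                   community_correlations = NULL,
                                   n_categories = 5,
                                   missing_rate = 0.1, seed = 1) {
  L <- as.matrix(loading_matrix)
  nc <- ncol(L)
  if (is.null(community_correlations)) {
    community_correlations <- matrix(0.5, nc, nc)
    diag(community_correlations) <- 1
  }
  R <- as.matrix(community_correlations)
  if (nrow(R) != nc || ncol(R) != nc)
    stop("community_correlations must be ", nc, " x ", nc)
  if (max(abs(R - t(R))) > 1e-12 || any(abs(diag(R) - 1) > 1e-12))
    stop("community_correlations must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("community_correlations must be positive-definite")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_categories < 2) stop("n_categories must be >= 2")
  communality <- rowSums((L %*% R) * L)
  if (any(communality >= 1))
    stop("loading rows imply item communality >= 1")
  set.seed(seed)
  lat <- MASS::mvrnorm(n_participants, mu = rep(0, nc), Sigma = R)
  cont <- lat %*% t(L) +
    matrix(stats::rnorm(n_participants * nrow(L)), n_participants) *
      rep(sqrt(1 - communality), each = n_participants)
  # equal-probability thresholds on the (unit-variance) marginals
  thr <- stats::qnorm(seq_len(n_categories - 1) / n_categories)
  items <- matrix(findInterval(cont, thr) + 1L, n_participants, nrow(L))
  if (missing_rate > 0)
    items[matrix(stats::runif(length(items)) < missing_rate,
                 nrow(items))] <- NA_integer_
  colnames(items) <- rownames(L)
  membership <- apply(abs(L), 1L, which.max)
  out <- list(items = items, latents = lat, membership = membership,
              loading_matrix = L, community_correlations = R,
              n_categories = n_categories, missing_rate = missing_rate,
              seed = seed)
  class(out) <- "item_response_matrix"
  out
}

#' @export
#' @method print item_response_matrix
print.item_response_matrix <- function(x, ...) {
  cat(sprintf(
    "item_response_matrix: %d participants x %d items, %d communities, %.1f%% missing\n",
    nrow(x$items), ncol(x$items), ncol(x$latents),
    100 * mean(is.na(x$items))))
  invisible(x)
}

#' Simulate correlated trait scores, one sharing signal with behavior
#'
#' Builds `n_traits` standardized trait scores with pairwise correlation
#' `r`, of which the trait in position `shared` equals the behavioral
#' target itself (so it shares whatever edges were planted against
#' behavior), while the remaining traits relate to the brain only through
#' their correlation with the shared trait. Used to check that masked
#' second-stage prediction with the other traits as covariates is specific:
#' only the sharing trait should be predictable from the planted edges.
#'
#' @param behavior per-subject behavioral target (standard normal scale).
#' @param n_traits number of traits (default 3).
#' @param r target pairwise correlation between traits (default 0.8).
#' @param shared index of the trait that carries the brain signal.
#' @param seed RNG seed.
#' @return subjects x n_traits matrix with columns "trait1", "trait2", ...
#' @export
simulate_trait_scores <- function(behavior, n_traits = 3, r = 0.8,
                                  shared = 1, seed = 1) {
  if (abs(r) >= 1) stop("r must lie in (-1, 1)")
  n <- length(behavior)
  set.seed(seed)
  k <- n_traits - 1L
  # remaining traits: r * behavior + sqrt(1 - r^2) * f, with the f's
  # equicorrelated at c = r / (1 + r) so that all pairwise trait
  # correlations equal r
  cc <- r / (1 + r)
  Rf <- matrix(cc, k, k); diag(Rf) <- 1
  f <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = Rf)
  f <- matrix(f, nrow = n)
  traits <- matrix(0, n, n_traits)
  traits[, shared] <- behavior
  traits[, -shared] <- r * behavior + sqrt(1 - r^2) * f
  colnames(traits) <- paste0("trait", seq_len(n_traits))
  traits
}
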