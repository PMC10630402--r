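#' Read a delimited table with schema validation
#'
#' Thin validated wrapper over [utils::read.csv()]/[utils::read.delim()]:
#' required columns must be present and numeric columns must parse, with
#' errors naming the offending column (and row for a bad cell).
#'
#' @param path file path; extension `.tsv` selects tab separation.
#' @param columns named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`).
#' @param sep field separator; default from extension.
#' @return data.frame with coerced columns (extra columns kept as-is).
#' @export
read_table <- function(path, columns = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!is.null(columns)) {
    miss <- setdiff(names(columns), names(df))
    if (length(miss))
      stop("missing required column(s) in ", basename(path), ": ",
           paste(miss, collapse = ", "))
    for (col in names(columns)) {
      type <- columns[[col]]
      v <- df[[col]]
      if (type %in% c("numeric", "integer")) {
        suppressWarnings(num <- as.numeric(v))
        bad <- which(is.na(num) & !is.na(v))
        if (length(bad))
          stop("non-numeric value in column '", col, "' at row ", bad[1],
               ": '", v[bad[1]], "'")
        df[[col]] <- if (type == "integer") as.integer(num) else num
      } else df[[col]] <- as.character(v)
    }
  }
  df
}

#' Read and write subjects x edges matrices
#'
#' CSV with one row per subject and one column per edge, headed by the
#' shared edge labels "n{i}_n{j}" (row-major upper triangle, 1-based node
#' ids). Values are written at full double precision so a round trip is
#' bit-exact.
#'
#' @param x subjects x edges matrix (or `subject_dataset`).
#' @param path file path.
#' @return `read_edge_matrix()`: numeric matrix with edge-label column
#'   names and attribute `n_nodes`.
#' @export
write_edge_matrix <- function(x, path) {
  m <- if (inherits(x, "subject_dataset")) x$edges else as.matrix(x)
  df <- as.data.frame(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                      stringsAsFactors = FALSE)
  names(df) <- colnames(m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_matrix
#' @export
read_edge_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  E <- ncol(m)
  n <- (1 + sqrt(1 + 8 * E)) / 2
  if (n == round(n)) {
    expected <- edge_labels(n)
    if (!identical(colnames(m), expected))
      warning("edge columns are not in the package's row-major ",
              "upper-triangle order")
    attr(m, "n_nodes") <- as.integer(n)
  }
  m
}

#' Read atlas node metadata
#'
#' TSV with columns node_id, name, hemisphere, lobe, network, ba, mni_x,
#' mni_y, mni_z (1-based contiguous node ids).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_atlas <- function(path) {
  at <- read_table(path, columns = c(node_id = "integer", name = "character",
                                     hemisphere = "character",
                                     lobe = "character",
                                     network = "character", ba = "character",
                                     mni_x = "numeric", mni_y = "numeric",
                                     mni_z = "numeric"),
                   sep = "\t")
  at <- at[order(at$node_id), ]
  if (!identical(at$node_id, seq_len(nrow(at))))
    stop("atlas node_id must be contiguous 1..n")
  at
}

#' Read one-back trial logs
#'
#' CSV with columns subject, block, condition, truth, response (blank truth
#' marks the unscorable first image of a block).
#'
#' @param path file path.
#' @return data.frame suitable for [score_oneback()] (split by subject).
#' @export
read_trials <- function(path) {
  read_table(path, columns = c(subject = "character", block = "integer",
                               condition = "character", truth = "character",
                               response = "character"))
}

#' Read and write item-response matrices
#'
#' CSV with a participant id column followed by item columns; blank cells
#' are missing responses.
#'
#' @param x participants x items matrix (or `item_response_matrix`).
#' @param path file path.
#' @param ids participant ids; defaults to p0001, ...
#' @return `read_items()`: numeric matrix (NA = missing) with participant
#'   ids as rownames.
#' @export
write_items <- function(x, path, ids = NULL) {
  m <- item_matrix(x)
  if (is.null(ids)) ids <- sprintf("p%04d", seq_len(nrow(m)))
  df <- data.frame(participant = ids, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_items
#' @export
read_items <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("NA", ""))
  if (!"participant" %in% names(df))
    stop("missing required column(s) in ", basename(path), ": participant")
  m <- as.matrix(df[, setdiff(names(df), "participant"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$participant
  m
}

#' Write a subject dataset to a directory
#'
#' Writes the edges matrix (CSV), the behavior/confound table (CSV), and a
#' JSON sidecar recording the generator settings and seed.
#'
#' @param data a `subject_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_subject_dataset <- function(data, dir) {
  stopifnot(inherits(data, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(dir, "edges.csv"),
             behavior = file.path(dir, "behavior.csv"),
             sidecar = file.path(dir, "dataset.json"))
  write_edge_matrix(data$edges, paths["edges"])
  beh <- data.frame(subject = data$subject, behavior = data$behavior,
                    data$confounds, check.names = FALSE)
  utils::write.csv(beh, paths["behavior"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_subjects = nrow(data$edges), n_nodes = data$n_nodes,
         signal_edges = data$signal_edges),
    paths["sidecar"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages in dependency order on synthetic or on-disk inputs:
#' (1) simulate or load a subjects x edges dataset, (2) CPM of the
#' behavioral target with confound residualization, (3) permutation
#' significance, (4) robust-edge mask, (5) masked second-stage CPM of each
#' trait score with the other traits as covariates (plus permutation
#' significance per trait). Every artifact is written under `out_dir` along
#' with a manifest linking outputs to the resolved configuration and seed.
#' Reruns with identical inputs and seed reproduce identical outputs.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Recognized blocks: `seed`; `simulate` (arguments of
#'   [simulate_cpm_dataset()], plus `n_traits`/`trait_r`/`trait_shared` for
#'   [simulate_trait_scores()]) or `inputs` (paths `edges`, `behavior` with
#'   column names under `behavior_column`, `confound_columns`,
#'   `trait_columns`); `cpm` (threshold, k_folds, n_iterations, model);
#'   `permutation` (n_permutations); `robust` (fraction).
#' @param out_dir output directory.
#' @return invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config),
                     c("seed", "simulate", "inputs", "cpm", "permutation",
                       "robust"))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  traits <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_sig <- sim$n_signal_edges %||% length(sim$signal_edges %||% integer(0))
    set.seed(seed)
    signal <- sim$signal_edges %||%
      sample.int(n_edges(sim$n_nodes %||% 268), n_sig)
    data <- simulate_cpm_dataset(
      n_subjects = sim$n_subjects %||% 67,
      n_nodes = sim$n_nodes %||% 268,
      signal_edges = signal,
      effect_size = sim$effect_size %||% 0.5,
      noise_sd = sim$noise_sd %||% 1,
      confound_r = sim$confound_r %||% -0.30,
      seed = seed)
    if (!is.null(sim$n_traits))
      traits <- simulate_trait_scores(data$behavior,
                                      n_traits = sim$n_traits,
                                      r = sim$trait_r %||% 0.8,
                                      shared = sim$trait_shared %||% 1,
                                      seed = seed + 1)
    edges <- data$edges
    behavior <- data$behavior
    confounds <- data$confounds
    write_subject_dataset(data, out_dir)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    edges <- read_edge_matrix(inp$edges)
    beh <- read_table(inp$behavior)
    behavior <- beh[[inp$behavior_column %||% "behavior"]]
    if (is.null(behavior)) stop("behavior column not found")
    confounds <- if (length(inp$confound_columns))
      beh[, inp$confound_columns, drop = FALSE] else NULL
    if (length(inp$trait_columns))
      traits <- as.matrix(beh[, inp$trait_columns, drop = FALSE])
  } else stop("config needs a 'simulate' or an 'inputs' block")

  cc <- config$cpm %||% list()
  fit <- cpm(edges, behavior, confounds,
             threshold = cc$threshold %||% 0.2,
             k_folds = cc$k_folds %||% 10,
             n_iterations = cc$n_iterations %||% 100,
             model = cc$model %||% "combined",
             seed = seed)
  utils::write.csv(data.frame(iteration = seq_along(fit$accuracies),
                              accuracy = fit$accuracies),
                   file.path(out_dir, "accuracies.csv"), row.names = FALSE)
  utils::write.csv(fit$selection_freq,
                   file.path(out_dir, "selection_freq.csv"),
                   row.names = FALSE)

  np <- (config$permutation %||% list())$n_permutations %||% 1000
  pt <- permutation_test(fit, edges, behavior, confounds,
                         n_permutations = np, seed = seed)
  utils::write.csv(data.frame(replicate = seq_along(pt$null_accuracies),
                              accuracy = pt$null_accuracies),
                   file.path(out_dir, "permutation.csv"), row.names = FALSE)

  frac <- (config$robust %||% list())$fraction %||% 0.97
  mask <- robust_edges(fit, fraction = frac)
  mask_df <- data.frame(
    edge = c(mask$positive, mask$negative),
    tail = rep(c("positive", "negative"),
               c(length(mask$positive), length(mask$negative))))
  utils::write.csv(mask_df, file.path(out_dir, "robust_mask.csv"),
                   row.names = FALSE)

  trait_results <- NULL
  if (!is.null(traits) && length(mask$positive) + length(mask$negative) > 0) {
    trait_results <- list()
    for (tcol in colnames(traits)) {
      covars <- traits[, setdiff(colnames(traits), tcol), drop = FALSE]
      tf <- cpm(edges, traits[, tcol], covars, mask = mask,
                threshold = cc$threshold %||% 0.2,
                k_folds = cc$k_folds %||% 10,
                n_iterations = cc$n_iterations %||% 100,
                seed = seed)
      tp <- permutation_test(tf, edges, traits[, tcol], covars,
                             n_permutations = np, seed = seed)
      trait_results[[tcol]] <- list(fit = tf, permtest = tp)
      jsonlite::write_json(
        list(trait = tcol, median_accuracy = tf$median_accuracy,
             p_value = tp$p_value, n_permutations = np, seed = seed),
        file.path(out_dir, paste0("trait_", tcol, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }

  manifest <- list(
    config = config, seed = seed,
    median_accuracy = fit$median_accuracy, p_value = pt$p_value,
    robust_positive = length(mask$positive),
    robust_negative = length(mask$negative),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, permtest = pt, mask = mask,
                 trait_results = trait_results, manifest = manifest))
}
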