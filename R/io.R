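#' Read a numeric data matrix from delimited text
#'
#' Expects a header row and a leading column of row identifiers. Validates
#' that all cells are numeric and non-missing, reporting offending rows, and
#' that identifiers are unique.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator (default comma).
#' @param standardise Centre and scale each column to mean 0, variance 1.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path, sep = ",", standardise = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("parse error: file is empty: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2) stop("parse error: expected row identifiers plus at least one variable")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row identifiers (e.g. line ",
         which(duplicated(ids))[1] + 1, "): ", ids[duplicated(ids)][1])
  vals <- df[, -1, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric cells in column(s): ",
         paste(names(vals)[!num], collapse = ", "))
  X <- as.matrix(vals)
  if (any(!is.finite(X))) {
    bad <- which(rowSums(!is.finite(X)) > 0)[1]
    stop("missing or non-finite value at data line ", bad + 1,
         " (row id '", ids[bad], "')")
  }
  rownames(X) <- ids
  if (standardise) X <- standardise_columns(X)
  X
}

#' Standardise columns to mean 0, variance 1
#'
#' @param X Numeric matrix.
#' @return Matrix with each column mean-centred and scaled to unit variance
#'   (constant columns are only centred).
#' @export
standardise_columns <- function(X) {
  X <- .validate_matrix(X)
  ctr <- scale(X, center = TRUE, scale = FALSE)
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  sweep(ctr, 2, s, "/")
}

#' Write a matrix as CSV with row identifiers
#'
#' Round-trips with [read_matrix()].
#'
#' @param X Matrix.
#' @param path Output path.
#' @param id_name Header of the identifier column.
#' @export
write_matrix <- function(X, path, id_name = "id") {
  df <- data.frame(rownames(X) %||% seq_len(nrow(X)), X,
                   check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full clustering pipeline and write a result bundle
#'
#' Orchestrates one reproducible end-to-end analysis: read (or accept) a data
#' matrix, optionally standardise, fit [sugs_varsel()] (or plain [sugs()]),
#' and write all outputs as plain text next to `output_prefix`: allocations,
#' variable mask and BMA scores, the model-averaged co-clustering matrix
#' (dense and long format), the consensus partition, the per-model score
#' table, an evaluation report when ground truth is supplied, a log, and the
#' resolved configuration with the seed, so any bundle can be regenerated.
#'
#' @param config Named list (or path to a JSON file) with entries: `input`
#'   (path) or `X` (matrix); optional `labels`, `truth_mask`; `method`
#'   ("sugsvarsel" or "sugs"); `standardise`; `seed`; `output_prefix`; plus
#'   any arguments of [sugs_varsel()] / [sugs()] (e.g. `orderings`,
#'   `n_subsamples`, `subsample_fraction`, `iterations`, `prior_on`,
#'   `occam_ratio`, `criterion`, `workers`).
#' @return Invisibly, a list with the fitted object and the written paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(method = "sugsvarsel", standardise = FALSE, seed = 1L,
         output_prefix = "sugsclust_run", orderings = 10, n_subsamples = 10,
         subsample_fraction = 0.1, init_orderings = 10, iterations = 2,
         prior_on = 0.5, occam_ratio = 100,
         criterion = if (identical(config$method, "sugs")) "pml" else "ml",
         consensus_h = 0.5, consensus_k = NULL, workers = 1L,
         prior = list(m = 0, c = 1, a = 1, b = 1),
         grid = list(L = 30, range = c(0.01, 100))),
    config)
  X <- if (!is.null(cfg$X)) .validate_matrix(cfg$X) else
    read_matrix(cfg$input)
  if (isTRUE(cfg$standardise)) X <- standardise_columns(X)
  prior <- do.call(ng_params, as.list(cfg$prior))
  grid <- beta_grid(L = cfg$grid$L, range = cfg$grid$range)
  set.seed(cfg$seed)

  prefix <- cfg$output_prefix
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  logf <- paste0(prefix, "_log.txt")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("pipeline start: method=%s n=%d D=%d seed=%d", cfg$method,
          nrow(X), ncol(X), cfg$seed)

  if (cfg$method == "sugs") {
    fit <- sugs(X, orderings = cfg$orderings, criterion = cfg$criterion,
                prior = prior, grid = grid, workers = cfg$workers)
    records <- fit$records
  } else {
    fit <- sugs_varsel(X, subsample_fraction = cfg$subsample_fraction,
                       n_subsamples = cfg$n_subsamples,
                       orderings = cfg$orderings,
                       init_orderings = cfg$init_orderings,
                       iterations = cfg$iterations, prior = prior,
                       grid = grid, prior_on = cfg$prior_on,
                       criterion = cfg$criterion,
                       occam_ratio = cfg$occam_ratio,
                       consensus_k = cfg$consensus_k,
                       consensus_h = cfg$consensus_h, workers = cfg$workers)
    records <- fit$records
  }
  for (r in records)
    logline("model: clusters=%d vars_on=%d log_ml=%.6f log_pml=%.6f",
            r$n_clusters, sum(r$mask), r$log_ml, r$log_pml)

  ids <- rownames(X) %||% paste0("obs", seq_len(nrow(X)))
  vars <- colnames(X) %||% paste0("var", seq_len(ncol(X)))
  paths <- list()
  wr <- function(df, name) {
    p <- paste0(prefix, "_", name, ".csv")
    utils::write.table(df, p, sep = ",", row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
  }
  wr(data.frame(id = ids, cluster = fit$allocations), "allocations")
  mt <- data.frame(ordering = seq_along(records),
                   clusters = vapply(records, function(r) r$n_clusters, integer(1)),
                   variables_on = vapply(records, function(r) sum(r$mask), integer(1)),
                   log_ml = vapply(records, function(r) r$log_ml, numeric(1)),
                   log_pml = vapply(records, function(r) r$log_pml, numeric(1)))
  wr(mt, "models")
  if (inherits(fit, "sugsvarsel")) {
    wr(data.frame(variable = vars, indicator = fit$mask,
                  bma_score = fit$variable_scores), "mask")
    S <- fit$bmac
    dimnames(S) <- list(ids, ids)
    pS <- paste0(prefix, "_bmac.csv"); write_matrix(S, pS); paths$bmac <- pS
    long <- data.frame(i = ids[row(S)[lower.tri(S, diag = TRUE)]],
                       j = ids[col(S)[lower.tri(S, diag = TRUE)]],
                       probability = S[lower.tri(S, diag = TRUE)])
    wr(long, "bmac_long")
    wr(data.frame(id = ids, cluster = fit$consensus), "consensus")
  }
  if (!is.null(cfg$labels)) {
    rep <- evaluate_clustering(fit$allocations, cfg$labels,
                               mask = if (inherits(fit, "sugsvarsel")) fit$mask,
                               truth_mask = cfg$truth_mask)
    pe <- paste0(prefix, "_evaluation.json")
    jsonlite::write_json(unclass(rep), pe, auto_unbox = TRUE, digits = NA)
    paths$evaluation <- pe
    logline("evaluation: ari=%.4f", rep$ari)
  }
  cfg_out <- cfg
  cfg_out$X <- NULL; cfg_out$labels <- NULL; cfg_out$truth_mask <- NULL
  pc <- paste0(prefix, "_config.json")
  jsonlite::write_json(cfg_out, pc, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths$config <- pc
  logline("pipeline done: %d clusters", max(fit$allocations))
  invisible(list(fit = fit, paths = paths))
}
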