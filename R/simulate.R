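#' Simulate a POBDS time series
#'
#' Generates a paired trajectory of hidden Boolean states and noisy
#' observations: the state path follows the noisy synchronous dynamics
#' (`X_k = f(X_{k-1}) XOR n_k`, `n_k` i.i.d. Bernoulli(`p`)) from `x0`
#' (drawn uniformly over the 2^d states when not supplied — the same
#' uninformative prior the filters default to), and each row of `Y` is drawn
#' from the observation channel given the state at that time.
#'
#' The seed drives the state path and the observation noise through separate
#' sub-streams, so rerunning with a different observation model leaves the
#' hidden state path untouched.
#'
#' @param net A `boolean_network`.
#' @param n_data Number of time points (>= 1).
#' @param p Process-noise intensity in \[0, 0.5\].
#' @param obs_model An `obs_model` (or `list(name, params)`; see
#'   [as_obs_model()]).
#' @param x0 Optional initial Boolean state (length d).
#' @param seed Optional integer seed; when given the trajectory is fully
#'   reproducible.
#' @return A `pobds_trajectory`: `X` (n x d integer states), `Y` (n x d
#'   observations), `genes`, and `meta` (parameters and seed used).
#' @examples
#' net <- p53_network(1)
#' traj <- simulate_network(net, 25, p = 0.01,
#'                          obs_model = obs_gaussian(1, 2, 5, 2), seed = 7)
#' head(traj$X)
#' @export
simulate_network <- function(net, n_data, p, obs_model, x0 = NULL, seed = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  n_data <- as.integer(n_data)
  if (length(n_data) != 1L || is.na(n_data) || n_data < 1L)
    stop("'n_data' must be a positive integer")
  if (p < 0 || p > 0.5) stop("'p' must be in [0, 0.5]")
  spec <- as_obs_model(obs_model)
  d <- length(net$genes)
  if (!is.null(x0)) x0 <- as_state_matrix(x0, d, "x0")[1L, ]

  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 2L)  # state stream, observation stream

  set.seed(sub[1L])
  X <- matrix(0L, n_data, d, dimnames = list(NULL, net$genes))
  X[1L, ] <- if (is.null(x0)) as.integer(stats::runif(d) < 0.5) else x0
  if (n_data > 1L) {
    noise <- matrix(stats::runif((n_data - 1L) * d) < p, n_data - 1L, d)
    for (k in 2:n_data)
      X[k, ] <- (network_step(net, X[k - 1L, ]) + noise[k - 1L, ]) %% 2L
  }

  set.seed(sub[2L])
  Y <- sample_observation(spec, X)

  structure(list(X = X, Y = Y, genes = net$genes,
                 meta = list(n_data = n_data, p = p, obs_model = spec,
                             x0 = x0, seed = if (is.null(seed)) NA_integer_ else seed)),
            class = "pobds_trajectory")
}

#' @export
print.pobds_trajectory <- function(x, ...) {
  cat(sprintf("POBDS trajectory: %d time points, %d genes (%s), %s observations\n",
              nrow(x$X), length(x$genes), paste(x$genes, collapse = ", "),
              x$meta$obs_model$type))
  invisible(x)
}

#' Write / read a trajectory as diff-able text files
#'
#' `write_trajectory()` writes three files sharing a prefix:
#' `<prefix>.states.tsv` (tab-separated hidden states, header = gene names),
#' `<prefix>.obs.tsv` (observations, reals serialized at full precision so
#' the round trip is exact), and `<prefix>.meta.json` (model parameters and
#' seed). `read_trajectory()` reads them back.
#'
#' @param traj A `pobds_trajectory`.
#' @param prefix Path prefix for the three files.
#' @return `write_trajectory()` the prefix invisibly; `read_trajectory()` a
#'   `pobds_trajectory` (with `meta` when the sidecar is present).
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "pobds_trajectory"))
  write_num_tsv(traj$X, traj$genes, paste0(prefix, ".states.tsv"))
  write_num_tsv(traj$Y, traj$genes, paste0(prefix, ".obs.tsv"))
  meta <- traj$meta
  meta$obs_model <- unclass(meta$obs_model)
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

write_num_tsv <- function(m, genes, path) {
  fmt <- function(v) {
    if (is.integer(v) || all(v == round(v))) sprintf("%d", as.integer(v))
    else sprintf("%.17g", v)
  }
  rows <- apply(m, 1L, function(r) paste(fmt(r), collapse = "\t"))
  writeLines(c(paste(genes, collapse = "\t"), rows), path)
}

read_num_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("trajectory file not found: '%s'", path))
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 2L) stop(sprintf("'%s': expected a header and at least one row", path))
  genes <- strsplit(ln[1], "\t", fixed = TRUE)[[1]]
  cells <- strsplit(ln[-1], "\t", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != length(genes)))
    stop(sprintf("'%s': row %d has %d columns, header has %d",
                 path, which(nc != length(genes))[1], nc[nc != length(genes)][1],
                 length(genes)))
  m <- do.call(rbind, lapply(cells, function(r) suppressWarnings(as.numeric(r))))
  if (sum(is.na(m)) > sum(unlist(cells) %in% c("NA", "NaN")))
    stop(sprintf("'%s': non-numeric cell", path))
  colnames(m) <- genes
  m
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(prefix) {
  X <- read_num_tsv(paste0(prefix, ".states.tsv"))
  Y <- read_num_tsv(paste0(prefix, ".obs.tsv"))
  if (!identical(dim(X), dim(Y)) || !identical(colnames(X), colnames(Y)))
    stop("state and observation files disagree in shape or gene names")
  if (!all(X %in% c(0, 1))) stop("state file contains non-Boolean entries")
  storage.mode(X) <- "integer"
  meta_path <- paste0(prefix, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  structure(list(X = X, Y = Y, genes = colnames(X), meta = meta),
            class = "pobds_trajectory")
}
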