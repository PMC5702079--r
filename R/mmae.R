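#' Build a bank of candidate POBDS models
#'
#' Multiple-model estimation handles two kinds of uncertainty at once: which
#' network generated the data, and how intense its process noise is. The
#' bank is the Cartesian product of candidate networks and candidate noise
#' intensities, ordered networks-outer (row-major): net1 with every p, then
#' net2 with every p, and so on. All networks must share the same gene set
#' and order.
#'
#' @param nets A list of `boolean_network` objects (a single network is
#'   accepted bare).
#' @param ps Numeric vector of candidate process-noise intensities.
#' @param prior Optional prior probability for each of the
#'   `length(nets) * length(ps)` models; `NULL` or `NA` means uniform.
#' @return A `model_bank`: `models` (list of `list(net, p)`), `labels`,
#'   `prior`, `genes`.
#' @export
make_model_bank <- function(nets, ps, prior = NULL) {
  if (inherits(nets, "boolean_network")) nets <- list(nets)
  if (length(nets) < 1L || length(ps) < 1L) stop("need at least one network and one p")
  if (!all(vapply(nets, inherits, TRUE, "boolean_network")))
    stop("'nets' must be a list of boolean_network objects")
  genes <- nets[[1]]$genes
  for (i in seq_along(nets))
    if (!identical(nets[[i]]$genes, genes))
      stop("all candidate networks must share the same gene set and order")
  if (any(ps < 0 | ps > 0.5)) stop("every 'p' must lie in [0, 0.5]")
  net_names <- names(nets)
  if (is.null(net_names)) net_names <- paste0("net", seq_along(nets))
  models <- list(); labels <- character(0)
  for (i in seq_along(nets))
    for (j in seq_along(ps)) {
      models[[length(models) + 1L]] <- list(net = nets[[i]], p = ps[j])
      labels <- c(labels, sprintf("%s,p=%g", net_names[i], ps[j]))
    }
  m <- length(models)
  if (is.null(prior) || (length(prior) == 1L && is.na(prior)))
    prior <- rep(1 / m, m)
  if (length(prior) != m) stop(sprintf("'prior' must have length %d", m))
  if (any(prior < 0) || sum(prior) <= 0) stop("'prior' must be non-negative with positive sum")
  structure(list(models = models, labels = labels, prior = prior / sum(prior),
                 genes = genes),
            class = "model_bank")
}

#' @export
print.model_bank <- function(x, ...) {
  cat(sprintf("Model bank: %d candidate models over genes %s\n",
              length(x$models), paste(x$genes, collapse = ", ")))
  for (i in seq_along(x$labels))
    cat(sprintf("  [%d] %s  (prior %.3g)\n", i, x$labels[i], x$prior[i]))
  invisible(x)
}

#' Multiple Model Adaptive Estimation
#'
#' Runs one Boolean Kalman filter per candidate model in parallel. After
#' each observation, every model's weight is multiplied by its per-step
#' predictive likelihood (the BKF's normalizer) and the weights are
#' renormalized across models — all in log space, since per-step likelihoods
#' on count data span many orders of magnitude. By Bayes' rule the weight of
#' model m after k steps is proportional to `prior_m * P(Y_{1:k} | m)`. The
#' run stops at the first step whose maximum posterior reaches `threshold`
#' (checked after the update); if the threshold is never crossed the filters
#' run to the end of the series and no model is selected, with the final
#' argmax reported separately.
#'
#' @param bank A `model_bank` from [make_model_bank()].
#' @param spec An `obs_model` shared by all candidate models.
#' @param Y n x d observation matrix.
#' @param threshold Stopping threshold in (0, 1].
#' @param prior Optional prior overriding the bank's.
#' @param stop_on_threshold When `FALSE`, keep filtering to the end of `Y`
#'   and record the full posterior history even after a crossing (useful for
#'   studying when each model's own posterior first crosses).
#' @return An `mmae_result`: `posterior_history` (one row per processed
#'   step), `selected_model` (index, or `NA` if never crossed),
#'   `stop_time` (first crossing step, or `NA`), `argmax_final`, `labels`,
#'   `threshold`.
#' @export
run_mmae <- function(bank, spec, Y, threshold = 0.8, prior = NULL,
                     stop_on_threshold = TRUE) {
  stopifnot(inherits(bank, "model_bank"))
  spec <- as_obs_model(spec)
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  d <- length(bank$genes)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  if (ncol(Y) != d) stop(sprintf("'Y' must have %d columns", d))
  n <- nrow(Y)
  if (n < 1L) stop("empty observation sequence")
  m <- length(bank$models)
  if (!is.null(prior)) {
    if (length(prior) != m) stop(sprintf("'prior' must have length %d", m))
    prior <- prior / sum(prior)
  } else prior <- bank$prior

  tms <- lapply(bank$models, function(mod) build_transition_matrix(mod$net, mod$p))
  n_states <- 2L^d
  pdv <- matrix(1 / n_states, n_states, m)
  logw <- log(prior)
  hist <- matrix(NA_real_, n, m, dimnames = list(NULL, bank$labels))
  selected <- NA_integer_; stop_time <- NA_integer_

  for (k in seq_len(n)) {
    for (j in seq_len(m)) {
      st <- bkf_step(pdv[, j], tms[[j]], spec, Y[k, ])
      pdv[, j] <- st$posterior
      logw[j] <- logw[j] + st$log_normalizer
    }
    logw <- logw - logsumexp(logw)
    hist[k, ] <- exp(logw)
    if (is.na(stop_time) && max(hist[k, ]) >= threshold) {
      stop_time <- k
      selected <- as.integer(which.max(hist[k, ]))  # ties -> lowest index
      if (stop_on_threshold) break
    }
  }
  processed <- if (!is.na(stop_time) && stop_on_threshold) stop_time else n
  hist <- hist[seq_len(processed), , drop = FALSE]
  structure(list(posterior_history = hist,
                 selected_model = selected,
                 stop_time = stop_time,
                 argmax_final = as.integer(which.max(hist[processed, ])),
                 labels = bank$labels, threshold = threshold,
                 prior = prior),
            class = "mmae_result")
}

#' @export
print.mmae_result <- function(x, ...) {
  if (!is.na(x$selected_model))
    cat(sprintf("MMAE: model [%d] %s crossed threshold %.2f at time %d (posterior %.3f)\n",
                x$selected_model, x$labels[x$selected_model], x$threshold,
                x$stop_time,
                x$posterior_history[min(x$stop_time, nrow(x$posterior_history)),
                                    x$selected_model]))
  else
    cat(sprintf("MMAE: threshold %.2f never crossed in %d steps; final argmax [%d] %s (posterior %.3f)\n",
                x$threshold, nrow(x$posterior_history), x$argmax_final,
                x$labels[x$argmax_final],
                x$posterior_history[nrow(x$posterior_history), x$argmax_final]))
  invisible(x)
}
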