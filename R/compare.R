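#' Bayesian Information Criterion
#'
#' `BIC = -2 * LL + k * log(T)` with the natural logarithm, where `LL` is
#' the maximized log-likelihood, `k` the number of free parameters and `T`
#' the number of choices the likelihood sums over. Smaller is better.
#'
#' @param best_loglik Maximized log-likelihood (a log, so usually
#'   negative).
#' @param k Number of free parameters.
#' @param n_trials Number of trials T.
#' @return Scalar BIC.
#' @examples
#' bic(-500, 2, 1000) # 1000 + 2 * log(1000)
#' @export
bic <- function(best_loglik, k, n_trials) {
  if (any(n_trials < 1)) stop("n_trials must be >= 1", call. = FALSE)
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  -2 * best_loglik + k * log(n_trials)
}

#' Fit several models to one dataset and select by BIC
#'
#' Each candidate model is fit with [fit_mle()]; models are scored with
#' [bic()] and the smallest BIC wins. BIC ties (within 1e-6) are broken
#' toward the model with fewer parameters. A model whose fit fails is
#' excluded with a warning; if every fit fails, an error is raised.
#'
#' @param data A [behav_data()].
#' @param model_ids Character vector of candidate models.
#' @param options A [fit_options()] shared across models.
#' @return A list of class `comparison_result`: `table` (data frame with
#'   `model`, `k`, `loglik`, `bic`), `selected` (winning model id) and
#'   `fits` (the underlying `fit_result`s).
#' @export
compare_models <- function(data, model_ids, options = fit_options()) {
  if (!length(model_ids)) stop("no models given", call. = FALSE)
  fits <- setNames(vector("list", length(model_ids)), model_ids)
  rows <- list()
  for (m in model_ids) {
    f <- tryCatch(fit_mle(m, data, options), error = function(e) {
      warning("fit of ", m, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    fits[[m]] <- f
    if (is.null(f)) next
    k <- n_params(m)
    rows[[m]] <- data.frame(model = m, k = k, loglik = f$best_loglik,
                            bic = bic(f$best_loglik, k, f$n_trials))
  }
  if (!length(rows)) stop("all model fits failed", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # minimum BIC; near-ties resolved toward parsimony
  near <- tab$bic <= min(tab$bic) + 1e-6
  cand <- tab[near, ]
  selected <- cand$model[order(cand$k, cand$bic)][1]
  structure(list(table = tab, selected = selected, fits = fits),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> selected:", x$selected, "\n")
  print(transform(x$table, loglik = round(loglik, 2), bic = round(bic, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Model-recovery experiment (confusion matrix)
#'
#' For each candidate model: draw parameters from its prior, simulate a
#' session on `task`, fit every candidate model and record which one wins
#' by BIC. Repeating `n_reps` times per generating model yields the
#' confusion matrix `p(fit model | simulated model)` — rows are generating
#' models, columns best-fitting models, each row summing to 1.
#'
#' @param model_ids Candidate models (both generating and fitting side).
#' @param priors Named list: per model, a prior list as accepted by
#'   [sample_parameters()]. Defaults to [recovery_priors()] panel A.
#' @param n_reps Simulations per generating model.
#' @param task Task the agents perform.
#' @param options A [fit_options()].
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return A list of class `confusion_matrix`: `models`, integer `counts`,
#'   row-stochastic `probabilities`, `n_reps`.
#' @export
model_recovery <- function(model_ids, priors = NULL, n_reps = 100L,
                           task = bandit_task(2, 1000, c(0.2, 0.8)),
                           options = fit_options(), seed = 1L) {
  if (is.null(priors)) {
    priors <- setNames(lapply(model_ids, recovery_priors, panel = "A"),
                       model_ids)
  }
  n_models <- length(model_ids)
  counts <- matrix(0L, n_models, n_models,
                   dimnames = list(sim = model_ids, fit = model_ids))
  for (mi in seq_len(n_models)) {
    m <- model_ids[mi]
    for (rep in seq_len(n_reps)) {
      rep_seed <- (seed * 1000L + mi * 101L + rep * 7L) %% 2147483647L
      set.seed(rep_seed)
      theta <- sample_parameters(m, priors[[m]])
      data <- simulate_agent(theta, task, seed = rep_seed + 1L)
      cmp <- compare_models(data, model_ids,
                            options = within_options(options, rep_seed + 2L))
      counts[m, cmp$selected] <- counts[m, cmp$selected] + 1L
    }
  }
  structure(list(models = model_ids, counts = counts,
                 probabilities = counts / n_reps, n_reps = n_reps),
            class = "confusion_matrix")
}

# fit options with a replicate-specific seed
within_options <- function(options, seed) {
  options$seed <- as.integer(seed %% 2147483647)
  options
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> p(fit | simulated),", x$n_reps,
      "simulations per row\n")
  print(round(x$probabilities, 2))
  invisible(x)
}

#' Invert a confusion matrix with Bayes rule
#'
#' Converts `p(fit model | simulated model)` into
#' `p(simulated model | fit model)` under a prior over generating models
#' (uniform by default):
#' `p(sim = A | fit = B) = p(fit = B | sim = A) p(A) / sum_A' p(fit = B | sim = A') p(A')`.
#' A fit model that never wins has an undefined column, returned as `NA`
#' and flagged.
#'
#' @param cm A `confusion_matrix` (or a row-stochastic matrix).
#' @param model_prior Prior masses over generating models (summing to 1).
#' @return A list of class `inversion_matrix`: `probabilities` (rows =
#'   simulated models, columns = fit models; each defined column sums
#'   to 1), `model_prior`, `undefined_columns`.
#' @export
invert_confusion <- function(cm, model_prior = NULL) {
  probs <- if (inherits(cm, "confusion_matrix")) cm$probabilities else as.matrix(cm)
  n <- nrow(probs)
  if (is.null(model_prior)) model_prior <- rep(1 / n, n)
  if (abs(sum(model_prior) - 1) > 1e-8) {
    stop("model_prior must sum to 1", call. = FALSE)
  }
  joint <- probs * model_prior            # p(fit | sim) p(sim)
  marginal <- colSums(joint)              # p(fit)
  inv <- sweep(joint, 2, marginal, "/")
  undefined <- marginal <= 0
  inv[, undefined] <- NA_real_
  structure(list(probabilities = inv, model_prior = model_prior,
                 undefined_columns = colnames(probs)[undefined] %||% which(undefined)),
            class = "inversion_matrix")
}

#' @export
print.inversion_matrix <- function(x, ...) {
  cat("<inversion_matrix> p(simulated | fit)\n")
  print(round(x$probabilities, 2))
  if (length(x$undefined_columns)) {
    cat("undefined columns (fit model never selected):",
        paste(x$undefined_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a confusion or inversion matrix to CSV
#'
#' @param x A `confusion_matrix` or `inversion_matrix`.
#' @param path Output path. Model ids appear as header row and first
#'   column.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  probs <- x$probabilities
  df <- data.frame(model = rownames(probs), probs, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
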