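#' Prior samplers for model parameters
#'
#' Priors are named lists of sampling functions (each takes a count `n`
#' and returns `n` draws), keyed by parameter name. They drive both the
#' generative side of recovery experiments and the initial points of the
#' multistart fitter. Exponential priors are parameterized by their MEAN
#' (so `prior_exp(10)` has mean 10), matching the identifiable softmax
#' range discussed alongside them; an optional `shift` adds a constant to
#' every draw (e.g. shifting inverse temperatures up by 1 to reduce choice
#' noise).
#'
#' @param min,max Uniform support.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_unif <- function(min = 0, max = 1) {
  force(min); force(max)
  function(n) runif(n, min, max)
}

#' @rdname priors
#' @param mean Mean of the exponential distribution.
#' @param shift Constant added to every draw.
#' @export
prior_exp <- function(mean = 1, shift = 0) {
  force(mean); force(shift)
  function(n) rexp(n, rate = 1 / mean) + shift
}

#' @rdname priors
#' @param value Constant returned for every draw.
#' @export
prior_const <- function(value) {
  force(value)
  function(n) rep(value, n)
}

#' Default parameter priors for a model
#'
#' Unit-interval parameters (`b`, `epsilon`, `alpha`, `alpha_c`) are
#' uniform on \[0, 1\]; inverse temperatures (`beta`, `beta_c`) are
#' exponential with mean 1; the side bias is uniform on \[-1, 1\], a range
#' commensurate with the value differences a two-armed 0.2/0.8 bandit can
#' produce.
#'
#' @param model_id Model identifier.
#' @return Named list of sampler functions.
#' @export
default_priors <- function(model_id) {
  info <- model_info(model_id)
  samplers <- list(
    b = prior_unif(), epsilon = prior_unif(),
    alpha = prior_unif(), alpha_c = prior_unif(),
    beta = prior_exp(1), beta_c = prior_exp(1),
    bias = prior_unif(-1, 1)
  )
  samplers[info$params]
}

#' Priors for the low-noise and high-noise model-recovery regimes
#'
#' `panel = "A"` uses the default priors (inverse temperatures exponential
#' with mean 1, allowing very noisy agents); `panel = "B"` shifts `beta`
#' and `beta_c` up by 1, reducing choice noise and making the models much
#' easier to tell apart.
#'
#' @param model_id Model identifier.
#' @param panel `"A"` (noisy) or `"B"` (low-noise).
#' @return Named list of sampler functions.
#' @export
recovery_priors <- function(model_id, panel = c("A", "B")) {
  panel <- match.arg(panel)
  pr <- default_priors(model_id)
  if (panel == "B") {
    for (nm in intersect(names(pr), c("beta", "beta_c"))) {
      pr[[nm]] <- prior_exp(1, shift = 1)
    }
  }
  pr
}

#' Draw a random parameter set from priors
#'
#' @param model_id Model identifier.
#' @param priors Named list of sampler functions covering every parameter
#'   of the model (default: [default_priors()]).
#' @param q0 Initial option value stored on the resulting set.
#' @return A [param_set()]. Draws falling outside the model's box bounds
#'   (possible only in a negligible exponential tail) are clamped.
#' @export
sample_parameters <- function(model_id, priors = default_priors(model_id),
                              q0 = 0) {
  info <- model_info(model_id)
  missing <- setdiff(info$params, names(priors))
  if (length(missing)) {
    stop("no prior for parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  values <- vapply(info$params, function(nm) priors[[nm]](1L), numeric(1))
  values <- pmin(pmax(values, info$lower), info$upper)
  do.call(param_set, c(list(model_id), as.list(values), list(q0 = q0)))
}
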