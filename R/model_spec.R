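# Model specification: which OU model to fit, multilevel structure,
# parameterization, and measurement-error handling.

#' Specify an OU model
#'
#' @param kind Model family: `"multi_optima"` (fixed regimes only),
#'   `"direct_effect"` / `"multi_optima_direct"` (predictor changes cause an
#'   immediate correlated response; allometric-constraint testing), or
#'   `"adaptive"` / `"multi_optima_adaptive"` (the optimum tracks a
#'   Brownian-motion predictor; requires an ultrametric tree).
#' @param multilevel `"none"`, `"varying_intercepts"` (regime optima drawn
#'   from a population distribution with hyperparameters) or
#'   `"varying_effects"` (joint population distribution of regime optima and
#'   slopes with an LKJ-correlated 2x2 covariance).
#' @param parameterization `"noncentered"` (default; hierarchical parameters
#'   written as hypermean + scale x standardized deviate, which improves
#'   sampler geometry) or `"centered"`.
#' @param slopes `"shared"` (one slope per predictor) or `"by_regime"`
#'   (regime-specific slopes; implied by `varying_effects`).
#' @param me_response,me_predictors Measurement-error handling: `"auto"`
#'   (use it when standard errors are supplied), `"latent"` (require SEs) or
#'   `"none"`.  Response-side latent true values are Gaussian and are
#'   marginalized exactly into diagonal variance inflation; predictor-side
#'   true values are sampled as latent parameters.
#' @param sigma2_x For the adaptive model: `"estimate"` the predictor's BM
#'   variance jointly (weak prior) or `"plugin"` (fix it at the GLS
#'   estimate).
#' @return An object of class `phylou_spec`.
#' @export
ou_model_spec <- function(kind = c("multi_optima", "direct_effect", "adaptive",
                                   "multi_optima_direct", "multi_optima_adaptive"),
                          multilevel = c("none", "varying_intercepts",
                                         "varying_effects"),
                          parameterization = c("noncentered", "centered"),
                          slopes = NULL,
                          me_response = c("auto", "latent", "none"),
                          me_predictors = c("auto", "latent", "none"),
                          sigma2_x = c("estimate", "plugin")) {
  kind <- match.arg(kind)
  multilevel <- match.arg(multilevel)
  parameterization <- match.arg(parameterization)
  me_response <- match.arg(me_response)
  me_predictors <- match.arg(me_predictors)
  sigma2_x <- match.arg(sigma2_x)
  has_pred <- kind %in% c("direct_effect", "adaptive", "multi_optima_direct",
                          "multi_optima_adaptive")
  if (is.null(slopes))
    slopes <- if (multilevel == "varying_effects") "by_regime" else "shared"
  slopes <- match.arg(slopes, c("shared", "by_regime"))
  if (multilevel == "varying_effects") {
    if (!has_pred)
      stop("varying_effects requires a model with at least one continuous predictor")
    slopes <- "by_regime"
  }
  if (slopes == "by_regime" && !has_pred)
    stop("by-regime slopes require a model with a continuous predictor")
  structure(list(kind = kind, multilevel = multilevel,
                 parameterization = parameterization, slopes = slopes,
                 me_response = me_response, me_predictors = me_predictors,
                 sigma2_x = sigma2_x),
            class = "phylou_spec")
}

#' @export
print.phylou_spec <- function(x, ...) {
  cat(sprintf("phylou_spec: %s | multilevel: %s (%s) | slopes: %s\n",
              x$kind, x$multilevel, x$parameterization, x$slopes))
  invisible(x)
}

# integer codes used by the C++ model
spec_kind_code <- function(spec) {
  switch(spec$kind,
         multi_optima = 0L,
         direct_effect = 1L, multi_optima_direct = 1L,
         adaptive = 2L, multi_optima_adaptive = 2L)
}

spec_ml_code <- function(spec) {
  match(spec$multilevel, c("none", "varying_intercepts", "varying_effects")) - 1L
}
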