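#' Structural-causal-model parameters
#'
#' Container for the numeric constants of the data-generating mechanism.
#' Two latent causes drive the system: tumour aggressiveness `u1` and
#' patient fitness `u2`. Tumour size `x` is a pre-treatment collider
#' (child of both latents), heterogeneity `z` is an independent prognostic
#' factor, treatment `t` depends on fitness only, and the survival outcome
#' `y` is linear in treatment, heterogeneity and aggressiveness. The
#' defaults give `x` a marginal standard deviation of approximately 1 and a
#' true average treatment effect of 1.
#'
#' @param sd_u standard deviation of the latents `u1` and `u2`
#'   (default 0.7071, i.e. sqrt(2)/2 so that `sd(x)` is about 1).
#' @param sd_z standard deviation of the heterogeneity `z`.
#' @param sd_x_noise standard deviation of the Gaussian noise on the
#'   collider `x` around `u1 - u2`.
#' @param treat_offset constant subtracted inside the treatment logit;
#'   larger values make treatment rarer.
#' @param sd_t_noise standard deviation of the Gaussian noise added to the
#'   treatment log-odds (models idiosyncratic treatment preference).
#' @param treatment_effect coefficient of `t` in the outcome equation;
#'   the true average treatment effect.
#' @param coef_z coefficient of `z` in the outcome equation.
#' @param coef_u1 coefficient of `u1` in the outcome equation.
#' @param outcome_offset constant in the outcome equation.
#' @param sd_y_noise standard deviation of the outcome noise.
#'
#' @return An object of class `scm_params` (a named list).
#' @seealso [sample_cohort()]
#' @export
#' @examples
#' p <- scm_params()
#' p$treatment_effect
scm_params <- function(sd_u = 0.7071,
                       sd_z = 1,
                       sd_x_noise = 0.05,
                       treat_offset = 0.5,
                       sd_t_noise = 0.25,
                       treatment_effect = 1,
                       coef_z = -1,
                       coef_u1 = -2,
                       outcome_offset = -0.5,
                       sd_y_noise = 0.05) {
  p <- list(sd_u = sd_u, sd_z = sd_z, sd_x_noise = sd_x_noise,
            treat_offset = treat_offset, sd_t_noise = sd_t_noise,
            treatment_effect = treatment_effect, coef_z = coef_z,
            coef_u1 = coef_u1, outcome_offset = outcome_offset,
            sd_y_noise = sd_y_noise)
  sds <- c("sd_u", "sd_z", "sd_x_noise", "sd_t_noise", "sd_y_noise")
  for (nm in sds) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single strictly positive number", nm))
  }
  structure(p, class = "scm_params")
}

#' @export
print.scm_params <- function(x, ...) {
  cat("Structural causal model parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-17s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Inverse logit (logistic) function
#'
#' Maps log-odds to a probability in (0, 1).
#'
#' @param s numeric vector of log-odds.
#' @return `1 / (1 + exp(-s))`.
#' @export
#' @examples
#' invlogit(0)     # 0.5
#' invlogit(-0.5)  # about 0.378
invlogit <- function(s) stats::plogis(s)

#' Sample a cohort from the structural causal model
#'
#' Draws `n` independent subjects following the collider DAG: latents
#' `u1, u2 ~ N(0, sd_u)`; heterogeneity `z ~ N(0, sd_z)`; collider
#' `x ~ N(u1 - u2, sd_x_noise)`; treatment
#' `t ~ Bern(invlogit(u2 - treat_offset + N(0, sd_t_noise)))`; outcome
#' `y ~ N(treatment_effect * t + coef_z * z + coef_u1 * u1 +
#' outcome_offset, sd_y_noise)`. All scale parameters are standard
#' deviations. Conditioning on `x` (or any proxy of it) opens a backdoor
#' path `t <- u2 -> x <- u1 -> y` and biases the estimated treatment
#' effect; marginally `t` and `y` share no open backdoor path.
#'
#' @param n number of subjects (non-negative integer).
#' @param params an [scm_params()] object.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A `data.frame` of class `cohort` with columns `id` (1..n),
#'   `u1`, `u2`, `z`, `x`, `t` (0/1 integer) and `y`. The empirical
#'   treated fraction is attached as attribute `treated_fraction`.
#' @export
#' @examples
#' co <- sample_cohort(1000, scm_params(), seed = 1)
#' sd(co$x)            # close to 1
#' attr(co, "treated_fraction")
sample_cohort <- function(n, params = scm_params(), seed = 1L) {
  if (!inherits(params, "scm_params")) params <- do.call(scm_params, params)
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("'n' must be a single non-negative integer")
  n <- as.integer(n)
  set.seed(seed)
  u1 <- rnorm(n, 0, params$sd_u)
  u2 <- rnorm(n, 0, params$sd_u)
  z  <- rnorm(n, 0, params$sd_z)
  x  <- rnorm(n, u1 - u2, params$sd_x_noise)
  # noise enters the log-odds additively before the logistic link
  t  <- rbinom(n, 1L, invlogit(rnorm(n, u2 - params$treat_offset,
                                     params$sd_t_noise)))
  y  <- rnorm(n, params$treatment_effect * t + params$coef_z * z +
                params$coef_u1 * u1 + params$outcome_offset,
              params$sd_y_noise)
  co <- data.frame(id = seq_len(n), u1 = u1, u2 = u2, z = z, x = x,
                   t = as.integer(t), y = y)
  class(co) <- c("cohort", "data.frame")
  attr(co, "treated_fraction") <- if (n > 0) mean(t) else NA_real_
  co
}

#' Re-measure the collider on a different scale
#'
#' Produces the *measured* collider under a monotone power transform of the
#' size variable, emulating a mismatch between the scale on which size
#' drives the data-generating mechanism and the scale on which it is
#' measured (e.g. a diameter-linear collider measured in units of volume, a
#' power-3 mismatch). The standardized input is interpreted as a z-score
#' of the log of the nodule's linear dimension (a diameter-like scale);
#' it is mapped to that positive scale via `exp(x * sdlog + meanlog)`,
#' raised to the mode's power, and the powered values are re-standardized
#' to zero mean and unit variance over the cohort. Basing the positive
#' mapping on the linear dimension keeps the power-3 scenarios at the
#' severity of a physical diameter-versus-volume mismatch (correlation of
#' about 0.8 between the scales) rather than an exponential one.
#'
#' @param x numeric vector, the standardized collider.
#' @param mode one of `"identity"` (standardize only), `"area"` (power 1,
#'   the reference measurement scale), `"volume"` (power 3: a
#'   diameter-linear collider measured in units of volume) or
#'   `"diameter"` (power 1/3: a volume-linear collider measured as
#'   diameter).
#' @param meanlog,sdlog parameters of the positive mapping; the defaults
#'   correspond to linear dimensions of roughly 4-25 mm over +/- 3
#'   standard deviations.
#' @return Numeric vector of the same length, re-standardized. Strictly
#'   monotone in the input for every mode, so rank order is preserved.
#' @export
#' @examples
#' x <- rnorm(100)
#' v <- collider_scale_transform(x, "volume")
#' cor(x, v, method = "spearman")  # exactly 1
collider_scale_transform <- function(x, mode = c("identity", "area",
                                                 "diameter", "volume"),
                                     meanlog = 2.35, sdlog = 0.285) {
  mode <- match.arg(mode)
  if (!all(is.finite(x))) stop("'x' must be finite")
  if (mode == "identity") {
    v <- x
  } else {
    p <- switch(mode, area = 1, volume = 3, diameter = 1 / 3)
    v <- exp(x * sdlog + meanlog)^p
  }
  s <- stats::sd(v)
  if (length(x) < 2L || s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

#' Write / read a cohort as a tab-delimited table
#'
#' @param cohort a cohort `data.frame` from [sample_cohort()].
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  co <- utils::read.table(path, header = TRUE, sep = "\t")
  class(co) <- c("cohort", "data.frame")
  co
}
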