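#' Random draws from the inverse-Gaussian distribution
#'
#' Michael-Schucany-Haas transformation method. Parameterised by the mean and
#' the shape `lambda`, so that the variance is `mean^3 / lambda`.
#'
#' @param n number of draws.
#' @param mean mean (> 0), recycled.
#' @param shape shape parameter lambda (> 0), recycled.
#' @return numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mean, shape) {
  stopifnot(all(mean > 0), all(shape > 0))
  mean <- rep_len(mean, n); shape <- rep_len(shape, n)
  y <- rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Simulate a clustered cohort feature table
#'
#' Generates the per-motor-unit outcome table the statistical layer consumes:
#' `n_subjects` subjects, each contributing `n_mus_per_cell` motor units at
#' every time point. Time-point effects enter as multipliers on the marginal
#' mean; subject-level clustering enters as a Gaussian random intercept on
#' the link scale. Outcomes are drawn from the stated family with dispersion
#' `phi` (gamma: shape `1/phi`; inverse-Gaussian: variance `phi * mu^3`).
#' The default of 11 subjects mirrors the cohort size the package's
#' statistical layer is designed around.
#'
#' @param effects named vector of positive mean multipliers, one per time
#'   point; names define the time-point levels (first level = reference).
#' @param n_subjects number of subjects (>= 2).
#' @param n_mus_per_cell motor units per subject and time point.
#' @param base_mean marginal mean at multiplier 1.
#' @param family `"gamma"` or `"inverse-gaussian"`.
#' @param link `"identity"`, `"inverse"`, `"inverse-squared"` or `"log"`.
#' @param dispersion GLM dispersion phi.
#' @param subject_sd SD of the subject random intercept on the link scale;
#'   default 10 percent of `|linkfun(base_mean)|`.
#' @param feature_name,contraction_level labels copied into the table.
#' @param seed integer seed; fully determines the table.
#' @return data.frame with columns `subject_id`, `time_point`,
#'   `contraction_level`, `mu_id`, `feature_name`, `value`.
#' @export
#' @examples
#' tab <- simulate_cohort_features(c(LS0 = 1, LS10 = 1.2, AR21 = 1), seed = 7)
#' aggregate(value ~ time_point, tab, mean)
simulate_cohort_features <- function(effects = c(LS0 = 1, LS10 = 1, AR21 = 1),
                                     n_subjects = 11, n_mus_per_cell = 20,
                                     base_mean = 100,
                                     family = c("gamma", "inverse-gaussian"),
                                     link = c("identity", "inverse",
                                              "inverse-squared", "log"),
                                     dispersion = 0.1, subject_sd = NULL,
                                     feature_name = "feature",
                                     contraction_level = 10, seed = 1) {
  family <- match.arg(family)
  link <- match.arg(link)
  if (!all(effects > 0)) stop("effect multipliers must be > 0", call. = FALSE)
  if (is.null(names(effects)) || any(!nzchar(names(effects))))
    stop("effects must be a named vector of time points", call. = FALSE)
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  stopifnot(base_mean > 0, dispersion > 0, n_mus_per_cell >= 1)
  lf <- link_funs(link)
  if (is.null(subject_sd)) subject_sd <- 0.1 * abs(lf$linkfun(base_mean))

  tps <- names(effects)
  with_seed(derive_seed(seed, "cohort", feature_name), {
    b <- rnorm(n_subjects, 0, subject_sd)
    d <- expand.grid(mu_id = seq_len(n_mus_per_cell),
                     subject_id = factor(seq_len(n_subjects)),
                     time_point = factor(tps, levels = tps),
                     KEEP.OUT.ATTRS = FALSE)
    eta <- lf$linkfun(base_mean * effects[as.character(d$time_point)]) +
      b[as.integer(d$subject_id)]
    mu <- lf$linkinv(eta)
    if (any(!is.finite(mu) | mu <= 0))
      stop("subject_sd too large for this link: non-positive means generated",
           call. = FALSE)
    d$value <- if (family == "gamma") {
      shape <- 1 / dispersion
      rgamma(nrow(d), shape = shape, scale = mu / shape)
    } else {
      rinvgauss(nrow(d), mean = mu, shape = 1 / dispersion)
    }
    d$feature_name <- feature_name
    d$contraction_level <- contraction_level
    d[, c("subject_id", "time_point", "contraction_level", "mu_id",
          "feature_name", "value")]
  })
}

link_funs <- function(link) {
  switch(link,
         "identity" = list(linkfun = identity, linkinv = identity),
         "inverse" = list(linkfun = function(mu) 1 / mu,
                          linkinv = function(eta) 1 / eta),
         "inverse-squared" = list(linkfun = function(mu) 1 / mu^2,
                                  linkinv = function(eta) 1 / sqrt(eta)),
         "log" = list(linkfun = log, linkinv = exp),
         stop("unknown link: ", link, call. = FALSE))
}
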