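#' Specify a clustered GLM for one MU-level feature
#'
#' The statistical layer models each positive-valued feature with a gamma or
#' inverse-Gaussian GLM, time point as the fixed effect and subject as the
#' cluster variable. The supported link menu is identity, inverse,
#' inverse-squared and log (the log link is excluded from the default
#' candidate menu, see [candidate_specs()]).
#'
#' @param feature_name feature this spec applies to.
#' @param family `"gamma"` or `"inverse-gaussian"`.
#' @param link `"identity"`, `"inverse"`, `"inverse-squared"` or `"log"`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(feature_name = "feature",
                       family = c("gamma", "inverse-gaussian"),
                       link = c("identity", "inverse", "inverse-squared",
                                "log")) {
  family <- match.arg(family)
  link <- match.arg(link)
  structure(list(feature_name = feature_name, family = family, link = link),
            class = "model_spec")
}

# stats::family object for a model_spec
spec_family <- function(spec) {
  lk <- switch(spec$link, "inverse-squared" = "1/mu^2", spec$link)
  if (spec$family == "gamma") Gamma(link = lk) else inverse.gaussian(link = lk)
}

#' Canonical link of a family
#'
#' Inverse for the gamma distribution, inverse-squared for the
#' inverse-Gaussian.
#'
#' @param family `"gamma"` or `"inverse-gaussian"`.
#' @return the canonical link name.
#' @export
canonical_link <- function(family = c("gamma", "inverse-gaussian")) {
  family <- match.arg(family)
  if (family == "gamma") "inverse" else "inverse-squared"
}

#' Default family/link candidate menu
#'
#' The four family/link pairs used by the statistical layer:
#' gamma with inverse link, and inverse-Gaussian with identity, inverse and
#' inverse-squared links. Pass `include_log = TRUE` to add the log link for
#' both families.
#'
#' @param feature_name feature the specs apply to.
#' @param include_log include gamma/log and inverse-gaussian/log?
#' @return list of [model_spec()] objects.
#' @export
candidate_specs <- function(feature_name = "feature", include_log = FALSE) {
  specs <- list(
    model_spec(feature_name, "gamma", "inverse"),
    model_spec(feature_name, "inverse-gaussian", "identity"),
    model_spec(feature_name, "inverse-gaussian", "inverse"),
    model_spec(feature_name, "inverse-gaussian", "inverse-squared"))
  if (include_log)
    specs <- c(specs, list(model_spec(feature_name, "gamma", "log"),
                           model_spec(feature_name, "inverse-gaussian", "log")))
  specs
}

#' Fit a clustered GLM for one feature
#'
#' Fits `value ~ time_point` with subject-level clustering. The primary
#' estimator is a generalized linear mixed model with a subject random
#' intercept ([lme4::glmer()]); when that fit errors or fails to converge
#' (some link/family combinations, notably the inverse-squared link, are
#' numerically fragile under PIRLS), the documented fallback is a fixed-effect
#' GLM with a cluster-robust (CR0, [sandwich::vcovCL()]) covariance, which
#' honours the same clustering contract. Confidence intervals are Wald at the
#' requested level; the overall p-value is a Wald chi-square test of all
#' time-point coefficients.
#'
#' @param table a cohort feature table (see [simulate_cohort_features()]);
#'   rows with other `feature_name`s are dropped when the spec names one.
#' @param spec a [model_spec()].
#' @param method `"glmm"` (random intercept, with GLM fallback) or `"glm"`
#'   (cluster-robust GLM directly).
#' @param conf_level confidence level for the Wald intervals.
#' @return an object of class `model_fit`: `spec`, `method_used`,
#'   `coefficients` (term/estimate/se/ci_lo/ci_hi/p), `overall_p`, `bic`,
#'   `converged`, `n_obs`, `n_subjects`, `vcov` and `df` (the coefficient
#'   covariance and cluster-based degrees of freedom used for intervals),
#'   and the underlying `model`.
#' @export
fit_cluster_glm <- function(table, spec, method = c("glmm", "glm"),
                            conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "model_spec"))
  d <- as.data.frame(table)
  if ("feature_name" %in% names(d) && spec$feature_name %in% d$feature_name)
    d <- d[d$feature_name == spec$feature_name, , drop = FALSE]
  req <- c("subject_id", "time_point", "value")
  if (!all(req %in% names(d)))
    stop("table must have subject_id, time_point, value", call. = FALSE)
  if (any(d$value <= 0))
    stop("outcomes must be strictly positive for gamma/inverse-Gaussian models",
         call. = FALSE)
  d$subject_id <- factor(d$subject_id)
  d$time_point <- factor(d$time_point)
  if (nlevels(d$subject_id) < 2 || nlevels(d$time_point) < 2)
    stop("need at least 2 subjects and 2 time points", call. = FALSE)
  fam <- spec_family(spec)

  fit <- NULL
  method_used <- method
  if (method == "glmm") {
    # a glmer fit that emits convergence warnings can carry a degenerate
    # covariance; treat any warning as failure and use the robust fallback
    warned <- FALSE
    fit <- tryCatch(
      withCallingHandlers(
        suppressMessages(
          lme4::glmer(value ~ time_point + (1 | subject_id), data = d,
                      family = fam)),
        warning = function(w) {
          warned <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (warned || lme4::isSingular(fit) || !is.finite(stats::BIC(fit))))
      fit <- NULL
    if (is.null(fit)) method_used <- "glm"
  }
  if (is.null(fit)) {
    fit <- tryCatch(stats::glm(value ~ time_point, family = fam, data = d),
                    error = function(e) NULL)
    if (is.null(fit))
      return(structure(list(spec = spec, method_used = "glm",
                            coefficients = NULL, overall_p = NA_real_,
                            bic = NA_real_, converged = FALSE,
                            n_obs = nrow(d),
                            n_subjects = nlevels(d$subject_id), model = NULL),
                       class = "model_fit"))
  }

  mixed <- inherits(fit, "merMod")
  beta <- if (mixed) lme4::fixef(fit) else stats::coef(fit)
  V <- if (mixed) as.matrix(stats::vcov(fit))
       else sandwich::vcovCL(fit, cluster = d$subject_id)
  se <- sqrt(diag(V))
  # t reference with cluster-based df: with few subjects the normal Wald
  # interval undercovers, since cluster-level variance is estimated from
  # only n_subjects units
  df_cl <- max(1, nlevels(d$subject_id) - 1)
  z <- stats::qt(1 - (1 - conf_level) / 2, df = df_cl)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_lo = unname(beta - z * se),
                      ci_hi = unname(beta + z * se),
                      p = 2 * stats::pt(-abs(unname(beta) / unname(se)),
                                        df = df_cl))
  tt <- grep("^time_point", names(beta))
  overall_p <- if (length(tt)) {
    b <- beta[tt]
    stat <- drop(t(b) %*% solve(V[tt, tt, drop = FALSE], b))
    stats::pchisq(stat, df = length(tt), lower.tail = FALSE)
  } else NA_real_
  converged <- if (mixed) length(fit@optinfo$conv$lme4$messages) == 0 ||
    is.finite(stats::BIC(fit)) else fit$converged
  structure(list(spec = spec, method_used = method_used, coefficients = coefs,
                 overall_p = overall_p, bic = stats::BIC(fit),
                 converged = isTRUE(converged), n_obs = nrow(d),
                 n_subjects = nlevels(d$subject_id),
                 time_levels = levels(d$time_point),
                 vcov = V, df = df_cl, model = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s ~ time | subject (%s, %s link; %s)\n",
              x$spec$feature_name, x$spec$family, x$spec$link, x$method_used))
  cat(sprintf("  BIC %.1f, overall p %.4g, converged: %s\n",
              x$bic, x$overall_p, x$converged))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}

#' Select the family/link by BIC with a canonical-link tie-break
#'
#' Fits every candidate spec and returns the fit with the smallest BIC. When
#' other fits come within `delta_tol` BIC units of the minimum (a
#' conventional equivalence band of 2 by default), preference goes to a fit
#' using the canonical link of its family — the inverse link for gamma, the
#' inverse-squared link for inverse-Gaussian; among several canonical
#' near-ties the smallest BIC wins.
#'
#' @param table cohort feature table.
#' @param specs list of [model_spec()] candidates (default [candidate_specs()]).
#' @param delta_tol BIC similarity tolerance.
#' @param ... passed to [fit_cluster_glm()].
#' @return the selected `model_fit`, with the per-candidate BIC table in
#'   `attr(, "selection")`.
#' @export
select_by_bic <- function(table, specs = candidate_specs(), delta_tol = 2,
                          ...) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  fits <- lapply(specs, function(s) fit_cluster_glm(table, s, ...))
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$bic),
               logical(1))
  if (!any(ok))
    stop(structure(class = c("nfemg_selection_failure", "error", "condition"),
                   list(message = "no candidate model converged",
                        call = sys.call())))
  fits <- fits[ok]
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  sel <- data.frame(
    family = vapply(fits, function(f) f$spec$family, character(1)),
    link = vapply(fits, function(f) f$spec$link, character(1)),
    bic = bics)
  near <- which(bics - min(bics) < delta_tol)
  canon <- near[vapply(fits[near], function(f)
    f$spec$link == canonical_link(f$spec$family), logical(1))]
  pick <- if (length(canon)) canon[which.min(bics[canon])] else which.min(bics)
  out <- fits[[pick]]
  sel$selected <- seq_along(fits) == pick
  attr(out, "selection") <- sel
  out
}

#' Holm step-down adjustment of p-values
#'
#' Step-down Holm correction: p-values are sorted ascending, the i-th
#' smallest is multiplied by `m - i + 1`, monotonicity is enforced by a
#' running maximum, values are capped at 1 and returned in the original
#' order. Delegates to [stats::p.adjust()].
#'
#' @param raw_p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.04 0.04
holm_adjust <- function(raw_p) {
  if (!is.numeric(raw_p) || any(!is.finite(raw_p)) ||
      any(raw_p < 0 | raw_p > 1))
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  stats::p.adjust(raw_p, method = "holm")
}

#' Holm-adjusted pairwise time-point contrasts
#'
#' Wald tests of every pairwise difference between time-point levels on the
#' link scale, using the fitted coefficients and covariance of a
#' [fit_cluster_glm()] result, with Holm correction across the contrasts.
#'
#' @param fit a `model_fit`.
#' @return data.frame with `contrast`, `estimate`, `se`, `raw_p`, `holm_p`.
#' @export
pairwise_contrasts <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  m <- fit$model
  if (is.null(m)) stop("fit did not converge", call. = FALSE)
  beta <- if (inherits(m, "merMod")) lme4::fixef(m) else stats::coef(m)
  V <- fit$vcov
  lv <- fit$time_levels
  coef_of <- function(l) if (l == lv[1]) 0 else beta[paste0("time_point", l)]
  var_of <- function(la, lb) {
    cv <- function(a, b) {
      if (a == lv[1] || b == lv[1]) return(0)
      V[paste0("time_point", a), paste0("time_point", b)]
    }
    cv(la, la) + cv(lb, lb) - 2 * cv(la, lb)
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  est <- vapply(pairs, function(p) coef_of(p[2]) - coef_of(p[1]), numeric(1))
  se <- sqrt(vapply(pairs, function(p) var_of(p[2], p[1]), numeric(1)))
  raw <- 2 * stats::pt(-abs(est / se), df = fit$df)
  data.frame(contrast = vapply(pairs, function(p)
    paste(p[2], "-", p[1]), character(1)),
    estimate = est, se = se, raw_p = raw, holm_p = holm_adjust(raw))
}
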