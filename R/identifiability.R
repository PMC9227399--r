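#' Finite-difference residual Jacobian
#'
#' Central-difference sensitivities of the residual vector with respect
#' to each free parameter at the fitted point, the `J` of the asymptotic
#' covariance `V = s2 * (J'J)^-1`. The step for parameter `i` is
#' `rel_step * max(|theta_i|, floor)`. If a perturbed simulation fails,
#' the step is halved once before erroring.
#'
#' @param theta_hat Named vector of fitted free parameters.
#' @param obs An `observation_set`.
#' @param spec The [fit_spec()] used for the fit.
#' @param rel_step Relative finite-difference step (default 1e-6).
#' @param floor Absolute step floor (default 1e-8).
#' @return N x q matrix (N residuals, q free parameters), columns in
#'   `spec$free` order.
#' @export
residual_jacobian <- function(theta_hat, obs, spec, rel_step = 1e-6,
                              floor = 1e-8) {
  fd_jacobian(function(theta) fit_residuals(theta, obs, spec),
              theta_hat[spec$free], rel_step = rel_step, floor = floor)
}

#' Central finite-difference Jacobian of a vector-valued function
#'
#' The numerical-differentiation core behind [residual_jacobian()],
#' usable with any residual function. Parameters are perturbed one at a
#' time with step `rel_step * max(|x_i|, floor)`, truncating the lower
#' point at 0 (parameters are non-negative). A failing evaluation at a
#' perturbed point is retried once with a halved step.
#'
#' @param fun Function mapping a named numeric vector to a numeric
#'   vector (same length for all inputs).
#' @param x Point of evaluation (named numeric vector).
#' @inheritParams residual_jacobian
#' @return `length(fun(x))` x `length(x)` matrix.
#' @examples
#' fd_jacobian(function(x) c(x[1] + 2 * x[2], x[1] * x[2]), c(a = 1, b = 3))
#' @export
fd_jacobian <- function(fun, x, rel_step = 1e-6, floor = 1e-8) {
  stopifnot(rel_step > 0, floor > 0)
  f0 <- fun(x)
  J <- matrix(NA_real_, nrow = length(f0), ncol = length(x),
              dimnames = list(names(f0), names(x)))
  for (i in seq_along(x)) {
    h <- rel_step * max(abs(x[[i]]), floor)
    col <- NULL
    for (attempt in 1:2) {
      col <- tryCatch({
        up <- x; up[[i]] <- up[[i]] + h
        dn <- x; dn[[i]] <- max(dn[[i]] - h, 0)
        (fun(up) - fun(dn)) / (up[[i]] - dn[[i]])
      }, error = function(e) NULL)
      if (!is.null(col)) break
      h <- h / 2
    }
    if (is.null(col))
      stop("Jacobian column ", i, " failed even at halved step",
           call. = FALSE)
    J[, i] <- col
  }
  J
}

#' Asymptotic covariance of the parameter estimates
#'
#' The ordinary-least-squares large-sample approximation
#' `V = s2 * (J'J)^-1` with residual variance `s2 = S(theta_hat)/(N-q)`,
#' where `S` is the sum-of-squares loss at the optimum, `N` the number
#' of non-missing scalar observations and `q` the number of free
#' parameters.
#'
#' @param Jmat Residual Jacobian from [residual_jacobian()].
#' @param loss_value `S(theta_hat)`.
#' @param N,q Observation and free-parameter counts (`N > q`).
#' @param max_kappa Condition-number ceiling for `J'J`; beyond it the
#'   matrix is treated as singular and the most collinear parameter
#'   pair is named in the error.
#' @return List with `V` (q x q covariance), `s2`, `SD` (per-parameter
#'   standard deviations), `correlation` (q x q) and `kappa` (condition
#'   number of `J'J`).
#' @export
asymptotic_covariance <- function(Jmat, loss_value, N, q,
                                  max_kappa = 1e14) {
  if (N <= q)
    stop("need more observations than free parameters (N > q)",
         call. = FALSE)
  JtJ <- crossprod(Jmat)
  kappa <- kappa(JtJ, exact = TRUE)
  if (!is.finite(kappa) || kappa > max_kappa) {
    # name the most collinear pair from the normalized JtJ
    d <- sqrt(diag(JtJ))
    C <- JtJ / outer(d, d)
    diag(C) <- 0
    worst <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "J'J is numerically singular (condition %.3g); parameters '%s' and '%s' are nearly collinear -- fix or drop one",
      kappa, colnames(JtJ)[worst[1]], colnames(JtJ)[worst[2]]),
      call. = FALSE)
  }
  s2 <- loss_value / (N - q)
  V <- s2 * solve(JtJ)
  SD <- sqrt(pmax(diag(V), 0))
  corr <- V / outer(SD, SD)
  diag(corr) <- 1
  list(V = V, s2 = s2, SD = setNames(SD, colnames(Jmat)),
       correlation = corr, kappa = kappa)
}

#' Normal 95% confidence limits
#'
#' `estimate +/- 1.96 * SD`. The 1.96 normal multiplier (rather than a
#' t quantile) is the convention the reference identifiability table
#' follows; see the methods vignette.
#'
#' @param estimate Parameter estimate(s).
#' @param SD Asymptotic standard deviation(s), `>= 0`.
#' @return List with vectors `LLC` and `ULC`.
#' @examples
#' confidence_limits(25.46, 4.922)
#' @export
confidence_limits <- function(estimate, SD) {
  if (any(SD < 0)) stop("'SD' must be non-negative", call. = FALSE)
  list(LLC = estimate - 1.96 * SD, ULC = estimate + 1.96 * SD)
}

#' Percent coefficient of variation
#'
#' `100 * SD / |estimate|`. Undefined (NA, with a warning) for a zero
#' estimate: a parameter estimated at exactly zero should be fixed, not
#' summarized by a CV.
#'
#' @inheritParams confidence_limits
#' @return CV in percent.
#' @examples
#' cv_percent(25.46, 4.922)
#' @export
cv_percent <- function(estimate, SD) {
  if (any(SD < 0)) stop("'SD' must be non-negative", call. = FALSE)
  out <- 100 * SD / abs(estimate)
  zero <- estimate == 0
  if (any(zero & SD > 0)) {
    warning("CV undefined for zero estimate; returning NA")
    out[zero & SD > 0] <- NA_real_
  }
  out[zero & SD == 0] <- 0
  out
}

#' A-posteriori identifiability report
#'
#' Computes, for a completed fit, the asymptotic covariance
#' `V = s2 (J'J)^-1`, and per free parameter the SD, CV% and normal 95%
#' confidence limits, plus the parameter correlation matrix. Parameters
#' are flagged for exclusion when they were held fixed at zero, or when
#' a pairwise correlation exceeds `corr_threshold` (the screening used
#' to drop, e.g., a medium-loss rate collinear with the uptake pair).
#' Derived quantities (`kG`, `kXGtot`) are functions of other
#' parameters and never appear as rows.
#'
#' @param fit A `za_fit` from [fit_kinetics()].
#' @param obs The observation set the fit used.
#' @param rel_step Finite-difference step for [residual_jacobian()].
#' @param corr_threshold Absolute pairwise correlation above which a
#'   parameter pair is flagged (default 0.99).
#' @return An `identifiability_report`: data frame `table` with columns
#'   `parameter, estimate, SD, CV_pct, LLC, ULC`, plus `s2`, `N`, `q`,
#'   `correlation`, `kappa` and `excluded` (name + reason).
#' @export
identifiability_report <- function(fit, obs, rel_step = 1e-6,
                                   corr_threshold = 0.99) {
  stopifnot(inherits(fit, "za_fit"))
  spec <- fit$spec
  J <- residual_jacobian(fit$theta_hat, obs, spec, rel_step = rel_step)
  ac <- asymptotic_covariance(J, fit$loss_value, fit$n_obs, fit$n_free)
  est <- fit$theta_hat[spec$free]
  cl <- confidence_limits(est, ac$SD)
  tab <- data.frame(parameter = spec$free, estimate = as.numeric(est),
                    SD = as.numeric(ac$SD),
                    CV_pct = suppressWarnings(
                      as.numeric(cv_percent(est, ac$SD))),
                    LLC = as.numeric(cl$LLC), ULC = as.numeric(cl$ULC),
                    row.names = NULL)
  excluded <- data.frame(parameter = character(), reason = character())
  fixed0 <- names(spec$fixed)[spec$fixed == 0]
  if (length(fixed0))
    excluded <- rbind(excluded,
                      data.frame(parameter = fixed0,
                                 reason = "fixed_at_zero"))
  C <- ac$correlation
  hi <- which(abs(C) > corr_threshold & upper.tri(C), arr.ind = TRUE)
  if (nrow(hi)) {
    flagged <- unique(c(rownames(C)[hi[, 1]], colnames(C)[hi[, 2]]))
    excluded <- rbind(excluded,
                      data.frame(parameter = flagged,
                                 reason = "correlated"))
  }
  structure(list(table = tab, s2 = ac$s2, N = fit$n_obs, q = fit$n_free,
                 correlation = ac$correlation, kappa = ac$kappa,
                 excluded = excluded, corr_threshold = corr_threshold),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, digits = 4, ...) {
  cat(sprintf("Identifiability report: N = %d, q = %d, s2 = %.6g\n",
              x$N, x$q, x$s2))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  if (nrow(x$excluded)) {
    cat("flagged parameters:\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}
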