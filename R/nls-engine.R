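# Damped Gauss-Newton (Levenberg-Marquardt) least-squares driver used by
# every fitting routine in the package.
#
# Contract: unweighted squared residuals, box constraints enforced by
# projection (with bound hits reported, never silently clipped into the
# result), multi-start support, and symmetric standard errors from the
# inverse Gauss-Newton curvature at the optimum scaled by ssr / dof.

# forward-difference Jacobian of a residual function
.num_jacobian <- function(fn, theta, r0 = NULL, eps = 1e-7) {
  if (is.null(r0)) r0 <- fn(theta)
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * max(abs(theta[j]), 1)
    tp <- theta; tp[j] <- tp[j] + h
    J[, j] <- (fn(tp) - r0) / h
  }
  J
}

# Levenberg-Marquardt minimisation of sum(fn(theta)^2) subject to
# lower <= theta <= upper. Returns theta, ssr, convergence flag and the
# Jacobian at the optimum.
.lm_minimize <- function(fn, theta, lower = -Inf, upper = Inf,
                         max_iter = 200, ftol = 1e-14, gtol = 1e-10) {
  p <- length(theta)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  theta <- pmin(pmax(theta, lower), upper)
  r <- fn(theta)
  ssr <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- .num_jacobian(fn, theta, r)
    g <- drop(crossprod(J, r))
    if (max(abs(g)) < gtol * max(ssr, 1e-30)) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    d <- pmax(diag(JtJ), 1e-12)
    improved <- FALSE
    for (try in 1:30) {
      H <- JtJ + lambda * diag(d, p)
      delta <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        theta_new <- pmin(pmax(theta + delta, lower), upper)
        r_new <- fn(theta_new)
        ssr_new <- sum(r_new^2)
        if (is.finite(ssr_new) && ssr_new < ssr) {
          rel <- (ssr - ssr_new) / max(ssr, 1e-300)
          theta <- theta_new; r <- r_new; ssr <- ssr_new
          lambda <- max(lambda / 5, 1e-12)
          improved <- TRUE
          if (rel < ftol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- TRUE; break }  # step size underflow: at optimum
    if (converged) break
  }
  J <- .num_jacobian(fn, theta, r)
  list(theta = theta, ssr = ssr, residuals = r, J = J,
       converged = converged, iterations = it,
       at_lower = is.finite(lower) &
         theta <= lower + 1e-10 * pmax(abs(lower), 1),
       at_upper = is.finite(upper) &
         theta >= upper - 1e-10 * pmax(abs(upper), 1))
}

# Run .lm_minimize from several starting points, keep the best.
.lm_multistart <- function(fn, starts, lower = -Inf, upper = Inf, ...) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(.lm_minimize(fn, s, lower, upper, ...),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$ssr < best$ssr)) best <- fit
  }
  if (is.null(best)) stop("convergence error: all starting points failed")
  best
}

# Build a fit_result from an .lm_minimize output.
.make_fit_result <- function(fit, par_names, n_points, model,
                             derived = list(), flags = character()) {
  p <- length(fit$theta)
  dof <- n_points - p
  if (dof <= 0) stop("degrees of freedom must be positive")
  se <- rep(NA_real_, p)
  JtJ <- crossprod(fit$J)
  cov <- tryCatch(solve(JtJ) * fit$ssr / dof, error = function(e) NULL)
  if (!is.null(cov)) {
    se <- sqrt(pmax(diag(cov), 0))
  } else {
    flags <- c(flags, "singular_curvature")
  }
  if (any(fit$at_lower | fit$at_upper)) {
    hit <- par_names[fit$at_lower | fit$at_upper]
    flags <- c(flags, paste0("bound_hit:", hit))
  }
  params <- data.frame(best_fit = fit$theta, se = se,
                       row.names = par_names)
  structure(list(model = model, params = params, dof = dof,
                 ssr = fit$ssr, n_points = n_points,
                 derived = derived, converged = fit$converged,
                 flags = flags, cov = cov),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s  ssr=%.6g  dof=%d  converged=%s\n",
              x$model, x$ssr, x$dof, x$converged))
  print(round(x$params, 6))
  if (length(x$derived)) {
    cat("derived:\n")
    for (nm in names(x$derived)) {
      d <- x$derived[[nm]]
      if (is.list(d) || length(d) > 1)
        cat(sprintf("  %s = %.6g (se %.3g)\n", nm, d[[1]], d[[2]]))
      else cat(sprintf("  %s = %.6g\n", nm, d))
    }
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficients of a fit result
#' @param object A `fit_result`.
#' @param ... Unused.
#' @return Named numeric vector of best-fit values.
#' @export
coef.fit_result <- function(object, ...) {
  stats::setNames(object$params$best_fit, rownames(object$params))
}

#' Extra-sum-of-squares F test between nested least-squares fits
#'
#' Compares a restricted model (fewer free parameters) with a full model
#' fitted to the same data: `F = ((ssr_r - ssr_f) / (df_r - df_f)) /
#' (ssr_f / df_f)`, with the p-value from the upper tail of the F
#' distribution. Invariant under uniform rescaling of the intensities.
#'
#' @param fit_restricted,fit_full `fit_result` objects (or lists with
#'   `ssr` and `dof`), restricted nested within full.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @examples
#' nested_f_test(list(ssr = 10, dof = 10), list(ssr = 8, dof = 9))
#' @export
nested_f_test <- function(fit_restricted, fit_full) {
  ssr_r <- fit_restricted$ssr; df_r <- fit_restricted$dof
  ssr_f <- fit_full$ssr; df_f <- fit_full$dof
  if (df_r <= df_f)
    stop("invalid comparison: restricted model must have more dof than full")
  if (ssr_r < ssr_f - 1e-9 * max(ssr_f, 1))
    stop("invalid comparison: restricted ssr below full ssr; not nested?")
  df1 <- df_r - df_f; df2 <- df_f
  Fstat <- max(0, (ssr_r - ssr_f) / df1) / (ssr_f / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the p-values ascending, adjusts the i-th smallest as
#' `1 - (1 - p_(i))^(m - i + 1)`, enforces monotonicity by running
#' maximum, and flags rejections at `alpha` by step-down stopping.
#'
#' @param p_values Raw p-values in [0, 1].
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data.frame with `p`, `p_adjusted`, `reject`, in input order.
#' @examples
#' holm_sidak(c(0.01, 0.04))
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values)))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  padj_sorted <- 1 - (1 - p_values[ord])^(m - seq_len(m) + 1)
  padj_sorted <- cummax(padj_sorted)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (padj_sorted[i] <= alpha) reject_sorted[i] <- TRUE else break
  }
  out <- data.frame(p = p_values, p_adjusted = NA_real_, reject = NA)
  out$p_adjusted[ord] <- padj_sorted
  out$reject[ord] <- reject_sorted
  out
}
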