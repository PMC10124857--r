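#' Predicted tissue delta value under first-order isotopic turnover
#'
#' The asymptotic turnover model: tissue starts at the day-0 value `delta0`
#' and approaches the diet-plus-discrimination equilibrium
#' `delta_e = delta_prey + disc` at first-order rate `tau` (day^-1):
#'
#'   `delta_t = delta_e + (delta0 - delta_e) * exp(-tau * t)`
#'
#' At t = 0 this is exactly `delta0`; as t grows it converges monotonically to
#' `delta_e`; at t = ln(2)/tau it sits midway between the two.
#'
#' @param t Time in days, >= 0 (vectorized).
#' @param delta0 Day-0 tissue value, per-mil.
#' @param delta_prey Diet (prey) value, per-mil (vectorized with `t`).
#' @param disc Discrimination factor, per-mil.
#' @param tau Turnover rate constant, day^-1, > 0.
#' @return Predicted tissue delta value(s), per-mil.
#' @export
#' @examples
#' predict_delta(0, -24.9, -15.28, -0.41, 0.0229)    # = delta0
#' predict_delta(log(2) / 0.0229, -24.9, -15.28, -0.41, 0.0229)  # midpoint
predict_delta <- function(t, delta0, delta_prey, disc, tau) {
  if (any(!is.finite(t)) || any(t < 0)) abort("`t` must be finite and >= 0")
  if (tau <= 0) abort("`tau` must be > 0")
  delta_e <- delta_prey + disc
  delta_e + (delta0 - delta_e) * exp(-tau * t)
}

#' Isotopic half-life from a turnover rate
#'
#' Days until 50% of tissue isotopic turnover: `ln(2) / tau`.
#'
#' @param tau First-order turnover rate constant(s), day^-1, > 0.
#' @return Half-life in days.
#' @export
#' @examples
#' half_life(0.0229)  # ~30 days
#' half_life(0.0192)  # ~36 days
half_life <- function(tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) abort("`tau` must be > 0")
  log(2) / tau
}

# residuals and analytic Jacobian of the turnover model at (disc, tau)
turnover_resid_jac <- function(theta, day, value, delta_prey, delta0) {
  disc <- theta[1]
  tau <- theta[2]
  delta_e <- delta_prey + disc
  decay <- exp(-tau * day)
  pred <- delta_e + (delta0 - delta_e) * decay
  r <- value - pred
  # d pred / d disc = 1 - exp(-tau t); d pred / d tau = -t (delta0 - delta_e) exp(-tau t)
  J <- cbind(1 - decay, -day * (delta0 - delta_e) * decay)
  list(r = r, J = J, rss = sum(r^2), pred = pred)
}

# Levenberg-Marquardt from one start; returns list(theta, rss, iter, converged)
lm_turnover_once <- function(start, day, value, delta_prey, delta0,
                             tau_bounds = c(1e-6, 10), max_iter = 200,
                             tol = 1e-10) {
  theta <- start
  cur <- turnover_resid_jac(theta, day, value, delta_prey, delta0)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    JtJ <- crossprod(cur$J)
    g <- crossprod(cur$J, cur$r)
    step_ok <- FALSE
    for (k in 1:30) {
      A <- JtJ + lambda * diag(diag(JtJ) + 1e-12, 2)
      delta_step <- tryCatch(drop(solve(A, g)), error = function(e) NULL)
      if (is.null(delta_step)) {
        lambda <- lambda * 10
        next
      }
      cand <- theta + delta_step
      cand[2] <- min(max(cand[2], tau_bounds[1]), tau_bounds[2])
      new <- turnover_resid_jac(cand, day, value, delta_prey, delta0)
      if (is.finite(new$rss) && new$rss <= cur$rss) {
        # accepted damped Gauss-Newton step: objective never increases
        rel <- (cur$rss - new$rss) / max(cur$rss, 1e-300)
        theta <- cand
        cur <- new
        lambda <- max(lambda / 10, 1e-12)
        step_ok <- TRUE
        if (rel < tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok || converged) break
  }
  if (!step_ok && !converged && iter < max_iter) converged <- TRUE # stalled at optimum
  list(theta = theta, rss = cur$rss, iter = iter, converged = converged || iter < max_iter)
}

#' Joint fit of discrimination factor and turnover rate across diet groups
#'
#' Fits the two-parameter turnover model to per-fish observations pooled
#' across diet groups, with one shared discrimination factor `disc` and one
#' shared rate `tau` (the diet groups differ only in their fixed prey values).
#' The day-0 tissue value `delta0` and per-group prey values are treated as
#' measured constants; each fish-day observation contributes one independent
#' squared residual. Minimization is Levenberg-Marquardt-damped Gauss-Newton
#' with the analytic Jacobian, multi-started over `tau` to guard against
#' local minima.
#'
#' Standard errors come from the Jacobian at the optimum:
#' `sqrt(diag(s^2 (J'J)^-1))` with `s^2 = RSS / (n - 2)`; the reported RMSE is
#' `sqrt(RSS / (n - 2))`.
#'
#' @param observations A data frame with columns `day` (>= 0), `value`
#'   (per-mil tissue delta, lipid rules already applied for carbon) and
#'   `delta_prey` (the observation's diet-group prey value, per-mil,
#'   lipid-normalized for carbon). An optional `diet_group` column is carried
#'   into the residual table.
#' @param delta0 Shared day-0 tissue mean, per-mil.
#' @param isotope Label stored on the fit (`"C13"` or `"N15"`).
#' @param init Optional starting values `c(disc, tau)`; the default starts
#'   disc at 0.4 (carbon) or 3.4 (nitrogen) and multi-starts tau over
#'   `tau_starts`.
#' @param tau_starts Rate starting points for the multistart (day^-1).
#' @param max_iter,tol Iteration budget and relative-RSS convergence
#'   tolerance.
#' @return An object of class `turnover_fit`: estimates, SEs, RMSE, n,
#'   half-life, residual table and convergence diagnostics. Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   day = rep(c(0, 14, 31, 42, 55, 63), 2),
#'   delta_prey = rep(c(-15.28, -21.47), each = 6)
#' )
#' obs$value <- predict_delta(obs$day, -24.9, obs$delta_prey, -0.41, 0.0229)
#' fit <- fit_turnover(obs, delta0 = -24.9, isotope = "C13")
#' tidy(fit)
fit_turnover <- function(observations, delta0, isotope = c("C13", "N15"),
                         init = NULL,
                         tau_starts = exp(seq(log(0.002), log(0.1), length.out = 10)),
                         max_iter = 200, tol = 1e-10) {
  isotope <- match.arg(isotope)
  need <- c("day", "value", "delta_prey")
  miss <- setdiff(need, names(observations))
  if (length(miss) > 0) {
    abort(paste0("`observations` missing column(s): ", paste(miss, collapse = ", ")))
  }
  obs <- tibble::as_tibble(observations)
  obs <- obs[stats::complete.cases(obs[need]), ]
  n <- nrow(obs)
  if (n < 3) abort("insufficient data: need at least 3 observations to fit (disc, tau)")
  if (length(unique(obs$day)) < 2) {
    abort("insufficient data: need observations on at least 2 distinct days")
  }
  if (any(obs$day < 0)) abort("`day` must be >= 0")

  day <- obs$day
  value <- obs$value
  delta_prey <- obs$delta_prey

  disc_init <- if (!is.null(init)) init[1] else if (isotope == "C13") 0.4 else 3.4
  starts <- lapply(if (!is.null(init)) init[2] else tau_starts,
                   function(tau0) c(disc_init, tau0))

  fits <- lapply(starts, lm_turnover_once,
                 day = day, value = value, delta_prey = delta_prey,
                 delta0 = delta0, max_iter = max_iter, tol = tol)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  theta <- best$theta
  at_boundary <- theta[2] <= 1e-6 * (1 + 1e-9) || theta[2] >= 10 * (1 - 1e-9)
  if (at_boundary) {
    warn("turnover rate estimate at its boundary; tau may be unidentifiable from these data")
  }

  final <- turnover_resid_jac(theta, day, value, delta_prey, delta0)
  JtJ <- crossprod(final$J)
  s2 <- final$rss / (n - 2)
  kappa <- tryCatch(kappa(JtJ, exact = TRUE), error = function(e) Inf)
  vcov <- tryCatch(s2 * solve(JtJ), error = function(e) matrix(NA_real_, 2, 2))
  if (!at_boundary && (!is.finite(kappa) || kappa > 1e10)) {
    warn("near-singular Jacobian: (disc, tau) weakly identified (no informative contrast between delta0 and equilibrium?)")
  }
  se <- sqrt(pmax(diag(vcov), 0))

  structure(
    list(
      isotope = isotope,
      disc = theta[1], tau = theta[2],
      se_disc = se[1], se_tau = se[2],
      vcov = vcov,
      rmse = sqrt(s2), rss = final$rss, n_obs = n,
      half_life_days = log(2) / theta[2],
      delta0 = delta0,
      residuals = dplyr::mutate(obs, fitted = final$pred, resid = final$r),
      convergence = list(converged = best$converged, iterations = best$iter,
                         at_boundary = at_boundary, condition_number = kappa)
    ),
    class = "turnover_fit"
  )
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat(sprintf("Turnover fit (%s): disc = %.3f (SE %.3f) per-mil, tau = %.4f (SE %.4f) /day\n",
              x$isotope, x$disc, x$se_disc, x$tau, x$se_tau))
  cat(sprintf("  n = %d, RMSE = %.3f per-mil, half-life = %.1f days\n",
              x$n_obs, x$rmse, x$half_life_days))
  invisible(x)
}

#' @rdname fit_turnover
#' @param x A `turnover_fit`.
#' @param ... Unused.
#' @export
tidy.turnover_fit <- function(x, ...) {
  tibble::tibble(
    term = c("disc", "tau"),
    estimate = c(x$disc, x$tau),
    std.error = c(x$se_disc, x$se_tau)
  )
}

#' @rdname fit_turnover
#' @export
glance.turnover_fit <- function(x, ...) {
  tibble::tibble(
    isotope = x$isotope,
    disc = x$disc, se_disc = x$se_disc,
    tau = x$tau, se_tau = x$se_tau,
    rmse = x$rmse, n_obs = x$n_obs,
    half_life_days = x$half_life_days,
    converged = x$convergence$converged
  )
}

#' Fit both isotopes through the full trial chain
#'
#' Runs the complete feeding-trial chain: applies the lipid-normalization
#' rules, takes the shared day-0 tissue mean per isotope from the day-0 fish,
#' takes per-diet-group prey means (lipid-normalized for carbon) from the
#' prey samples or from a supplied summary, then fits the joint
#' (disc, tau) model separately for d13C and d15N.
#'
#' @param trial A sample table (see [read_samples()]) holding `trial_fish`
#'   rows — including day-0 baseline fish — and, unless `prey_means` is
#'   given, `prey` rows per diet group.
#' @param prey_means Optional per-group prey summary: a data frame with
#'   columns `diet_group`, `d13c_prey` (lipid-normalized) and `d15n_prey`.
#'   Overrides prey rows in `trial`.
#' @param include_day0 Should the day-0 fish also enter the fit as t = 0
#'   observations (`TRUE`), or only set `delta0` (`FALSE`, default)?
#' @param threshold Fish C:N lipid-rule threshold, see
#'   [apply_fish_lipid_rule()].
#' @param ... Passed to [fit_turnover()].
#' @return A named list with elements `C13` and `N15`, each a `turnover_fit`.
#' @export
fit_both_isotopes <- function(trial, prey_means = NULL, include_day0 = FALSE,
                              threshold = 3.5, ...) {
  trial <- validate_samples(trial)
  trial <- apply_fish_lipid_rule(trial, threshold = threshold)

  fish <- dplyr::filter(trial, .data$role == "trial_fish")
  baseline <- dplyr::filter(fish, .data$day == 0)
  if (nrow(baseline) == 0) {
    abort("insufficient data: no day-0 baseline fish to set delta0")
  }
  if (!any(fish$day > 0)) {
    abort("insufficient data: no post-baseline sampling days")
  }

  if (is.null(prey_means)) {
    prey <- dplyr::filter(trial, .data$role == "prey")
    if (nrow(prey) == 0) abort("no prey samples and no `prey_means` supplied")
    prey_means <- prey |>
      dplyr::group_by(.data$diet_group) |>
      dplyr::summarise(
        d13c_prey = mean(.data$d13c_norm),
        d15n_prey = mean(.data$d15n),
        .groups = "drop"
      )
  }

  fit_obs <- if (include_day0) fish else dplyr::filter(fish, .data$day > 0)
  fit_obs <- dplyr::inner_join(fit_obs, prey_means, by = "diet_group")
  if (nrow(fit_obs) < nrow(if (include_day0) fish else dplyr::filter(fish, .data$day > 0))) {
    warn("some trial fish had no matching prey mean and were dropped")
  }

  delta0_c <- mean(baseline$d13c_norm)
  delta0_n <- mean(baseline$d15n)

  obs_c <- dplyr::transmute(fit_obs, .data$diet_group, .data$day,
                            value = .data$d13c_norm, delta_prey = .data$d13c_prey)
  obs_n <- dplyr::transmute(fit_obs, .data$diet_group, .data$day,
                            value = .data$d15n, delta_prey = .data$d15n_prey)

  list(
    C13 = fit_turnover(obs_c, delta0 = delta0_c, isotope = "C13", ...),
    N15 = fit_turnover(obs_n, delta0 = delta0_n, isotope = "N15", ...)
  )
}

#' Plot a turnover fit: per-group trajectories and observations
#'
#' @param object A `turnover_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed per-fish values by day, faceted by diet
#'   group, with the fitted approach-to-equilibrium curve overlaid.
#' @export
autoplot.turnover_fit <- function(object, ...) {
  res <- object$residuals
  if (!"diet_group" %in% names(res)) res$diet_group <- "all"
  grid <- res |>
    dplyr::distinct(.data$diet_group, .data$delta_prey) |>
    tidyr::crossing(day = seq(0, max(res$day), length.out = 100)) |>
    dplyr::mutate(value = predict_delta(.data$day, object$delta0, .data$delta_prey,
                                        object$disc, object$tau))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$diet_group)) +
    ggplot2::labs(
      x = "Day of trial",
      y = sprintf("%s (per-mil)", ifelse(object$isotope == "C13", "d13C", "d15N")),
      title = sprintf("Turnover fit: disc = %.2f, tau = %.4f/day (half-life %.0f d)",
                      object$disc, object$tau, object$half_life_days)
    )
}
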