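## Fitting the three-parameter hydration-shell model to cloud-point /
## aggregation observations.
##
## The model chemical potential is linear in (dH0, dS0, cp_shell):
##   mu_hyd(T) = dH0 * 1 + dS0 * (-T_K) + cp * [(T_K - T0) - T_K ln(T_K/T0)]
## so the fit is (weighted) linear least squares and is exactly reproducible.
## When the dominant error source is the measured cloud-point temperature
## rather than the chemical potential, the induced residual variance is
## heteroscedastic (proportional to the squared local temperature-derivative
## of the shell-minus-solution potential); `t_noise_sd > 0` switches on
## iterative effective-variance weighting to account for this.

#' Cloud-point observations
#'
#' Builds the observation table for [hydration_fit()]: each row is a
#' cloud/aggregation point with its temperature and the water activity of
#' the bulk phase in which it was observed.
#'
#' @param temperature cloud-point temperatures in deg C.
#' @param water_activity water activities in `(0, 1]`, same length.
#' @param salt optional salt labels.
#' @param weight optional nonnegative fit weights (default 1).
#' @return a data frame of class `"cloud_points"`.
#' @export
cloud_points <- function(temperature, water_activity, salt = "",
                         weight = 1) {
  .stopifnot_num(temperature, "temperature")
  .stopifnot_num(water_activity, "water_activity")
  if (length(water_activity) != length(temperature))
    stop("'temperature' and 'water_activity' lengths differ")
  if (any(water_activity <= 0 | water_activity > 1))
    stop("'water_activity' must lie in (0, 1]")
  if (any(weight < 0)) stop("'weight' must be >= 0")
  out <- data.frame(temperature = temperature,
                    water_activity = water_activity,
                    salt = salt, weight = weight)
  class(out) <- c("cloud_points", "data.frame")
  out
}

## model basis at temperatures T_C (deg C)
.hyd_basis <- function(T_C, T0) {
  T_K <- T_C + .const$T_zero_C
  cbind(h0 = rep(1, length(T_K)), s0 = -T_K,
        cp = (T_K - T0) - T_K * log(T_K / T0))
}

#' Fit the hydration-shell model to cloud-point data
#'
#' Estimates the shell parameters `(dH0, dS0, cp_shell)` by least squares on
#' the chemical-potential scale: the shell potential `mu_hyd(T_i)` is matched
#' to the solution potential `mu_w(T_i) + R T_K ln(a_i)` at each observed
#' cloud point. The model is linear in its parameters, so the solution is
#' deterministic. With `fit_cp = FALSE` the heat capacity is held at its
#' initial value and only the two offsets are estimated.
#'
#' @param data a [cloud_points()] data frame (or any data frame with columns
#'   `temperature`, `water_activity` and optionally `weight`). At least 4
#'   points spanning at least 15 deg C are required.
#' @param init optional [hydration_params()] giving the fixed `cp_shell`
#'   when `fit_cp = FALSE` (and `T0` / `cp_water_ref` overrides otherwise).
#' @param fit_cp estimate `cp_shell` (default `TRUE`).
#' @param t_noise_sd assumed standard deviation of the cloud-point
#'   temperatures in deg C. When positive, effective-variance weights
#'   `1 / (t_noise_sd * d(mu_hyd - mu_sol)/dT)^2` are iterated (4 passes);
#'   when 0 (default), plain (user-)weighted least squares is used.
#' @param water_curve water-curve [quadratic_mu()] used for the solution
#'   potential.
#' @return an object of class `"hydration_fit"` with components `params`
#'   (a [hydration_params()]), `coefficients`, `se`, `residuals`, `fitted`,
#'   `data`, `sigma` and `df.residual`.
#' @examples
#' pts <- gen_cloud_points(seed = 1)
#' fit <- hydration_fit(pts, t_noise_sd = 0.3)
#' coef(fit)
#' @export
hydration_fit <- function(data, init = NULL, fit_cp = TRUE, t_noise_sd = 0,
                          water_curve = mu_water_curve()) {
  stopifnot(is.data.frame(data),
            all(c("temperature", "water_activity") %in% names(data)))
  T_C <- data$temperature; a <- data$water_activity
  n <- length(T_C)
  if (n < 4) stop("at least 4 cloud points are required")
  if (diff(range(T_C)) < 15)
    stop("cloud points must span at least 15 degC (degenerate span)")
  w_user <- if (is.null(data$weight)) rep(1, n) else data$weight
  T0 <- if (is.null(init)) .const$T_zero_C else init$T0
  cp_ref <- if (is.null(init)) .const$cp_water else init$cp_water_ref
  y <- mu_solution(T_C, a, curve = water_curve)
  X <- .hyd_basis(T_C, T0)

  solve_wls <- function(w) {
    if (fit_cp) {
      sw <- sqrt(w)
      fit <- stats::lsfit(X * sw, y * sw, intercept = FALSE)
      theta <- stats::setNames(unname(fit$coefficients), c("dH0", "dS0", "cp_shell"))
    } else {
      if (is.null(init)) stop("'init' must supply cp_shell when fit_cp = FALSE")
      cp <- init$cp_shell
      y2 <- y - cp * X[, "cp"]
      sw <- sqrt(w)
      fit <- stats::lsfit(X[, 1:2, drop = FALSE] * sw, y2 * sw, intercept = FALSE)
      theta <- c(dH0 = unname(fit$coefficients[1]),
                 dS0 = unname(fit$coefficients[2]), cp_shell = cp)
    }
    if (theta[["cp_shell"]] <= 0)
      stop("fit did not converge to a physical shell heat capacity (cp <= 0)")
    theta
  }

  theta <- solve_wls(w_user)
  w <- w_user
  if (t_noise_sd > 0) {
    for (k in 1:4) {
      p <- hydration_params(theta[["dH0"]], theta[["dS0"]], theta[["cp_shell"]],
                            T0 = T0, cp_water_ref = cp_ref)
      eps <- 0.01
      slope <- ((mu_hydration(T_C + eps, p) -
                   mu_solution(T_C + eps, a, curve = water_curve)) -
                (mu_hydration(T_C - eps, p) -
                   mu_solution(T_C - eps, a, curve = water_curve))) / (2 * eps)
      w <- w_user / pmax(t_noise_sd * abs(slope), 1e-6)^2
      theta <- solve_wls(w)
    }
  }

  params <- hydration_params(theta[["dH0"]], theta[["dS0"]], theta[["cp_shell"]],
                             T0 = T0, cp_water_ref = cp_ref)
  fitted <- mu_hydration(T_C, params)
  res <- y - fitted
  p_free <- if (fit_cp) 3L else 2L
  dof <- n - p_free
  sigma <- sqrt(sum(w * res^2) / dof)
  XtWX <- crossprod(X[, seq_len(if (fit_cp) 3 else 2), drop = FALSE] * sqrt(w))
  se3 <- rep(NA_real_, 3)
  se3[seq_len(if (fit_cp) 3 else 2)] <-
    sigma * sqrt(diag(solve(XtWX)))
  names(se3) <- c("dH0", "dS0", "cp_shell")

  structure(list(params = params, coefficients = theta, se = se3,
                 residuals = res, fitted = fitted, weights = w,
                 data = data, sigma = sigma, df.residual = dof,
                 t_noise_sd = t_noise_sd, water_curve = water_curve,
                 call = match.call()),
            class = "hydration_fit")
}

#' @export
coef.hydration_fit <- function(object, ...) object$coefficients

#' @export
residuals.hydration_fit <- function(object, ...) object$residuals

#' @export
fitted.hydration_fit <- function(object, ...) object$fitted

#' @export
print.hydration_fit <- function(x, ...) {
  cat("Hydration-shell model fit (", length(x$residuals), " cloud points)\n",
      sep = "")
  print(x$params)
  Tg <- tryCatch(gelation_temperature_heating(x$params), error = function(e) NULL)
  if (!is.null(Tg))
    cat(sprintf("  predicted heating gelation (dG = 0): %.1f degC\n", Tg))
  invisible(x)
}

#' @export
summary.hydration_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  Tg <- tryCatch(gelation_temperature_heating(object$params),
                 error = function(e) NULL)
  Tf <- tryCatch(gelation_temperature_freezing(object$params),
                 error = function(e) NULL)
  pen <- if (is.null(Tg)) NULL else enthalpy_penalty_at_gelation(object$params)
  out <- list(coefficients = tab, sigma = object$sigma,
              df.residual = object$df.residual,
              dCp = shell_cp_deficit(object$params),
              gelation_heating = Tg, gelation_freezing = Tf,
              enthalpy_penalty = pen,
              residual_range = range(object$residuals))
  class(out) <- "summary.hydration_fit"
  out
}

#' @export
print.summary.hydration_fit <- function(x, ...) {
  cat("Hydration-shell model fit\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nResidual standard error %.3g on %d degrees of freedom\n",
              x$sigma, x$df.residual))
  cat(sprintf("dCp (water - shell): %.3g J/mol/K\n", x$dCp))
  if (!is.null(x$gelation_heating))
    cat(sprintf("Heating gelation (dG = 0): %.2f degC; enthalpy penalty %.3f kJ/mol\n",
                x$gelation_heating, x$enthalpy_penalty))
  if (!is.null(x$gelation_freezing))
    cat(sprintf("Freezing gelation (shell = ice): %.2f degC\n",
                x$gelation_freezing))
  invisible(x)
}

#' Predict from a hydration-shell fit
#'
#' @param object a [hydration_fit()].
#' @param newdata temperatures in deg C (vector, or data frame with a
#'   `temperature` column). Defaults to the fitted temperatures.
#' @param type `"mu"` for the shell chemical potential (J/mol) or
#'   `"delta"` for the [delta_thermo()] table relative to bulk water.
#' @param ... unused.
#' @return numeric vector or data frame according to `type`.
#' @export
predict.hydration_fit <- function(object, newdata = NULL,
                                  type = c("mu", "delta"), ...) {
  type <- match.arg(type)
  T_C <- if (is.null(newdata)) object$data$temperature
         else if (is.data.frame(newdata)) newdata$temperature else newdata
  if (type == "mu") mu_hydration(T_C, object$params)
  else delta_thermo(T_C, object$params)
}

#' Simulate cloud points from a fitted hydration-shell model
#'
#' Delegates to [gen_cloud_points()] with the fitted parameters, producing
#' replicate synthetic data sets under the fitted shell state.
#'
#' @param object a [hydration_fit()].
#' @param nsim number of data sets (default 1).
#' @param seed optional RNG seed.
#' @param ... passed to [gen_cloud_points()] (e.g. `molality`,
#'   `temp_noise_sd`).
#' @return a [cloud_points()] data frame, or a list of them when `nsim > 1`.
#' @export
simulate.hydration_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- lapply(seq_len(nsim), function(i)
    gen_cloud_points(params = object$params,
                     seed = if (is.null(seed)) NULL else seed + i - 1, ...))
  if (nsim == 1) sims[[1]] else sims
}

#' Plot a hydration-shell fit
#'
#' Chemical potential against temperature: observed cloud points, the fitted
#' shell curve, and the bulk water and ice curves.
#'
#' @param x a [hydration_fit()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.hydration_fit <- function(x, ...) {
  T_C <- x$data$temperature
  y <- x$fitted + x$residuals
  grid <- seq(min(-10, floor(min(T_C))), max(80, ceiling(max(T_C))),
              length.out = 200)
  mu_h <- mu_hydration(grid, x$params)
  mu_w <- suppressWarnings(mu_water(grid))
  mu_i <- suppressWarnings(mu_ice(grid))
  rng <- range(c(y, mu_h, mu_w, mu_i))
  graphics::plot(grid, mu_h, type = "l", col = "blue", lwd = 2, ylim = rng,
                 xlab = "Temperature (degC)",
                 ylab = expression(mu ~ (J ~ mol^-1)), ...)
  graphics::lines(grid, mu_w, lty = 2, col = "steelblue")
  graphics::lines(grid, mu_i, lty = 2, col = "grey40")
  graphics::points(T_C, y, pch = 15, col = "darkgreen")
  graphics::legend("bottomleft",
                   legend = c("hydration shell (fit)", "water", "ice",
                              "cloud points"),
                   col = c("blue", "steelblue", "grey40", "darkgreen"),
                   lty = c(1, 2, 2, NA), pch = c(NA, NA, NA, 15), bty = "n")
  invisible(x)
}
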