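# Constructor for the common fitted-object shell shared by all the
# temperature-response fitters.
.temp_fit <- function(model, coef, se, rss, data, extra = list()) {
  structure(
    c(list(model = model, coef = coef, se = se, rss = rss, data = data),
      extra),
    class = "temp_fit"
  )
}

# Asymptotic standard errors for a converged nls.lm fit from the
# Gauss-Newton approximation at the optimum; NA when the information
# matrix is not invertible (e.g. a perfectly flat series).
.nlslm_se <- function(fit) {
  n <- length(fit$fvec)
  p <- length(fit$par)
  sigma2 <- sum(fit$fvec^2) / max(n - p, 1)
  v <- tryCatch(sigma2 * solve(fit$hessian),
                error = function(e) matrix(NA_real_, p, p))
  stats::setNames(sqrt(pmax(diag(v), 0)), names(fit$par))
}

.check_series <- function(data, min_temps) {
  data <- tibble::as_tibble(data)
  if (!all(c("Tleaf", "value") %in% names(data))) {
    stop("series must have Tleaf and value columns", call. = FALSE)
  }
  if (length(unique(data$Tleaf)) < min_temps) {
    stop("need at least ", min_temps, " distinct temperatures",
         call. = FALSE)
  }
  data
}

#' Fit the Arrhenius temperature response
#'
#' Nonlinear least squares of
#' \eqn{k(T) = k_{25}\exp[E_a(T_k-298)/(R\,298\,T_k)]} to a series of
#' (Tleaf, value) pairs; recovers the generating constants exactly on
#' noiseless input. Replicate values at a temperature are fitted as
#' individual points.
#'
#' @param data A data frame with columns `Tleaf` (degC) and `value`.
#' @return A `temp_fit` object with `k25` and `Ea` (kJ mol^-1).
#' @examples
#' d <- data.frame(Tleaf = c(15, 20, 25, 30, 35))
#' d$value <- arrhenius_scale(1.25, 30.9, d$Tleaf)
#' fit_arrhenius(d)
#' @export
fit_arrhenius <- function(data) {
  data <- .check_series(data, 4)
  if (any(data$value <= 0)) stop("values must be positive", call. = FALSE)
  # log-linear regression provides the starting values (exact when the
  # data are noiseless in log space)
  Tk <- data$Tleaf + .K0
  x <- (Tk - 298) / (.R_GAS * 298 * Tk)
  lin <- stats::lm(log(value) ~ x, data = data.frame(value = data$value, x))
  start <- list(k25 = exp(stats::coef(lin)[[1]]),
                Ea = stats::coef(lin)[[2]] / 1000)
  fit <- minpack.lm::nls.lm(
    par = c(k25 = start$k25, Ea = start$Ea),
    fn = function(p) {
      data$value - p[["k25"]] *
        exp(p[["Ea"]] * 1000 * (Tk - 298) / (8.314 * 298 * Tk))
    },
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12))
  cf <- stats::coef(fit)
  se <- .nlslm_se(fit)
  .temp_fit("arrhenius", cf, se, sum(fit$fvec^2), data)
}

#' Fit the Q10 respiration model
#'
#' Least squares in log space of \eqn{R_d = R_{d25} Q_{10}^{(T-25)/10}}:
#' \eqn{\log R_d} is linear in \eqn{(T-25)/10} with slope \eqn{\log Q_{10}},
#' so the fit is an exact linear regression.
#'
#' @param data A data frame with columns `Tleaf` (degC) and `value`
#'   (respiration, umol m^-2 s^-1; strictly positive).
#' @return A `temp_fit` object with `Rd25` and `Q10`.
#' @examples
#' d <- data.frame(Tleaf = c(15, 20, 25, 30, 35))
#' d$value <- q10_respiration(1.25, 1.51, d$Tleaf)
#' fit_q10(d)
#' @export
fit_q10 <- function(data) {
  data <- .check_series(data, 2)
  if (any(data$value <= 0)) {
    stop("respiration values must be positive for the log-space fit",
         call. = FALSE)
  }
  x <- (data$Tleaf - 25) / 10
  lin <- stats::lm(log(data$value) ~ x)
  cf <- c(Rd25 = exp(stats::coef(lin)[[1]]),
          Q10 = exp(stats::coef(lin)[[2]]))
  se_log <- suppressWarnings(summary(lin))$coefficients[, "Std. Error"]
  # delta method back to the natural scale
  se <- c(Rd25 = cf[["Rd25"]] * se_log[[1]], Q10 = cf[["Q10"]] * se_log[[2]])
  pred <- cf[["Rd25"]] * cf[["Q10"]]^x
  .temp_fit("q10", cf, se, sum((data$value - pred)^2), data)
}

#' Fit the peaked Arrhenius temperature response
#'
#' Nonlinear least squares of the peaked function over
#' (`k25`, `Ea`, `deltaS`) with the deactivation energy held fixed
#' (200 kJ mol^-1 by convention, to avoid over-parametrisation). The
#' temperature optimum is then computed in closed form by [topt_peaked()]
#' and the value at the optimum by evaluation. `deltaS` is bounded to
#' [500, 800] J mol^-1 K^-1 to prevent parameter exchange with `Ea`.
#'
#' @param data A data frame with columns `Tleaf` (degC) and `value`; at
#'   least 5 distinct temperatures.
#' @param Hd Fixed deactivation energy (kJ mol^-1).
#' @return A `temp_fit` object with `k25`, `Ea`, `deltaS` plus derived
#'   `Topt` (degC) and `value_at_Topt`.
#' @examples
#' d <- data.frame(Tleaf = c(15, 20, 25, 30, 35))
#' d$value <- peaked_arrhenius_scale(187.9, 37.7, 200, 648.3, d$Tleaf)
#' fit_peaked(d)
#' @export
fit_peaked <- function(data, Hd = 200) {
  data <- .check_series(data, 5)
  Tk <- data$Tleaf + .K0
  near25 <- data$value[which.min(abs(data$Tleaf - 25))]
  fit <- minpack.lm::nls.lm(
    par = c(k25 = near25, Ea = 40, deltaS = 640),
    fn = function(p) {
      data$value - peaked_arrhenius_scale(p[["k25"]], p[["Ea"]], Hd,
                                          p[["deltaS"]], data$Tleaf)
    },
    lower = c(k25 = 1e-6, Ea = 1, deltaS = 500),
    upper = c(k25 = Inf, Ea = Hd - 1e-3, deltaS = 800),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12))
  cf <- stats::coef(fit)
  se <- .nlslm_se(fit)
  Topt <- topt_peaked(cf[["Ea"]], Hd, cf[["deltaS"]])
  if (Topt >= max(data$Tleaf) || Topt <= min(data$Tleaf)) {
    warning("fitted optimum lies at or beyond the measured temperature ",
            "range; the series may be monotone", call. = FALSE)
  }
  vopt <- peaked_arrhenius_scale(cf[["k25"]], cf[["Ea"]], Hd,
                                 cf[["deltaS"]], Topt)
  .temp_fit("peaked", cf, se, sum(fit$fvec^2), data,
            extra = list(Hd = Hd, Topt = Topt, value_at_Topt = vopt))
}

#' Fit the parabolic temperature response of Asat
#'
#' \eqn{A_{sat} = A_{opt} - b (T - T_{opt})^2}. The parabola is an exact
#' re-parametrisation of quadratic regression, so the fit is solved in
#' closed form: fit \eqn{y = A + BT + CT^2} by ordinary least squares, then
#' \eqn{T_{opt} = -B/2C}, \eqn{A_{opt} = A - B^2/4C}, \eqn{b = -C}.
#' Standard errors come from the delta method on the regression
#' variance-covariance matrix.
#'
#' @param data A data frame with columns `Tleaf` (degC) and `value`.
#' @return A `temp_fit` object with `Aopt`, `Topt`, `b_curv`.
#' @examples
#' d <- data.frame(Tleaf = c(15, 20, 25, 30, 35))
#' d$value <- parabola_asat(24.6, 23.4, 0.05, d$Tleaf)
#' fit_parabola(d)
#' @export
fit_parabola <- function(data) {
  data <- .check_series(data, 3)
  quad <- fit_quadratic(data)
  A <- quad$coef[["A"]]; B <- quad$coef[["B"]]; C <- quad$coef[["C"]]
  if (C >= 0) {
    warning("fitted parabola opens upward (no interior maximum)",
            call. = FALSE)
  }
  cf <- c(Aopt = A - B^2 / (4 * C), Topt = -B / (2 * C), b_curv = -C)
  V <- quad$vcov
  # delta method gradients of (Aopt, Topt, b) wrt (A, B, C)
  gA <- c(1, -B / (2 * C), B^2 / (4 * C^2))
  gT <- c(0, -1 / (2 * C), B / (2 * C^2))
  gb <- c(0, 0, -1)
  se <- c(Aopt = sqrt(drop(t(gA) %*% V %*% gA)),
          Topt = sqrt(drop(t(gT) %*% V %*% gT)),
          b_curv = sqrt(V[3, 3]))
  .temp_fit("parabola", cf, se, quad$rss, data,
            extra = list(Topt = cf[["Topt"]], value_at_Topt = cf[["Aopt"]]))
}

#' Fit a plain quadratic temperature response
#'
#' Ordinary polynomial least squares \eqn{y = A + BT + CT^2}; the vertex
#' \eqn{-B/2C} is reported as the temperature optimum for rates such as
#' mesophyll or stomatal conductance whose response is described
#' empirically rather than mechanistically.
#'
#' @param data A data frame with columns `Tleaf` (degC) and `value`.
#' @return A `temp_fit` object with `A`, `B`, `C` and, when `C != 0`, the
#'   `vertex` (degC); for near-linear data (`C` indistinguishable from 0)
#'   the vertex is `NA` with a warning.
#' @export
fit_quadratic <- function(data) {
  data <- .check_series(data, 3)
  lin <- stats::lm(value ~ Tleaf + I(Tleaf^2),
                   data = data.frame(value = data$value, Tleaf = data$Tleaf))
  cf <- stats::setNames(stats::coef(lin), c("A", "B", "C"))
  sm <- suppressWarnings(stats::summary.lm(lin))
  se <- stats::setNames(sm$coefficients[, "Std. Error"], c("A", "B", "C"))
  scale_ref <- max(abs(cf[["B"]] / (2 * diff(range(data$Tleaf)))), 1e-12)
  vertex <- if (abs(cf[["C"]]) < 1e-10 * max(scale_ref, 1)) {
    warning("quadratic coefficient is ~0 (linear data); vertex undefined",
            call. = FALSE)
    NA_real_
  } else {
    -cf[["B"]] / (2 * cf[["C"]])
  }
  .temp_fit("quadratic", cf, se, sum(stats::residuals(lin)^2), data,
            extra = list(vertex = vertex,
                         vcov = sm$cov.unscaled * sm$sigma^2))
}

#' @export
print.temp_fit <- function(x, ...) {
  cat(sprintf("<temp_fit: %s>  n = %d, RSS = %.4g\n",
              x$model, nrow(x$data), x$rss))
  print(round(rbind(estimate = x$coef, se = x$se), 4))
  if (!is.null(x$Topt)) cat(sprintf("  Topt %.2f degC, value at Topt %.2f\n",
                                    x$Topt, x$value_at_Topt))
  if (!is.null(x$vertex)) cat(sprintf("  vertex %.2f degC\n", x$vertex))
  invisible(x)
}

#' @method tidy temp_fit
#' @export
tidy.temp_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef),
                 estimate = unname(x$coef),
                 std.error = unname(x$se))
}

#' @method glance temp_fit
#' @export
glance.temp_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, nobs = nrow(x$data),
                 Topt = x$Topt %||% x$vertex %||% NA_real_)
}

#' @export
predict.temp_fit <- function(object, newdata = NULL, ...) {
  Tleaf <- if (is.null(newdata)) object$data$Tleaf else newdata$Tleaf
  cf <- object$coef
  switch(object$model,
    arrhenius = arrhenius_scale(cf[["k25"]], cf[["Ea"]], Tleaf),
    q10       = q10_respiration(cf[["Rd25"]], cf[["Q10"]], Tleaf),
    peaked    = peaked_arrhenius_scale(cf[["k25"]], cf[["Ea"]], object$Hd,
                                       cf[["deltaS"]], Tleaf),
    parabola  = parabola_asat(cf[["Aopt"]], cf[["Topt"]], cf[["b_curv"]],
                              Tleaf),
    quadratic = cf[["A"]] + cf[["B"]] * Tleaf + cf[["C"]] * Tleaf^2
  )
}

#' Plot a fitted temperature response
#'
#' @param object A `temp_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot temp_fit
#' @export
autoplot.temp_fit <- function(object, ...) {
  grid <- tibble::tibble(
    Tleaf = seq(min(object$data$Tleaf), max(object$data$Tleaf),
                length.out = 200))
  grid$value <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$Tleaf, y = .data$value)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Leaf temperature (degC)", y = "Rate",
                  title = paste("Temperature response:", object$model)) +
    ggplot2::theme_minimal()
}

#' Assemble a temperature-response parameter summary table
#'
#' Collects the component fits for one or more cultivars into a long
#' summary table: the Asat parabola optimum, the gm quadratic vertex and
#' 25 degC value, the Vcmax and Rd Arrhenius constants, the Jmax
#' peaked-Arrhenius constants with derived optimum, and the respiration
#' Q10. Missing component fits yield rows marked unavailable rather than
#' an error.
#'
#' @param fits A named list (one element per cultivar) of named lists with
#'   any of the components `asat` ([fit_parabola()]), `gm`
#'   ([fit_quadratic()]), `vcmax` ([fit_arrhenius()]), `jmax`
#'   ([fit_peaked()]), `rd_arrhenius` ([fit_arrhenius()]), `rd_q10`
#'   ([fit_q10()]).
#' @return A tibble with columns `cultivar`, `parameter`, `constant`,
#'   `estimate`, `se`, `available`.
#' @export
build_table1 <- function(fits) {
  row <- function(cultivar, parameter, constant, fit, pick, se_pick = pick,
                  derived = NULL) {
    if (is.null(fit)) {
      return(tibble::tibble(cultivar = cultivar, parameter = parameter,
                            constant = constant, estimate = NA_real_,
                            se = NA_real_, available = FALSE))
    }
    est <- if (identical(derived, "at25")) {
      predict(fit, data.frame(Tleaf = 25))
    } else if (!is.null(derived)) {
      fit[[derived]]
    } else {
      fit$coef[[pick]]
    }
    se <- if (!is.null(derived)) NA_real_ else fit$se[[pick]]
    tibble::tibble(cultivar = cultivar, parameter = parameter,
                   constant = constant, estimate = est, se = se,
                   available = TRUE)
  }
  purrr::imap_dfr(fits, function(f, cultivar) {
    dplyr::bind_rows(
      row(cultivar, "Asat", "Topt (degC)", f$asat, "Topt"),
      row(cultivar, "Asat", "Aopt", f$asat, "Aopt"),
      row(cultivar, "gm", "Topt (degC)", f$gm, NULL, derived = "vertex"),
      row(cultivar, "gm", "gm at 25 degC", f$gm, NULL, derived = "at25"),
      row(cultivar, "Vcmax", "Vcmax at 25 degC", f$vcmax, "k25"),
      row(cultivar, "Vcmax", "EaV (kJ mol-1)", f$vcmax, "Ea"),
      row(cultivar, "Jmax", "Jmax at 25 degC", f$jmax, "k25"),
      row(cultivar, "Jmax", "Topt (degC)", f$jmax, NULL, derived = "Topt"),
      row(cultivar, "Jmax", "Jmax at Topt", f$jmax, NULL,
          derived = "value_at_Topt"),
      row(cultivar, "Jmax", "EaJ (kJ mol-1)", f$jmax, "Ea"),
      row(cultivar, "Jmax", "dSJ (J mol-1 K-1)", f$jmax, "deltaS"),
      row(cultivar, "Jmax", "Hd (kJ mol-1)", f$jmax, NULL, derived = "Hd"),
      row(cultivar, "Rd", "Rd at 25 degC", f$rd_arrhenius, "k25"),
      row(cultivar, "Rd", "EaR (kJ mol-1)", f$rd_arrhenius, "Ea"),
      row(cultivar, "Rd", "Q10", f$rd_q10, "Q10")
    )
  })
}
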