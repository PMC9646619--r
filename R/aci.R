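# Forward FvCB net assimilation at the measurement temperature (no 25 degC
# normalisation): Vcmax/Jmax/Rd are taken as valid at Tleaf directly.
.fvcb_at_leaf_T <- function(Ci, Vcmax, Jmax, Rd, gm, kinT,
                            PPFD = 1500, theta = 0.85, alpha = 0.24) {
  J  <- electron_transport(PPFD, Jmax, theta, alpha)
  Km <- kinT$Kc * (1 + kinT$O / kinT$Ko)
  Ac <- .assim_limited(Ci, Vcmax, Km, kinT$GammaStar, Rd, gm)
  Aj <- .assim_limited(Ci, J / 4, 2 * kinT$GammaStar, kinT$GammaStar, Rd, gm)
  list(A = pmin(Ac, Aj), Ac = Ac, Aj = Aj)
}

#' Fit Vcmax and Jmax to an A-Ci response curve
#'
#' Joint two-parameter nonlinear least squares of the FvCB model to a
#' measured A-Ci curve, with day respiration and mesophyll conductance held
#' fixed at their measured values (they are not co-fitted). The objective is
#' the sum of squared residuals between measured net assimilation and the
#' min(Ac, Aj) - Rd surface over all points; Levenberg-Marquardt with
#' bounded restarts from halved and doubled starting values. With
#' `temp_correct = FALSE` (the default and only implemented mode) the
#' returned Vcmax and Jmax are valid at the curve's leaf temperature, not
#' normalised to 25 degC; the kinetic constants are still evaluated at
#' `Tleaf`.
#'
#' @param curve A data frame with columns `Ci` (umol mol^-1) and `A`
#'   (umol m^-2 s^-1); at least 5 points, spanning below 300 and above
#'   600 umol mol^-1 for an identifiable fit.
#' @param Rd Measured day respiration (umol m^-2 s^-1).
#' @param gm Measured mesophyll conductance (mol m^-2 s^-1 bar^-1);
#'   `Inf` for the no-mesophyll-resistance model.
#' @param Tleaf Leaf temperature of the curve (degC).
#' @param PPFD Photon flux during the curve (umol m^-2 s^-1).
#' @param kinetics A [bernacchi_kinetics()] object.
#' @param theta,alpha Light-response shape constants.
#' @param temp_correct Must be `FALSE`: estimates are reported at `Tleaf`.
#' @param start Optional named vector `c(Vcmax = , Jmax = )` of starting
#'   values; defaults to `Vcmax = 100`, `Jmax = 170`.
#' @return An object of class `aci_fit`: a list with `coef` (named vector),
#'   `se`, `rss`, `convergence`, `fitted`, `limitation`, `data`, and the
#'   fixed inputs. `tidy()`, `glance()`, `autoplot()` and `predict()`
#'   methods are provided.
#' @examples
#' p <- cultivar_params("Scout")
#' curve <- net_assimilation(
#'   data.frame(Ci = c(50, 100, 230, 330, 420, 650, 1200, 1800)), p)
#' fit_aci(curve, Rd = 1.25, gm = 0.31)
#' @export
fit_aci <- function(curve, Rd, gm = Inf, Tleaf = 25, PPFD = 1500,
                    kinetics = bernacchi_kinetics(),
                    theta = 0.85, alpha = 0.24,
                    temp_correct = FALSE, start = NULL) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("Ci", "A") %in% names(curve))) {
    stop("curve must have Ci and A columns", call. = FALSE)
  }
  if (nrow(curve) < 5) {
    stop("A-Ci curve needs at least 5 points", call. = FALSE)
  }
  if (any(curve$Ci <= 0)) stop("Ci must be strictly positive", call. = FALSE)
  if (isTRUE(temp_correct)) {
    stop("temp_correct = TRUE is not implemented; estimates are reported ",
         "at the curve's leaf temperature", call. = FALSE)
  }
  jmax_identifiable <- any(curve$Ci > 600)
  if (!any(curve$Ci < 300) || !jmax_identifiable) {
    warning("Ci span does not cover both limitations (need points below ",
            "300 and above 600 umol mol-1); estimates may be unidentifiable",
            call. = FALSE)
  }

  kinT <- .kinetics_at(kinetics, Tleaf)
  resid_fn <- function(par) {
    pred <- .fvcb_at_leaf_T(curve$Ci, par[1], par[2], Rd, gm, kinT,
                            PPFD, theta, alpha)$A
    curve$A - pred
  }

  if (is.null(start)) start <- c(Vcmax = 100, Jmax = 170)
  starts <- list(start, start * 0.5, start * 2)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, fn = resid_fn,
        lower = c(1, 1), upper = c(2000, 2000),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-8, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
    if (!is.null(best) && fit$info %in% 1:4) break
  }
  if (is.null(best)) {
    stop("A-Ci fit failed to converge from all starting values ",
         "(Vcmax0 = ", start[1], ", and x0.5 / x2 restarts)", call. = FALSE)
  }

  fit <- best$fit
  par <- stats::setNames(fit$par, c("Vcmax", "Jmax"))
  pred <- .fvcb_at_leaf_T(curve$Ci, par["Vcmax"], par["Jmax"], Rd, gm, kinT,
                          PPFD, theta, alpha)
  limitation <- ifelse(pred$Ac <= pred$Aj, "Rubisco", "RuBP")
  if (length(unique(limitation)) < 2) {
    warning("all points share one limitation (", limitation[1],
            "); the other capacity parameter is weakly identified",
            call. = FALSE)
  }
  n <- nrow(curve)
  sigma2 <- best$rss / max(n - 2, 1)
  # standard errors from the Jacobian at the optimum (Gauss-Newton)
  Jac <- tryCatch({
    eps <- pmax(abs(par) * 1e-6, 1e-6)
    sapply(1:2, function(k) {
      pp <- par; pp[k] <- pp[k] + eps[k]
      (resid_fn(par) - resid_fn(pp)) / eps[k]
    })
  }, error = function(e) NULL)
  se <- if (!is.null(Jac)) {
    v <- tryCatch(sigma2 * solve(crossprod(Jac)),
                  error = function(e) matrix(NA_real_, 2, 2))
    sqrt(diag(v))
  } else c(NA_real_, NA_real_)

  structure(
    list(coef = par, se = stats::setNames(se, names(par)),
         rss = best$rss, convergence = fit$info %in% 1:4,
         fitted = pred$A, limitation = limitation,
         data = curve, Rd = Rd, gm = gm, Tleaf = Tleaf, PPFD = PPFD,
         kinetics = kinetics, theta = theta, alpha = alpha,
         axis = "Ci", fitmethod = "default"),
    class = "aci_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-point limitation labels along an A-Ci curve
#'
#' Labels each curve point by the active minimum of the Rubisco-limited and
#' RuBP-regeneration-limited rates at the supplied parameters. For
#' physiological parameter sets the labels are monotone along Ci with a
#' single Rubisco-to-RuBP switch.
#'
#' @param curve A data frame with a `Ci` column.
#' @param Vcmax,Jmax Capacity parameters at the leaf temperature.
#' @inheritParams fit_aci
#' @return The input tibble with `Ac`, `Aj` and `limitation` columns.
#' @export
assign_limitation <- function(curve, Vcmax, Jmax, Rd, gm = Inf, Tleaf = 25,
                              PPFD = 1500, kinetics = bernacchi_kinetics(),
                              theta = 0.85, alpha = 0.24) {
  curve <- tibble::as_tibble(curve)
  kinT <- .kinetics_at(kinetics, Tleaf)
  pred <- .fvcb_at_leaf_T(curve$Ci, Vcmax, Jmax, Rd, gm, kinT,
                          PPFD, theta, alpha)
  dplyr::mutate(curve, Ac = pred$Ac, Aj = pred$Aj,
                limitation = ifelse(pred$Ac <= pred$Aj, "Rubisco", "RuBP"))
}

#' Fit Vcmax and Jmax on the chloroplastic CO2 (A-Cc) axis
#'
#' Transforms the curve to the chloroplastic CO2 axis with the measured
#' mesophyll conductance, `Cc = Ci - A/gm` per point, then applies the same
#' joint estimator with mesophyll resistance removed (gm treated as
#' infinite thereafter). On data generated with finite gm the Ci-axis and
#' Cc-axis routes agree closely.
#'
#' @inheritParams fit_aci
#' @param gm Measured mesophyll conductance used for the transformation
#'   (mol m^-2 s^-1 bar^-1); must be finite here.
#' @return An `aci_fit` object (with `axis = "Cc"`).
#' @export
fit_from_cc <- function(curve, Rd, gm, Tleaf = 25, PPFD = 1500,
                        kinetics = bernacchi_kinetics(),
                        theta = 0.85, alpha = 0.24, start = NULL) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("Ci", "A") %in% names(curve))) {
    stop("curve must have Ci and A columns", call. = FALSE)
  }
  Cc <- curve$Ci - curve$A / gm
  if (any(Cc <= 0)) {
    stop("Cc = Ci - A/gm is non-positive at some points; ",
         "gm is inconsistent with the curve", call. = FALSE)
  }
  cc_curve <- dplyr::mutate(curve, Ci = Cc)
  fit <- fit_aci(cc_curve, Rd = Rd, gm = Inf, Tleaf = Tleaf, PPFD = PPFD,
                 kinetics = kinetics, theta = theta, alpha = alpha,
                 start = start)
  fit$axis <- "Cc"
  fit$gm <- gm
  fit
}

#' @export
print.aci_fit <- function(x, ...) {
  cat(sprintf("<aci_fit>  A-%s curve, %d points, Tleaf %.1f degC\n",
              x$axis, nrow(x$data), x$Tleaf))
  cat(sprintf("  Vcmax %.2f (se %.2f)   Jmax %.2f (se %.2f)  umol m-2 s-1\n",
              x$coef["Vcmax"], x$se["Vcmax"], x$coef["Jmax"], x$se["Jmax"]))
  cat(sprintf("  fixed: Rd %.3f, gm %s   RSS %.4g   converged: %s\n",
              x$Rd, format(x$gm), x$rss, x$convergence))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy aci_fit
#' @export
tidy.aci_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef),
                 estimate = unname(x$coef),
                 std.error = unname(x$se))
}

#' @method glance aci_fit
#' @export
glance.aci_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, nobs = nrow(x$data),
                 converged = x$convergence, axis = x$axis,
                 Tleaf = x$Tleaf, Rd = x$Rd, gm = x$gm,
                 fitmethod = x$fitmethod)
}

#' @export
predict.aci_fit <- function(object, newdata = NULL, ...) {
  Ci <- if (is.null(newdata)) object$data$Ci else newdata$Ci
  kinT <- .kinetics_at(object$kinetics, object$Tleaf)
  .fvcb_at_leaf_T(Ci, object$coef["Vcmax"], object$coef["Jmax"],
                  object$Rd, object$gm, kinT, object$PPFD,
                  object$theta, object$alpha)$A
}

#' Plot an A-Ci fit
#'
#' Measured points coloured by limitation with the fitted FvCB curve.
#'
#' @param object An `aci_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aci_fit
#' @export
autoplot.aci_fit <- function(object, ...) {
  grid <- tibble::tibble(
    Ci = seq(min(object$data$Ci), max(object$data$Ci), length.out = 200))
  grid$A <- predict(object, grid)
  pts <- dplyr::mutate(object$data, limitation = object$limitation)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$Ci, y = .data$A)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$limitation), size = 2) +
    ggplot2::labs(
      x = expression(C[i] ~ "(" * mu * mol ~ mol^-1 * ")"),
      y = expression(A ~ "(" * mu * mol ~ m^-2 ~ s^-1 * ")"),
      colour = "Limitation",
      title = sprintf("Vcmax = %.1f, Jmax = %.1f umol m-2 s-1",
                      object$coef["Vcmax"], object$coef["Jmax"])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
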