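# Quench-flow product-accumulation analysis: single-exponential kobs per
# concentration and the hyperbolic concentration dependence yielding Kd and kpol.

#' Construct a quench-flow product time course
#'
#' @param times Seconds, increasing.
#' @param product_fraction Fraction of primer extended, in `[0, 1]` (a product
#'   concentration in uM is accepted too; the exponential fit is scale-free).
#' @param conc_titrant Concentration of the varied species (ddNTP or enzyme), uM.
#' @param label Free text.
#' @return Object of class `"product_time_course"`.
#' @export
product_time_course <- function(times, product_fraction, conc_titrant = NA_real_,
                                label = "") {
  if (length(times) != length(product_fraction)) stop("length mismatch")
  if (any(diff(times) <= 0)) stop("times must be increasing")
  if (any(product_fraction < -1e-9)) stop("product signal must be non-negative")
  structure(list(times = as.numeric(times),
                 product_fraction = as.numeric(product_fraction),
                 conc_titrant = conc_titrant, label = label),
            class = "product_time_course")
}

#' Single-exponential fit of product accumulation
#'
#' Fits `P(t) = A * (1 - exp(-kobs * t))` by least squares (amplitude fitted,
#' not fixed) and returns the observed rate with its standard error.
#'
#' @param tc A [product_time_course()] with at least 4 points.
#' @return List of class `"kobs_point"`: `conc`, `kobs`, `kobs_stderr`,
#'   `A`, `rss`.
#' @export
fit_product_exponential <- function(tc) {
  t <- tc$times; y <- tc$product_fraction
  if (length(t) < 4) stop("need at least 4 time points")
  slope <- coef(lm.fit(cbind(1, t), y))[2]
  if (max(y) <= 1e-12 || slope <= 0)
    stop("product signal does not increase; cannot fit accumulation ",
         "(max signal ", format(max(y), digits = 3), ", trend ",
         format(slope, digits = 3), "/s)")
  k0 <- max(1 / t[max(which(y <= 0.632 * max(y)))], 1e-3)
  start <- c(A = max(y), logk = log(k0))
  res <- function(par) y - par[1] * (1 - exp(-exp(par[2]) * t))
  fit <- minpack.lm::nls.lm(par = start, fn = res,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  kobs <- exp(fit$par[["logk"]])
  dof <- length(t) - 2L
  se <- NA_real_
  cv <- tryCatch(chol2inv(chol(fit$hessian)), error = function(e) NULL)
  if (!is.null(cv) && dof > 0)
    se <- kobs * sqrt(cv[2, 2] * fit$deviance / dof)  # delta method from log k
  structure(list(conc = tc$conc_titrant, kobs = kobs, kobs_stderr = se,
                 A = fit$par[["A"]], rss = fit$deviance),
            class = "kobs_point")
}

#' Observed-rate hyperbola in the standard dissociation form
#' @param conc Titrant concentration, uM.
#' @param Kd Dissociation constant, uM.
#' @param kpol Maximal incorporation rate, s^-1.
#' @return `kpol * conc / (Kd + conc)`.
#' @export
kobs_hyperbola <- function(conc, Kd, kpol) kpol * conc / (Kd + conc)

#' Observed-rate hyperbola in the printed association form
#'
#' `kobs = K * kpol * c / (K * c + 1)` with `K` an association constant
#' (uM^-1); algebraically identical to [kobs_hyperbola()] with `Kd = 1/K`.
#' @param conc Titrant concentration, uM.
#' @param K Association constant, uM^-1.
#' @param kpol Maximal rate, s^-1.
#' @return Observed rate, s^-1.
#' @export
kobs_hyperbola_assoc <- function(conc, K, kpol) K * kpol * conc / (K * conc + 1)

#' Hyperbolic fit of the kobs concentration dependence
#'
#' Fits `kobs = kpol * c / (Kd + c)` over a set of per-concentration observed
#' rates, reporting `Kd` (uM) and `kpol` (s^-1) with standard errors plus the
#' equivalent association constant `K_assoc = 1/Kd` of the printed form.
#' Saturation (`Kd` far below the sampled range) and linear-regime
#' (`Kd` far above it) fits are flagged rather than trusted.
#'
#' @param points List of `kobs_point`s (>= 3 concentrations spanning >= 3-fold).
#' @return Object of class `"hyperbola_fit"`: `Kd`, `kpol`, `Kd_stderr`,
#'   `kpol_stderr`, `K_assoc`, `rss`, `flags`.
#' @export
fit_kobs_hyperbola <- function(points) {
  conc <- vapply(points, `[[`, 0, "conc")
  kobs <- vapply(points, `[[`, 0, "kobs")
  if (length(conc) < 3) stop("need >= 3 concentrations")
  if (max(conc) / min(conc) < 3) stop("concentrations must span >= 3-fold")
  if (any(kobs <= 0)) stop("kobs must be positive")
  start <- c(logKd = log(stats::median(conc)), logkpol = log(max(kobs)))
  res <- function(par)
    kobs - kobs_hyperbola(conc, exp(par[1]), exp(par[2]))
  fit <- minpack.lm::nls.lm(par = start, fn = res,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  Kd <- exp(fit$par[["logKd"]]); kpol <- exp(fit$par[["logkpol"]])
  flags <- character()
  if (Kd < min(conc) / 10) flags <- c(flags, "saturated_Kd_unidentifiable")
  if (Kd > max(conc) * 10) flags <- c(flags, "linear_regime_Kd_lower_bound_only")
  dof <- length(conc) - 2L
  se <- c(NA_real_, NA_real_)
  cv <- tryCatch(chol2inv(chol(fit$hessian)), error = function(e) NULL)
  if (!is.null(cv) && dof > 0)
    se <- c(Kd, kpol) * sqrt(pmax(diag(cv), 0) * fit$deviance / dof)
  structure(list(Kd = Kd, kpol = kpol, Kd_stderr = se[1], kpol_stderr = se[2],
                 K_assoc = 1 / Kd, rss = fit$deviance, flags = flags,
                 conc = conc, kobs = kobs),
            class = "hyperbola_fit")
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  cat(sprintf("<hyperbola_fit> Kd = %.4g uM (se %.3g), kpol = %.4g s^-1 (se %.3g)\n",
              x$Kd, x$Kd_stderr, x$kpol, x$kpol_stderr))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
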