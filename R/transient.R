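# Stopped-flow fluorescence traces: forward simulation, photobleach handling,
# variable-projection global fitting, empirical multi-exponential fits and
# mutant relative-activity comparison.

#' Construct a stopped-flow fluorescence trace
#'
#' @param times Seconds, strictly increasing.
#' @param signal Fluorescence, arbitrary units, finite.
#' @param channel `"Trp"` (intrinsic tryptophan) or `"CPy"` (pyrrolocytosine).
#' @param conc_enzyme,conc_primer,conc_nucleotide Mixing-cell concentrations, uM.
#' @param id Free-text identifier.
#' @param kbleach Photobleach rate (s^-1) calibrated for this trace; 0 = none.
#' @param F0 Background fluorescence used by the bleach model.
#' @return Object of class `"kin_trace"`.
#' @export
kin_trace <- function(times, signal, channel = c("Trp", "CPy"),
                      conc_enzyme = NA_real_, conc_primer = NA_real_,
                      conc_nucleotide = NA_real_, id = "",
                      kbleach = 0, F0 = 0) {
  channel <- match.arg(channel)
  if (length(times) != length(signal)) stop("times and signal lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(signal))) stop("signal must be finite")
  concs <- c(conc_enzyme, conc_primer, conc_nucleotide)
  if (any(!is.na(concs) & concs < 0)) stop("concentrations must be >= 0")
  if (kbleach < 0) stop("kbleach must be >= 0")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 channel = channel, conc_enzyme = conc_enzyme,
                 conc_primer = conc_primer, conc_nucleotide = conc_nucleotide,
                 id = id, kbleach = kbleach, F0 = F0),
            class = "kin_trace")
}

#' @export
print.kin_trace <- function(x, ...) {
  cat("<kin_trace>", x$id, sprintf(
    "(%s channel, %d points, %.4g-%.4g s; E=%g, primer=%g, dNTP=%g uM)\n",
    x$channel, length(x$times), min(x$times), max(x$times),
    x$conc_enzyme, x$conc_primer, x$conc_nucleotide))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.kin_trace <- function(x, ...) {
  data.frame(time_s = x$times, signal_au = x$signal)
}

#' Fluorescence observable model
#'
#' Ideal signal is `F0 + sum_i responses[i] * c_i(t)`; the observed signal is
#' attenuated by photobleaching of the above-background component:
#' `F_obs(t) = (F_ideal(t) - F0) * exp(-kbleach * t) + F0`.
#'
#' @param responses Named numeric vector, response coefficient (a.u./uM) per
#'   fluorescent species; species not listed contribute nothing.
#' @param F0 Background fluorescence (a.u.).
#' @param kbleach Photobleach rate (s^-1), `>= 0`.
#' @return Object of class `"observable_model"`.
#' @export
observable_model <- function(responses, F0 = 0, kbleach = 0) {
  if (is.null(names(responses)) || any(!nzchar(names(responses))))
    stop("responses must be a named vector")
  if (!any(responses != 0)) stop("at least one response must be nonzero")
  if (kbleach < 0) stop("kbleach must be >= 0")
  structure(list(responses = responses, F0 = F0, kbleach = kbleach),
            class = "observable_model")
}

#' Initial state vector for a mechanism from mixing concentrations
#'
#' Schemes with a preformed enzyme-primer complex start from
#' `[ED] = min(enzyme, primer)` (the excess partner is not a species of the
#' scheme and is inert); the primer-free scheme starts from free enzyme.
#'
#' @param m A [mechanism()].
#' @param enzyme,primer,nucleotide Concentrations after mixing, uM.
#' @return Named concentration vector over `m$species$name`.
#' @export
initial_concentrations <- function(m, enzyme, primer = 0, nucleotide = 0) {
  if (any(c(enzyme, primer, nucleotide) < 0))
    stop("initial concentrations must be >= 0")
  y0 <- setNames(numeric(nrow(m$species)), m$species$name)
  if ("E" %in% names(y0)) y0[["E"]] <- enzyme
  else y0[["ED"]] <- min(enzyme, primer)
  y0[["N"]] <- nucleotide
  y0
}

# Integrate a mechanism; returns concentration matrix (rows = times) with the
# species as columns. `times` need not include 0; integration starts at 0.
solve_concentrations <- function(m, p, y0, times, rtol = 1e-8, atol = 1e-10) {
  rhs <- derive_rhs(m, p)
  full <- m$species$name
  y <- setNames(numeric(length(full)), full)
  y[names(y0)] <- y0
  tt <- times
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  out <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol, method = "lsoda")
  conc <- out[, full, drop = FALSE]
  if (prepend) conc <- conc[-1, , drop = FALSE]
  conc
}

#' Default logarithmic stopped-flow time grid
#'
#' @param n Number of points.
#' @param t_min,t_max Window, s (defaults: instrument dead time to 10 s).
#' @return Numeric vector of times.
#' @export
stopped_flow_times <- function(n = 400, t_min = dead_time(), t_max = 10) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Simulate a fluorescence trace from a mechanism
#'
#' Integrates the mass-action ODEs (relative tolerance `1e-8`), applies the
#' species response coefficients and the photobleach attenuation of
#' [observable_model()].
#'
#' @param m A [mechanism()].
#' @param p A [rate_parameters()] set.
#' @param obs An [observable_model()].
#' @param init Named initial concentrations (uM); see [initial_concentrations()].
#' @param times Sampling times, s; default [stopped_flow_times()].
#' @param channel,id Trace metadata.
#' @param rtol Solver relative tolerance.
#' @return A [kin_trace()]; the bleach calibration (`kbleach`, `F0`) is carried
#'   in the trace.
#' @export
simulate_trace <- function(m, p, obs, init, times = stopped_flow_times(),
                           channel = c("Trp", "CPy"), id = "", rtol = 1e-8) {
  channel <- match.arg(channel)
  if (any(init < 0)) stop("initial concentrations must be >= 0")
  conc <- solve_concentrations(m, p, init, times, rtol = rtol)
  resp <- obs$responses[names(obs$responses) %in% colnames(conc)]
  ideal <- obs$F0 + as.numeric(conc[, names(resp), drop = FALSE] %*% resp)
  signal <- (ideal - obs$F0) * exp(-obs$kbleach * times) + obs$F0
  full <- setNames(numeric(nrow(m$species)), m$species$name)
  full[names(init)] <- init
  enz <- sum(full * m$species$n_enzyme)
  prm <- sum(full * m$species$n_primer)
  nuc <- sum(full * m$species$n_nucleotide)
  kin_trace(times, signal, channel = channel, conc_enzyme = enz,
            conc_primer = prm, conc_nucleotide = nuc, id = id,
            kbleach = obs$kbleach, F0 = obs$F0)
}

#' Correct a trace for photobleaching
#'
#' Inverts the exponential attenuation of the above-background fluorescence:
#' `F = (F_obs - F0) * exp(kbleach * t) + F0`. Applying the forward bleach model
#' to the corrected trace reproduces the input exactly.
#'
#' @param trace A [kin_trace()].
#' @param F0 Background fluorescence (default: the trace's own calibration).
#' @param kbleach Bleach rate, s^-1 (default: the trace's own calibration).
#' @return The corrected [kin_trace()] (with `kbleach` reset to 0).
#' @export
correct_photobleach <- function(trace, F0 = trace$F0, kbleach = trace$kbleach) {
  if (kbleach < 0) stop("kbleach must be >= 0")
  out <- trace
  out$signal <- (trace$signal - F0) * exp(kbleach * trace$times) + F0
  out$kbleach <- 0
  out$F0 <- F0
  out
}

#' Estimate the photobleach rate from a chemically static calibration trace
#'
#' Least-squares fit of `F0 + A * exp(-kbleach * t)`; `kbleach >= 0` is
#' enforced. A trace that does not decay yields `kbleach = 0` with a warning
#' flag rather than an error.
#'
#' @param trace A [kin_trace()] recorded with static chemistry.
#' @return List with `kbleach`, `F0`, `A`, `converged` and `nondecaying`.
#' @export
estimate_kbleach <- function(trace) {
  t <- trace$times; y <- trace$signal
  n <- length(y)
  head_m <- mean(y[seq_len(max(3, n %/% 10))])
  tail_m <- mean(y[seq(n - max(3, n %/% 10) + 1, n)])
  if (tail_m >= head_m) {
    warning("trace does not decay; kbleach set to 0")
    return(list(kbleach = 0, F0 = mean(y), A = 0,
                converged = TRUE, nondecaying = TRUE))
  }
  start <- c(F0 = tail_m, A = head_m - tail_m,
             logk = log(3 / (max(t) - min(t))))
  res <- function(par) y - (par[1] + par[2] * exp(-exp(par[3]) * t))
  fit <- minpack.lm::nls.lm(par = start, fn = res,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  list(kbleach = exp(fit$par[["logk"]]), F0 = fit$par[["F0"]],
       A = fit$par[["A"]], converged = fit$info %in% 1:3, nondecaying = FALSE)
}

#' Declare which response coefficients are fixed vs fitted for one channel
#'
#' Absolute fluorescence is in arbitrary units, so the response scale is fixed
#' by convention: one coefficient per channel is held at a known value (the
#' free-nucleotide response for the CPy channel, the unbound enzyme-primer
#' complex response for the Trp channel) and the remaining responses plus the
#' background `F0` are profiled out linearly.
#'
#' Fluorophores contribute additively, so a species carrying both an
#' incorporated dye and a newly bound one responds with the sum of the two
#' environment responses. `free` may therefore be either a character vector of
#' species (one independent coefficient each) or a named list of weight vectors
#' tying one coefficient to a weighted combination of species — e.g.
#' `list(r_inc = c(ED1 = 1, C1b = 1, ED2 = 2))` fits a single
#' incorporated-dye response shared by every species in proportion to its
#' incorporated-residue count. Tying keeps the linear problem well-conditioned
#' when a concentration series probes few distinct initial states.
#'
#' @param channel `"Trp"` or `"CPy"`.
#' @param fixed Named numeric vector of fixed response coefficients.
#' @param free Character vector of species whose responses are fitted, or a
#'   named list of species-weight vectors (tied response groups).
#' @param fit_F0 Fit a shared background for the channel (default `TRUE`).
#' @param F0 Background value used when `fit_F0 = FALSE`.
#' @return Object of class `"response_spec"`.
#' @export
response_spec <- function(channel = c("Trp", "CPy"), fixed = numeric(),
                          free = character(), fit_F0 = TRUE, F0 = 0) {
  channel <- match.arg(channel)
  if (length(fixed) && (is.null(names(fixed)) || any(!nzchar(names(fixed)))))
    stop("fixed responses must be named")
  if (is.character(free))
    free <- setNames(lapply(free, function(s) setNames(1, s)), free)
  if (length(free) && (is.null(names(free)) || any(!nzchar(names(free)))))
    stop("free response groups must be named")
  structure(list(channel = channel, fixed = fixed, free = free,
                 fit_F0 = fit_F0, F0 = F0),
            class = "response_spec")
}

# Per-channel linear solve of free responses and F0 given simulated
# concentrations. Returns fitted values, coefficients and a rank-deficiency flag.
profile_linear <- function(spec, rows) {
  y <- unlist(lapply(rows, `[[`, "y"))
  offset <- unlist(lapply(rows, function(r) r$fixed_part))
  X <- do.call(rbind, lapply(rows, `[[`, "X"))
  yy <- y - offset
  if (!spec$fit_F0) yy <- yy - spec$F0
  if (ncol(X) == 0L) {
    return(list(fitted = offset + if (!spec$fit_F0) spec$F0 else 0,
                coef = numeric(), F0 = if (spec$fit_F0) NA_real_ else spec$F0,
                degenerate = FALSE))
  }
  fit <- lm.fit(X, yy)
  degenerate <- fit$rank < ncol(X)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  fitted <- offset + as.numeric(X %*% beta) + if (!spec$fit_F0) spec$F0 else 0
  F0 <- if (spec$fit_F0) unname(beta[["(F0)"]]) else spec$F0
  coefs <- beta[setdiff(names(beta), "(F0)")]
  list(fitted = fitted, coef = coefs, F0 = F0, degenerate = degenerate)
}

#' Global fit of rate constants to a set of stopped-flow traces
#'
#' Minimises the summed squared residuals over all traces simultaneously. Rate
#' constants are searched in log space by seeded multi-start (log-uniform draws
#' within the bounds, screened by their initial residual sum of squares, the
#' best `n_refine` refined by Levenberg-Marquardt); response coefficients and
#' backgrounds are linear in the signal and are profiled out exactly at every
#' candidate (variable projection), so only rate constants are searched
#' nonlinearly. Per-trace photobleach rates are taken from the traces' own
#' calibration and held fixed unless `co_fit_kbleach = TRUE`, which co-fits one
#' shared bleach rate. Points before the instrument dead time are ignored.
#'
#' @param traces List of [kin_trace()] at distinct concentrations (>= 2 for a
#'   concentration series; a single trace is accepted for empirical use).
#' @param m A [mechanism()].
#' @param free Character vector of rate-constant names to fit.
#' @param lower,upper Named bounds (same names as `free`), all `> 0`.
#' @param fixed Named numeric vector of rate constants held fixed.
#' @param specs A [response_spec()] or list of them, one per channel present.
#' @param n_starts Number of log-uniform multi-start draws (default 20).
#' @param n_refine How many screened starts to polish (default 5).
#' @param n_hops Basin-hopping restarts around the incumbent best (default 8):
#'   log-space jitter followed by a full Levenberg-Marquardt polish.
#' @param seed Integer seed making the start draws deterministic.
#' @param weighting `"none"` (default) or `"inverse_variance"` (per-trace
#'   weights from a robust noise estimate).
#' @param co_fit_kbleach Co-fit a single shared photobleach rate.
#' @param rtol ODE solver relative tolerance used during fitting.
#' @return Object of class `"global_fit"`: full `parameters`, per-parameter
#'   `stderr`, per-channel `responses` and `F0`, `rss`, `converged`, `flags`,
#'   `n_starts_used` and per-trace `fitted` curves.
#' @export
fit_global <- function(traces, m, free, lower, upper, fixed = NULL,
                       specs, n_starts = 20, n_refine = 5, n_hops = 8, seed = 1,
                       weighting = c("none", "inverse_variance"),
                       co_fit_kbleach = FALSE, rtol = 1e-8) {
  weighting <- match.arg(weighting)
  if (inherits(traces, "kin_trace")) traces <- list(traces)
  if (inherits(specs, "response_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, "", "channel")
  if (length(free) == 0) stop("no free parameters")
  if (!all(free %in% names(lower)) || !all(free %in% names(upper)))
    stop("bounds must be named for every free parameter")
  if (any(lower[free] <= 0)) stop("bounds must keep rates positive")
  flags <- character()

  span <- vapply(traces, function(tr) diff(range(tr$signal)), 0)
  scale <- max(abs(unlist(lapply(traces, `[[`, "signal"))), 1e-300)
  if (all(span <= 1e-12 * scale)) {
    warning("traces carry no signal; fit is non-identifiable")
    return(structure(list(parameters = NULL, stderr = NULL, responses = NULL,
                          rss = NA_real_, converged = FALSE,
                          flags = "non_identifiable", n_starts_used = 0L,
                          fitted = NULL),
                     class = "global_fit"))
  }

  keep <- lapply(traces, function(tr) tr$times >= dead_time() - 1e-12)
  wts <- lapply(seq_along(traces), function(i) {
    n <- sum(keep[[i]])
    if (weighting == "none") rep(1, n)
    else {
      s <- sd(diff(traces[[i]]$signal[keep[[i]]])) / sqrt(2)
      rep(1 / max(s, 1e-12), n)
    }
  })

  chans <- vapply(traces, `[[`, "", "channel")
  if (!all(chans %in% names(specs)))
    stop("missing response_spec for channel(s): ",
         paste(setdiff(chans, names(specs)), collapse = ", "))

  theta_names <- free
  lo <- log10(lower[free]); hi <- log10(upper[free])
  if (co_fit_kbleach) {
    theta_names <- c(theta_names, ".kbleach")
    lo <- c(lo, .kbleach = log10(1e-4)); hi <- c(hi, .kbleach = log10(10))
  }

  eval_model <- function(theta) {
    p <- c(fixed, setNames(10^theta[free], free))
    kb_shared <- if (co_fit_kbleach) 10^theta[[".kbleach"]] else NULL
    per_chan <- setNames(vector("list", length(specs)), names(specs))
    for (i in seq_along(traces)) {
      tr <- traces[[i]]
      spec <- specs[[tr$channel]]
      tt <- tr$times[keep[[i]]]
      y0 <- initial_concentrations(m, tr$conc_enzyme, tr$conc_primer,
                                   tr$conc_nucleotide)
      conc <- solve_concentrations(m, p, y0, tt, rtol = rtol)
      kb <- if (is.null(kb_shared)) tr$kbleach else kb_shared
      bl <- exp(-kb * tt)
      fixed_part <- if (length(spec$fixed)) {
        nm <- intersect(names(spec$fixed), colnames(conc))
        as.numeric(conc[, nm, drop = FALSE] %*% spec$fixed[nm]) * bl
      } else numeric(length(tt))
      X <- vapply(spec$free, function(w)
        as.numeric(conc[, names(w), drop = FALSE] %*% w) * bl,
        numeric(length(tt)))
      X <- matrix(X, nrow = length(tt),
                  dimnames = list(NULL, names(spec$free)))
      if (spec$fit_F0) X <- cbind(`(F0)` = 1, X)
      per_chan[[tr$channel]] <- c(per_chan[[tr$channel]], list(list(
        y = tr$signal[keep[[i]]], fixed_part = fixed_part, X = X,
        w = wts[[i]], trace = i, n = length(tt))))
    }
    resid <- list(); lin <- list(); degenerate <- FALSE
    fitted_by_trace <- vector("list", length(traces))
    for (ch in names(per_chan)) {
      if (is.null(per_chan[[ch]])) next
      pl <- profile_linear(specs[[ch]], per_chan[[ch]])
      degenerate <- degenerate || pl$degenerate
      lin[[ch]] <- pl
      ofs <- 0L
      for (r in per_chan[[ch]]) {
        idx <- ofs + seq_len(r$n); ofs <- ofs + r$n
        fitted_by_trace[[r$trace]] <- pl$fitted[idx]
        resid[[length(resid) + 1L]] <- (r$y - pl$fitted[idx]) * r$w
      }
    }
    list(resid = unlist(resid), lin = lin, degenerate = degenerate,
         fitted = fitted_by_trace, p = p)
  }

  resid_fn <- function(theta) {
    # extreme draws can overrun the stiff solver; treat as off-model
    out <- tryCatch(
      suppressWarnings(eval_model(setNames(theta, theta_names))$resid),
      error = function(e) NULL)
    if (is.null(out) || !all(is.finite(out)))
      rep(1e6 * sqrt(scale), sum(lengths(wts)))
    else out
  }

  set.seed(seed)
  # stratified (Latin-hypercube) log-uniform draws: one draw per equal-width
  # stratum per dimension, independently permuted, for even bound coverage
  starts <- vapply(seq_along(theta_names), function(j)
    (sample(n_starts) - runif(n_starts)) / n_starts, numeric(n_starts))
  starts <- matrix(starts, nrow = n_starts)
  starts <- sweep(sweep(starts, 2, hi - lo, "*"), 2, lo, "+")
  colnames(starts) <- theta_names
  # maxiter-reached in the short screening polish is expected, not a problem
  run_lm <- function(par, maxiter = 120) tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par, fn = resid_fn, lower = lo, upper = hi,
      # epsfcn keeps finite-difference steps well above the ODE solver
      # noise; the default sqrt(machine eps) step makes Jacobians garbage
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                           ptol = 1e-10, epsfcn = 1e-6))),
    error = function(e) NULL)

  # three-stage screen: raw RSS at every draw, a short Levenberg-Marquardt
  # polish of the most promising draws (raw RSS barely separates basins), and
  # a full refinement of the best-polished few
  rss0 <- apply(starts, 1, function(th) sum(resid_fn(th)^2))
  n_short <- min(3L * n_refine, n_starts)
  short_idx <- order(rss0)[seq_len(n_short)]
  shorts <- lapply(short_idx, function(i) run_lm(starts[i, ], maxiter = 12))
  short_rss <- vapply(shorts, function(f)
    if (is.null(f)) Inf else f$deviance, 0)
  best <- NULL
  for (j in order(short_rss)[seq_len(min(n_refine, n_short))]) {
    if (is.null(shorts[[j]])) next
    fit <- run_lm(coef(shorts[[j]]))
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all multi-start fits failed")
  # exchange-symmetry restarts: sequential first-order steps of a linear
  # pathway can trade roles in a local optimum (e.g. a slow conformational
  # step with fast chemistry mimics the reverse), so restart from
  # role-swapped variants of the incumbent before accepting it
  swappable <- intersect(c("k2", "kpol", "kt"), theta_names)
  if (length(swappable) >= 2) {
    pairs <- utils::combn(swappable, 2, simplify = FALSE)
    for (pr in pairs) {
      par0 <- coef(best)
      par0[pr] <- par0[rev(pr)]
      par0 <- pmin(pmax(par0, lo), hi)
      fit <- run_lm(par0)
      if (!is.null(fit) && fit$deviance < best$deviance) best <- fit
    }
  }
  # profile restarts: competing basins typically displace one slow-step rate
  # by a small factor with the others compensating, so re-descend from the
  # incumbent with each such rate pushed a factor of 3 either way
  for (nm in intersect(c("k2", "k_minus2", "kpol", "kt"), theta_names)) {
    for (shift in c(log10(3), -log10(3))) {
      par0 <- coef(best)
      par0[nm] <- par0[nm] + shift
      par0 <- pmin(pmax(par0, lo), hi)
      fit <- run_lm(par0, maxiter = 200)
      if (!is.null(fit) && fit$deviance < best$deviance) best <- fit
    }
  }
  # valley descent: the objective has long, curved, nearly flat valleys along
  # correlated rate combinations where Levenberg-Marquardt stalls; alternate a
  # long deep polish with small log-space jitters until stationary
  for (round in seq_len(max(n_hops, 1L))) {
    before <- best$deviance
    deep <- run_lm(coef(best), maxiter = 500)
    if (!is.null(deep) && deep$deviance < best$deviance) best <- deep
    for (hop in 1:3) {
      par0 <- pmin(pmax(coef(best) + rnorm(length(lo), sd = 0.15), lo), hi)
      fit <- run_lm(par0, maxiter = 200)
      if (!is.null(fit) && fit$deviance < best$deviance) best <- fit
    }
    if (before - best$deviance < 1e-8 * (best$deviance + 1e-30)) break
  }

  theta_hat <- setNames(coef(best), theta_names)
  final <- eval_model(theta_hat)
  rss <- sum(final$resid^2)
  converged <- best$info %in% 1:4
  if (!converged) flags <- c(flags, "non_convergence")
  if (final$degenerate) flags <- c(flags, "degenerate_responses")

  # standard errors: delta method on the log10-space LM covariance
  stderr <- rep(NA_real_, length(theta_names))
  names(stderr) <- theta_names
  dof <- length(final$resid) - length(theta_names) -
    sum(vapply(final$lin, function(l) length(l$coef) + !is.na(l$F0), 0L))
  ch <- tryCatch(chol2inv(chol(best$hessian)), error = function(e) NULL)
  if (!is.null(ch) && dof > 0) {
    se_theta <- sqrt(pmax(diag(ch), 0) * rss / dof)
    stderr <- log(10) * 10^theta_hat * se_theta
  }
  params <- final$p
  responses <- lapply(final$lin, function(l) list(coef = l$coef, F0 = l$F0))

  structure(list(parameters = params,
                 stderr = setNames(stderr, theta_names),
                 responses = responses, rss = rss, converged = converged,
                 flags = flags, n_starts_used = n_starts,
                 fitted = final$fitted, theta = theta_hat,
                 free = free, traces = traces),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit> RSS =", format(x$rss, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$parameters)) {
    for (nm in x$free)
      cat(sprintf("  %-10s %.6g  (se %.3g)\n", nm, x$parameters[[nm]],
                  x$stderr[[nm]]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Empirical multi-exponential fit of a trace
#'
#' Fits `offset + sum_j A_j * exp(-kobs_j * t)` with 1 to 3 phases by seeded
#' multi-start variable projection (amplitudes and offset profiled linearly,
#' rates searched in log space). Phases are reported sorted by `kobs`
#' descending. If two fitted rates collapse (within 1% of each other) the fit
#' carries a reduced-model warning flag.
#'
#' @param trace A [kin_trace()].
#' @param n_phases 1, 2 or 3.
#' @param n_starts Multi-start draws (default 40).
#' @param seed Integer seed.
#' @param k_range Search range for the rates, s^-1 (default set from the
#'   trace's time span).
#' @return Object of class `"multiexp_fit"`: `n_phases`, `kobs` (descending),
#'   `amplitudes` (matched to `kobs`), `offset`, `rss`, `flags`.
#' @export
fit_multiexponential <- function(trace, n_phases, n_starts = 40, seed = 1,
                                 k_range = NULL) {
  stopifnot(n_phases %in% 1:3)
  t <- trace$times; y <- trace$signal
  if (2 * n_phases + 1 >= length(t))
    stop("too few points for ", n_phases, " phases")
  if (is.null(k_range)) k_range <- c(0.05 / max(t), 5 / min(t))
  lo <- rep(log10(k_range[1]), n_phases)
  hi <- rep(log10(k_range[2]), n_phases)

  lin_fit <- function(logk) {
    k <- sort(10^logk, decreasing = TRUE)
    X <- cbind(1, exp(-outer(t, k)))
    f <- lm.fit(X, y)
    beta <- f$coefficients; beta[is.na(beta)] <- 0
    list(resid = y - as.numeric(X %*% beta), k = k,
         offset = beta[1], A = beta[-1])
  }
  set.seed(seed)
  starts <- matrix(runif(n_starts * n_phases, lo[1], hi[1]), ncol = n_phases)
  rss0 <- apply(starts, 1, function(th) sum(lin_fit(th)$resid^2))
  best <- NULL
  for (i in order(rss0)[seq_len(min(6, n_starts))]) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lo, upper = hi,
                         fn = function(th) lin_fit(th)$resid,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("multi-exponential fit failed")
  final <- lin_fit(coef(best))
  flags <- character()
  if (n_phases > 1) {
    ratios <- final$k[-n_phases] / final$k[-1]
    if (any(ratios < 1.01)) {
      warning("phase collapse: two kobs within 1%; consider fewer phases")
      flags <- c(flags, "reduced_model")
    }
  }
  structure(list(n_phases = n_phases, kobs = unname(final$k),
                 amplitudes = unname(final$A), offset = unname(final$offset),
                 rss = sum(final$resid^2), flags = flags),
            class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat("<multiexp_fit>", x$n_phases, "phase(s), RSS =",
      format(x$rss, digits = 4), "\n")
  for (j in seq_len(x$n_phases))
    cat(sprintf("  phase %d: kobs = %.5g s^-1, A = %.4g\n",
                j, x$kobs[j], x$amplitudes[j]))
  invisible(x)
}

#' Per-phase relative activity of a mutant versus wild type
#'
#' Normalises each observed rate constant of the mutant to the corresponding
#' wild-type constant, phases matched by descending-`kobs` order.
#'
#' @param mutant,wildtype [fit_multiexponential()] results with equal phase counts.
#' @return Numeric vector of per-phase ratios `kobs_mut / kobs_wt`.
#' @export
relative_activity <- function(mutant, wildtype) {
  if (mutant$n_phases != wildtype$n_phases)
    stop("phase-count mismatch: ", mutant$n_phases, " vs ", wildtype$n_phases)
  mutant$kobs / wildtype$kobs
}
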