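# Config-driven workflow commands tying the stages together. Each command takes
# a validated config (a named list, or a path to a YAML file), checks its inputs
# before writing anything, logs the seed and solver settings, and writes
# plain-text outputs. Flagged non-convergence is an error, never silent, so
# script drivers exit nonzero.

#' Validate a command config
#'
#' Unknown keys are rejected (no silent typos); missing required keys are
#' reported together.
#'
#' @param config Named list or path to a YAML file.
#' @param required,optional Character vectors of allowed keys.
#' @return The config as a named list.
#' @export
validate_config <- function(config, required, optional = character()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML file path")
  unknown <- setdiff(names(config), c(required, optional))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  config
}

log_run <- function(cmd, seed, extra = NULL) {
  message(sprintf("[tdtkinetics %s] %s: seed=%s, ode_rtol=1e-08%s",
                  as.character(packageVersion("tdtkinetics")), cmd,
                  if (is.null(seed)) "none" else seed,
                  if (is.null(extra)) "" else paste0(", ", extra)))
}

ensure_outdir <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outdir
}

check_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
}

#' Simulate stopped-flow traces from a config
#'
#' Config keys: `scheme`, `params` (named rates), `responses` (named), `design`
#' (list of rows with `enzyme`, `primer`, `nucleotide`), `outdir`; optional
#' `options` (scheme options), `F0`, `kbleach`, `channel`, `times`
#' (`n`, `t_min`, `t_max`).
#'
#' @param config Named list or YAML path.
#' @return Paths of the written trace CSVs, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- validate_config(config,
                         required = c("scheme", "params", "responses",
                                      "design", "outdir"),
                         optional = c("options", "F0", "kbleach", "channel",
                                      "times"))
  m <- do.call(build_scheme, c(list(name = cfg$scheme),
                               if (is.null(cfg$options)) list() else cfg$options))
  p <- do.call(rate_parameters, as.list(cfg$params))
  obs <- observable_model(unlist(cfg$responses),
                          F0 = if (is.null(cfg$F0)) 0 else cfg$F0,
                          kbleach = if (is.null(cfg$kbleach)) 0 else cfg$kbleach)
  tcfg <- cfg$times
  times <- if (is.null(tcfg)) stopped_flow_times()
           else stopped_flow_times(tcfg$n, tcfg$t_min, tcfg$t_max)
  channel <- if (is.null(cfg$channel)) "Trp" else cfg$channel
  log_run("simulate", seed = NULL, extra = paste0("scheme=", cfg$scheme))
  ensure_outdir(cfg$outdir)
  paths <- character()
  for (i in seq_along(cfg$design)) {
    d <- cfg$design[[i]]
    init <- initial_concentrations(m, d$enzyme, d$primer, d$nucleotide)
    tr <- simulate_trace(m, p, obs, init, times = times, channel = channel,
                         id = sprintf("sim_%02d", i))
    tr$conc_enzyme <- d$enzyme; tr$conc_primer <- d$primer
    tr$conc_nucleotide <- d$nucleotide
    paths[i] <- file.path(cfg$outdir, sprintf("trace_%02d.csv", i))
    write_trace_csv(tr, paths[i])
  }
  invisible(paths)
}

#' Generate a synthetic dataset (plus ground truth) from a config
#'
#' Config keys: `kind` (`"stopped_flow"`, `"quench"`, `"decay"`,
#' `"alignment"`), `outdir`; optional `preset`, `seed`, `noise_sigma` and
#' kind-specific overrides (`total_counts`, `n_sequences`, `n_duplicates`,
#' `n_fragments`). The ground truth is written alongside as YAML.
#'
#' @param config Named list or YAML path.
#' @return Invisible list of written paths.
#' @export
run_generate <- function(config) {
  cfg <- validate_config(config, required = c("kind", "outdir"),
                         optional = c("preset", "seed", "noise_sigma",
                                      "total_counts", "n_sequences",
                                      "n_duplicates", "n_fragments"))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  log_run("generate", seed, extra = paste0("kind=", cfg$kind))
  ensure_outdir(cfg$outdir)
  paths <- character()
  if (cfg$kind == "stopped_flow") {
    preset <- if (is.null(cfg$preset)) "cpy_scheme3" else cfg$preset
    sigma <- if (is.null(cfg$noise_sigma)) 0.01 else cfg$noise_sigma
    truth <- preset_truth(preset, noise_sigma = sigma, seed = seed)
    gen <- gen_stopped_flow(truth)
    for (i in seq_along(gen$traces)) {
      paths[i] <- file.path(cfg$outdir, sprintf("trace_%02d.csv", i))
      write_trace_csv(gen$traces[[i]], paths[i])
    }
    truth_rec <- list(preset = preset, params = as.list(truth$params),
                      responses = as.list(truth$observable$responses),
                      F0 = truth$observable$F0,
                      kbleach = truth$observable$kbleach,
                      noise_sigma = sigma, seed = seed)
  } else if (cfg$kind == "quench") {
    sigma <- if (is.null(cfg$noise_sigma)) 0.02 else cfg$noise_sigma
    truth <- preset_truth_quench(noise_sigma = sigma, seed = seed)
    gen <- gen_quench(truth)
    for (i in seq_along(gen$courses)) {
      paths[i] <- file.path(cfg$outdir, sprintf("quench_%02d.csv", i))
      write_quench_csv(gen$courses[[i]], paths[i])
    }
    truth_rec <- list(params = as.list(truth$params), noise_sigma = sigma,
                      seed = seed)
  } else if (cfg$kind == "decay") {
    preset <- if (is.null(cfg$preset)) "free_dCPyTP" else cfg$preset
    pp <- decay_preset(preset)
    total <- if (is.null(cfg$total_counts)) 1e6 else cfg$total_counts
    gen <- gen_decay(pp$lifetimes, pp$amplitudes, total_counts = total,
                     seed = seed)
    paths <- file.path(cfg$outdir, "decay.csv")
    write_decay_csv(gen$histogram, paths)
    truth_rec <- c(gen$truth, list(preset = preset))
  } else if (cfg$kind == "alignment") {
    n <- if (is.null(cfg$n_sequences)) 469 else cfg$n_sequences
    gen <- gen_alignment(n_sequences = n,
                         n_duplicates = if (is.null(cfg$n_duplicates)) 0
                                        else cfg$n_duplicates,
                         n_fragments = if (is.null(cfg$n_fragments)) 0
                                       else cfg$n_fragments,
                         seed = seed)
    paths <- file.path(cfg$outdir, "alignment.fasta")
    write_alignment_fasta(gen$alignment, paths)
    truth_rec <- list(n_sequences = n, seed = seed,
                      duplicate_ids = gen$truth$duplicate_ids,
                      fragment_ids = gen$truth$fragment_ids)
  } else stop("unknown kind '", cfg$kind, "'")
  truth_path <- file.path(cfg$outdir, "truth.yaml")
  yaml::write_yaml(truth_rec, truth_path)
  invisible(list(data = paths, truth = truth_path))
}

#' Global transient fit from a config
#'
#' Config keys: `traces` (CSV paths), `scheme`, `free`, `lower`, `upper`,
#' `fixed_responses`, `outdir`; optional `options`, `fixed`, `free_responses`
#' (default: all species appearing in neither list get no response),
#' `fit_F0`, `n_starts`, `n_refine`, `seed`. Writes `transient_fit.txt` and
#' `transient_residuals.csv`.
#'
#' @param config Named list or YAML path.
#' @return The [fit_global()] result, invisibly.
#' @export
run_fit_transient <- function(config) {
  cfg <- validate_config(config,
                         required = c("traces", "scheme", "free", "lower",
                                      "upper", "fixed_responses", "outdir"),
                         optional = c("options", "fixed", "free_responses",
                                      "fit_F0", "n_starts", "n_refine", "seed"))
  check_inputs(unlist(cfg$traces))
  traces <- lapply(unlist(cfg$traces), read_trace_csv)
  m <- do.call(build_scheme, c(list(name = cfg$scheme),
                               if (is.null(cfg$options)) list() else cfg$options))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  n_starts <- if (is.null(cfg$n_starts)) 20 else cfg$n_starts
  n_refine <- if (is.null(cfg$n_refine)) 5 else cfg$n_refine
  channel <- traces[[1]]$channel
  spec <- response_spec(channel, fixed = unlist(cfg$fixed_responses),
                        free = if (is.null(cfg$free_responses)) character()
                               else unlist(cfg$free_responses),
                        fit_F0 = if (is.null(cfg$fit_F0)) TRUE else cfg$fit_F0)
  log_run("fit_transient", seed,
          extra = sprintf("scheme=%s, n_starts=%d", cfg$scheme, n_starts))
  fit <- fit_global(traces, m, free = unlist(cfg$free),
                    lower = unlist(cfg$lower), upper = unlist(cfg$upper),
                    fixed = if (is.null(cfg$fixed)) NULL else unlist(cfg$fixed),
                    specs = spec, n_starts = n_starts, n_refine = n_refine,
                    seed = seed)
  if (!fit$converged || length(fit$flags))
    stop("transient fit flagged: ",
         paste(c(if (!fit$converged) "non_convergence", fit$flags),
               collapse = ", "))
  ensure_outdir(cfg$outdir)
  rep <- c(as.list(fit$parameters[cfg$free]),
           setNames(as.list(fit$stderr[cfg$free]),
                    paste0(cfg$free, "_stderr")),
           list(rss = fit$rss, n_starts = fit$n_starts_used, seed = seed))
  write_report(rep, file.path(cfg$outdir, "transient_fit.txt"))
  resid <- do.call(rbind, lapply(seq_along(traces), function(i) {
    keep <- traces[[i]]$times >= dead_time() - 1e-12
    data.frame(trace = traces[[i]]$id, time_s = traces[[i]]$times[keep],
               signal_au = traces[[i]]$signal[keep],
               fitted_au = fit$fitted[[i]],
               residual_au = traces[[i]]$signal[keep] - fit$fitted[[i]])
  }))
  write.csv(resid, file.path(cfg$outdir, "transient_residuals.csv"),
            row.names = FALSE)
  invisible(fit)
}

#' Quench-flow Kd/kpol analysis from a config
#'
#' Config keys: `files` (per-concentration CSVs) or `file` (long CSV),
#' `outdir`. Writes `quench_fit.txt`.
#'
#' @param config Named list or YAML path.
#' @return The [fit_kobs_hyperbola()] result, invisibly.
#' @export
run_fit_quench <- function(config) {
  cfg <- validate_config(config, required = "outdir",
                         optional = c("files", "file"))
  if (is.null(cfg$files) && is.null(cfg$file))
    stop("missing required config key(s): files (or file)")
  courses <- if (!is.null(cfg$files)) {
    check_inputs(unlist(cfg$files))
    lapply(unlist(cfg$files), read_quench_csv)
  } else {
    check_inputs(cfg$file)
    read_quench_csv(cfg$file)
  }
  log_run("fit_quench", seed = NULL,
          extra = paste0("n_concentrations=", length(courses)))
  points <- lapply(courses, fit_product_exponential)
  hyp <- fit_kobs_hyperbola(points)
  ensure_outdir(cfg$outdir)
  write_report(list(Kd_uM = hyp$Kd, Kd_stderr = hyp$Kd_stderr,
                    kpol_per_s = hyp$kpol, kpol_stderr = hyp$kpol_stderr,
                    K_assoc_per_uM = hyp$K_assoc, rss = hyp$rss,
                    flags = paste(hyp$flags, collapse = ";")),
               file.path(cfg$outdir, "quench_fit.txt"))
  invisible(hyp)
}

#' TCSPC lifetime analysis from a config
#'
#' Config keys: `file` (decay CSV), `outdir`; optional `n_components`
#' (1, 2 or `"auto"` for F-test selection), `seed`. Writes `lifetime_fit.txt`.
#'
#' @param config Named list or YAML path.
#' @return The [fit_decay()] result, invisibly.
#' @export
run_fit_lifetime <- function(config) {
  cfg <- validate_config(config, required = c("file", "outdir"),
                         optional = c("n_components", "seed"))
  check_inputs(cfg$file)
  h <- read_decay_csv(cfg$file)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  nc <- if (is.null(cfg$n_components)) "auto" else cfg$n_components
  log_run("fit_lifetime", seed, extra = paste0("n_components=", nc))
  if (identical(nc, "auto")) nc <- select_model(h, seed = seed)
  fit <- fit_decay(h, as.integer(nc), seed = seed)
  if (!fit$converged) stop("lifetime fit did not converge")
  ensure_outdir(cfg$outdir)
  rep <- list(n_components = fit$n_components,
              chi2_reduced = fit$chi2_reduced, seed = seed)
  for (j in seq_len(fit$n_components)) {
    rep[[paste0("tau", j, "_ns")]] <- fit$lifetimes[j]
    rep[[paste0("amplitude", j)]] <- fit$amplitudes[j]
  }
  write_report(rep, file.path(cfg$outdir, "lifetime_fit.txt"))
  invisible(fit)
}

#' Alignment conservation profiling from a config
#'
#' Config keys: `fasta`, `outdir`; optional `reference_id`, `positions`,
#' `min_coverage`, `exclude_ambiguous`. Writes `conservation_profile.tsv`.
#'
#' @param config Named list or YAML path.
#' @return The [pocket_profile()] list, invisibly.
#' @export
run_profile_alignment <- function(config) {
  cfg <- validate_config(config, required = c("fasta", "outdir"),
                         optional = c("reference_id", "positions",
                                      "min_coverage", "exclude_ambiguous"))
  check_inputs(cfg$fasta)
  a <- read_alignment_fasta(cfg$fasta, reference_id = cfg$reference_id)
  log_run("profile_alignment", seed = NULL,
          extra = paste0("n=", length(a$records)))
  a <- filter_redundancy(a, min_coverage = if (is.null(cfg$min_coverage)) 0.8
                                           else cfg$min_coverage)
  positions <- if (is.null(cfg$positions)) pocket_positions()
               else as.integer(unlist(cfg$positions))
  prof <- pocket_profile(a, positions,
                         exclude_ambiguous = isTRUE(cfg$exclude_ambiguous))
  ensure_outdir(cfg$outdir)
  write_profile_tsv(prof, file.path(cfg$outdir, "conservation_profile.tsv"))
  invisible(prof)
}
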