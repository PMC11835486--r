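#' A diced-fraction time series
#'
#' Observed (or simulated) fraction of pre-miRNA converted to mature
#' miRNA over time, together with the assay's initial concentrations.
#' Small negative fractions from quantification noise are tolerated on
#' input (down to -0.05) and flagged, never silently clipped.
#'
#' @param times_min time points in minutes, non-negative ascending.
#' @param diced_fraction fraction matured at each time, nominally in
#'   \[0, 1\].
#' @param P0,D0 initial pre-miRNA and Dicer concentrations (nM).
#' @param label condition name, e.g. `"WT"` or `"SL"`.
#' @return A `dicing_timeseries` data.frame with attributes `P0`, `D0`,
#'   `label`, `n_flagged` (points outside \[0, 1\]).
#' @export
dicing_timeseries <- function(times_min, diced_fraction, P0, D0,
                              label = "data") {
  if (length(times_min) != length(diced_fraction)) {
    stop("'times_min' and 'diced_fraction' must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(times_min)) || any(times_min < 0) ||
      is.unsorted(times_min)) {
    stop("'times_min' must be non-negative and ascending", call. = FALSE)
  }
  if (any(!is.finite(diced_fraction)) ||
      any(diced_fraction < -0.05 | diced_fraction > 1.05)) {
    stop("diced fractions must lie in [-0.05, 1.05]", call. = FALSE)
  }
  if (P0 <= 0) stop("'P0' must be > 0", call. = FALSE)
  if (D0 < 0) stop("'D0' must be >= 0", call. = FALSE)
  structure(
    data.frame(time_min = times_min, diced_fraction = diced_fraction),
    class = c("dicing_timeseries", "data.frame"),
    P0 = P0, D0 = D0, label = label,
    n_flagged = sum(diced_fraction < 0 | diced_fraction > 1)
  )
}

#' Read / write diced-fraction time series as TSV
#'
#' Plain tab-separated files with columns `time_min` and `diced_fraction`;
#' `P0`, `D0` and the label travel as `# key: value` header comments.
#'
#' @param path file path.
#' @param ts a [dicing_timeseries()] (for writing).
#' @param P0,D0,label used if the file carries no header comments.
#' @return A [dicing_timeseries()] (reader); invisibly `path` (writer).
#' @export
read_dicing_timeseries <- function(path, P0 = 1, D0 = 5, label = "data") {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m)) trimws(sub(".*:", "", m[1L])) else default
  }
  P0 <- as.numeric(meta("P0_nM", P0))
  D0 <- as.numeric(meta("D0_nM", D0))
  label <- meta("label", label)
  df <- utils::read.delim(textConnection(grep("^#", lines, value = TRUE,
                                              invert = TRUE)))
  dicing_timeseries(df$time_min, df$diced_fraction, P0 = P0, D0 = D0,
                    label = label)
}

#' @rdname read_dicing_timeseries
#' @export
write_dicing_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "dicing_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", attr(ts, "label")),
               sprintf("# P0_nM: %g", attr(ts, "P0")),
               sprintf("# D0_nM: %g", attr(ts, "D0"))), con)
  utils::write.table(as.data.frame(ts), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Diced fraction along a trajectory
#'
#' @param traj a `dicer_trajectory` from [simulate_kinetics()].
#' @param species_label which species; defaults to the only one.
#' @return Data frame with `time_s` and `fraction` = M(t)/P0.
#' @export
diced_fraction <- function(traj, species_label = NULL) {
  stopifnot(inherits(traj, "dicer_trajectory"))
  config <- attr(traj, "config")
  labs <- config_labels(config)
  if (is.null(species_label)) {
    if (length(labs) != 1L) {
      stop("multiple species present; give 'species_label'", call. = FALSE)
    }
    species_label <- labs
  }
  if (!species_label %in% labs) {
    stop("unknown species '", species_label, "'", call. = FALSE)
  }
  P0 <- config_P0(config)[match(species_label, labs)]
  if (P0 <= 0) {
    stop("diced fraction undefined for P0 = 0 (species '", species_label,
         "')", call. = FALSE)
  }
  sub <- traj[traj$species == species_label, ]
  data.frame(time_s = sub$time_s, fraction = sub$M / P0)
}

# model diced fractions at the data's time points (minutes -> seconds)
model_fractions <- function(k_a, k_b, k_c, k_d, data,
                            rtol = 1e-8, atol = 1e-10) {
  P0 <- attr(data, "P0"); D0 <- attr(data, "D0")
  cfg <- system_config(list(species_spec("fit", P0,
                                         rate_set(k_a, k_b, k_c, k_d))),
                       D0 = D0)
  tsec <- data$time_min * 60
  grid <- if (tsec[1L] == 0) tsec else c(0, tsec)
  traj <- simulate_kinetics(cfg, t_end = max(grid), times = grid,
                            rtol = rtol, atol = atol)
  fr <- diced_fraction(traj, "fit")
  fr$fraction[match(tsec, fr$time_s)]
}

#' Sum-of-squares objective for constrained rate fitting
#'
#' Residual sum of squares between the model's diced-fraction curve and an
#' observed time series, with the dissociation rate tied to the
#' association rate through the fixed dissociation constant
#' (`k_b = kd_ratio * k_a`). Solver failures return `penalty` rather than
#' raising, so a stochastic optimizer can rank past them.
#'
#' @param params numeric vector `(k_a, k_c, k_d)` on the natural scale.
#' @param data a [dicing_timeseries()].
#' @param kd_ratio fixed Kd = k_b/k_a (nM).
#' @param penalty sentinel objective value for failed evaluations.
#' @return Scalar SSE (squared-fraction units).
#' @export
sse_objective <- function(params, data, kd_ratio, penalty = 1e6) {
  stopifnot(inherits(data, "dicing_timeseries"), kd_ratio > 0)
  k_a <- params[[1L]]; k_c <- params[[2L]]; k_d <- params[[3L]]
  fit <- tryCatch(
    model_fractions(k_a, kd_ratio * k_a, k_c, k_d, data),
    error = function(e) NULL
  )
  if (is.null(fit) || any(!is.finite(fit))) return(penalty)
  sum((fit - data$diced_fraction)^2)
}

#' Fit rate constants to a dicing time course under a Kd constraint
#'
#' Minimizes [sse_objective()] over `(k_a, k_c, k_d)` with CMA-ES,
#' searching in log10 space because the plausible rates span many orders
#' of magnitude. The dissociation rate is never a free parameter: every
#' candidate (and the returned fit) has `k_b = kd_ratio * k_a` exactly.
#'
#' The diced-fraction curve constrains the plateau
#' `q = k_a k_d / (k_a k_d + k_c (k_b + k_d))` and the depletion rate
#' `(k_a + k_c) D` much more tightly than the individual rates; when
#' `k_d >> k_b` the likelihood is flat in `k_d`, so interpret recovered
#' rates through `q` and the fitted curve.
#'
#' @param data a [dicing_timeseries()] with at least 3 points.
#' @param kd_ratio fixed Kd = k_b/k_a (nM), e.g. [let7_kd_ratio()].
#' @param log10_bounds length-2 log10 search bounds applied to each rate.
#' @param x0 log10-scale start point for `(k_a, k_c, k_d)`.
#' @param sigma initial CMA-ES step size (log10 units).
#' @param popsize,max_evals,seed passed to [cma_es()].
#' @return A `fit_result`: list with the fitted [rate_set()], `kd_ratio`,
#'   `sse`, `n_evaluations`, `converged`, `seed`, and the per-generation
#'   SSE `trace`.
#' @export
fit_constrained <- function(data, kd_ratio,
                            log10_bounds = c(-5, 5),
                            x0 = c(-2, -2, 0), sigma = 1.5,
                            popsize = 10L, max_evals = 2000L,
                            seed = 1234L) {
  stopifnot(inherits(data, "dicing_timeseries"))
  if (nrow(data) < 3L) stop("need at least 3 time points", call. = FALSE)

  obj <- function(theta) {
    rates <- 10^theta
    # every candidate carries k_b = kd_ratio * k_a by construction
    k_b <- kd_ratio * rates[1L]
    stopifnot(abs(k_b / rates[1L] - kd_ratio) <= 1e-12 * kd_ratio)
    sse_objective(rates, data, kd_ratio)
  }
  opt <- cma_es(obj, x0 = x0, sigma = sigma,
                lower = log10_bounds[1L], upper = log10_bounds[2L],
                popsize = popsize, max_evals = max_evals, seed = seed)
  k <- 10^opt$par
  structure(
    list(rates = rate_set(k_a = k[1L], k_b = kd_ratio * k[1L],
                          k_c = k[2L], k_d = k[3L]),
         kd_ratio = kd_ratio, sse = opt$value,
         n_evaluations = opt$n_evaluations, converged = opt$converged,
         seed = seed, trace = opt$trace),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> SSE=%.3g after %d evaluations (Kd=%g nM)\n",
              x$sse, x$n_evaluations, x$kd_ratio))
  print(x$rates)
  invisible(x)
}
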