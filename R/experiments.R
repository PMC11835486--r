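#' The eight-species competition panel
#'
#' Eight hypothetical pre-miRNA species built from a common base rate set:
#' for each rate in (k_a, k_b, k_c, k_d), one species with that rate
#' scaled 10-fold ("hi") and one scaled 20-fold ("2hi"), all other rates
#' left at the base values. Labels are fixed as `ka_hi, ka_2hi, kb_hi,
#' kb_2hi, kc_hi, kc_2hi, kd_hi, kd_2hi` so matrix row/column order is
#' stable.
#'
#' @param base base [rate_set()]; default the wild-type let-7 rates.
#' @param P0 initial concentration given to every species (nM).
#' @param scales the two fold scalings.
#' @return A list of 8 [species_spec()] objects.
#' @export
#' @examples
#' panel <- competition_panel()
#' vapply(panel, function(s) s$label, character(1))
competition_panel <- function(base = dicing_rates_let7("wt"), P0 = 1,
                              scales = c(10, 20)) {
  stopifnot(inherits(base, "rate_set"), length(scales) == 2L)
  out <- list()
  for (rate in c("k_a", "k_b", "k_c", "k_d")) {
    for (j in 1:2) {
      r <- unclass(base)
      r[[rate]] <- r[[rate]] * scales[j]
      lab <- paste0(sub("k_", "k", rate), if (j == 1L) "_hi" else "_2hi")
      out[[lab]] <- species_spec(lab, P0,
                                 do.call(rate_set, r))
    }
  }
  unname(out)
}

# panel with one species' P0 replaced
set_species_P0 <- function(panel, label, P0) {
  labs <- vapply(panel, `[[`, character(1), "label")
  i <- match(label, labs)
  if (is.na(i)) stop("unknown species '", label, "'", call. = FALSE)
  panel[[i]] <- species_spec(label, P0, panel[[i]]$rates)
  panel
}

#' Steady-state sweep of one rate against a concentration grid
#'
#' For a single species, scales one rate constant over a multiplicative
#' grid while varying either the Dicer pool `D0` or the initial pre-miRNA
#' `P0`, recording steady-state mature miRNA at every grid point.
#'
#' @param rates base [rate_set()].
#' @param rate_name one of `"k_a"`, `"k_b"`, `"k_c"`, `"k_d"`.
#' @param scale_grid multiplicative scalings of the chosen rate; default
#'   25 log-spaced points over 1e-2..1e2.
#' @param D0_grid,P0_grid exactly one of these is a grid; the other is a
#'   single fixed value. Defaults: vary `D0` over 40 points in
#'   0.01..15 nM at fixed `P0 = 1`.
#' @param ... passed to [run_to_steady_state()].
#' @return A `sweep_result` data.frame with columns `scale`, `D0`, `P0`,
#'   `M`.
#' @export
single_species_sweep <- function(rates, rate_name,
                                 scale_grid = 10^seq(-2, 2, length.out = 25),
                                 D0_grid = seq(0.01, 15, length.out = 40),
                                 P0_grid = 1, ...) {
  stopifnot(inherits(rates, "rate_set"))
  if (!rate_name %in% c("k_a", "k_b", "k_c", "k_d")) {
    stop("'rate_name' must be one of k_a, k_b, k_c, k_d", call. = FALSE)
  }
  grid <- expand.grid(scale = scale_grid, D0 = D0_grid, P0 = P0_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$M <- vapply(seq_len(nrow(grid)), function(i) {
    r <- unclass(rates)
    r[[rate_name]] <- r[[rate_name]] * grid$scale[i]
    if (grid$P0[i] == 0) return(0)
    cfg <- system_config(list(species_spec("s", grid$P0[i],
                                           do.call(rate_set, r))),
                         D0 = grid$D0[i])
    unname(steady_mature(run_to_steady_state(cfg, ...)))
  }, numeric(1))
  structure(grid, class = c("sweep_result", "data.frame"),
            rate_name = rate_name)
}

#' Steady-state mature miRNA of a panel across a Dicer grid
#'
#' Runs the competition panel to steady state at each Dicer availability,
#' with all species drawing on one shared pool (competition) or each
#' simulated alone with the full pool (control).
#'
#' @param panel list of [species_spec()], e.g. [competition_panel()].
#' @param D_grid Dicer concentrations (nM).
#' @param shared_dicer competition (`TRUE`) or isolated pools (`FALSE`).
#' @param P0 optional uniform override of every species' initial
#'   concentration (nM); `NULL` keeps the panel's own values.
#' @param ... passed to [run_to_steady_state()].
#' @return A `sweep_result` data.frame with columns `D0`, `P0`, `species`,
#'   `M`.
#' @export
dicer_sweep <- function(panel, D_grid = seq(0.01, 8, length.out = 40),
                        shared_dicer = TRUE, P0 = NULL, ...) {
  rows <- lapply(D_grid, function(D0) {
    pp <- panel
    if (!is.null(P0)) {
      for (i in seq_along(pp)) {
        pp[[i]] <- species_spec(pp[[i]]$label, P0, pp[[i]]$rates)
      }
    }
    if (all(vapply(pp, `[[`, numeric(1), "P0") == 0)) {
      labs <- vapply(pp, `[[`, character(1), "label")
      return(data.frame(D0 = D0, P0 = if (is.null(P0)) 0 else P0,
                        species = labs, M = 0))
    }
    cfg <- system_config(pp, D0 = D0, shared_dicer = shared_dicer)
    M <- steady_mature(run_to_steady_state(cfg, ...))
    data.frame(D0 = D0, P0 = if (is.null(P0)) NA_real_ else P0,
               species = names(M), M = unname(M))
  })
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"),
            shared_dicer = shared_dicer)
}

#' Fold change of steady-state mature miRNA against a reference condition
#'
#' @param result a `sweep_result` from [dicer_sweep()] or
#'   [premirna_dicer_sweep()].
#' @param reference named list selecting the reference grid point, e.g.
#'   `list(D0 = 8)`; must match exactly one row per species.
#' @return Data frame `species`, plus the grid columns, and `fold_change`
#'   (`NA` where the reference is 0 and the numerator is not).
#' @export
fold_change <- function(result, reference) {
  stopifnot(inherits(result, "sweep_result"))
  keep <- rep(TRUE, nrow(result))
  for (nm in names(reference)) {
    keep <- keep & abs(result[[nm]] - reference[[nm]]) < 1e-12
  }
  ref <- result[keep, ]
  if (!nrow(ref)) stop("reference point not on the grid", call. = FALSE)
  if (anyDuplicated(ref$species)) {
    stop("reference selects more than one grid point per species",
         call. = FALSE)
  }
  refM <- stats::setNames(ref$M, ref$species)
  out <- result
  out$fold_change <- ifelse(
    refM[out$species] > 0, out$M / refM[out$species],
    ifelse(out$M == 0, NA_real_, NA_real_)
  )
  # reference rows are exactly 1 when reference M > 0
  out$fold_change[keep & refM[out$species] > 0] <- 1
  out
}

#' Joint pre-miRNA / Dicer sweep with fold changes
#'
#' Varies the initial concentration of every panel species uniformly
#' together with the Dicer pool, and reports fold changes of steady
#' mature miRNA relative to the abundant reference condition
#' (`P0 = 5` nM per species, `D0 = 15` nM by default).
#'
#' @inheritParams dicer_sweep
#' @param P0_grid per-species initial concentrations (nM).
#' @param reference named list with the reference `P0` and `D0`.
#' @return Data frame `D0`, `P0`, `species`, `M`, `fold_change`.
#' @export
premirna_dicer_sweep <- function(panel,
                                 P0_grid = seq(0, 5, length.out = 21),
                                 D_grid = seq(0.01, 15, length.out = 40),
                                 reference = list(P0 = 5, D0 = 15),
                                 shared_dicer = TRUE, ...) {
  if (!any(abs(P0_grid - reference$P0) < 1e-12)) {
    P0_grid <- sort(c(P0_grid, reference$P0))
  }
  if (!any(abs(D_grid - reference$D0) < 1e-12)) {
    D_grid <- sort(c(D_grid, reference$D0))
  }
  parts <- lapply(P0_grid, function(p0) {
    dicer_sweep(panel, D_grid = D_grid, shared_dicer = shared_dicer,
                P0 = p0, ...)
  })
  res <- structure(do.call(rbind, parts),
                   class = c("sweep_result", "data.frame"),
                   shared_dicer = shared_dicer)
  fold_change(res, reference)
}

#' Minimum Dicer needed to reach a fold-change threshold
#'
#' For each panel species, finds the smallest Dicer availability at which
#' the steady mature miRNA reaches `threshold` times its value at the
#' abundant reference (`D0 = 8` nM). A coarse grid locates the bracketing
#' interval and bisection refines the crossing to `tol` nM; species that
#' never reach the threshold on the range are reported as `NA`.
#'
#' @inheritParams dicer_sweep
#' @param threshold fold-change threshold in (0, 1].
#' @param D_range search range for `D0` (nM).
#' @param n_grid coarse grid size.
#' @param tol bisection tolerance (nM).
#' @param reference_D0 Dicer availability defining the fold-change
#'   reference (nM).
#' @return Data frame `species`, `min_dicer` (nM, `NA` if not reached).
#' @export
min_dicer_for_fold_change <- function(panel, threshold = 0.5,
                                      shared_dicer = TRUE,
                                      D_range = c(0.01, 8), n_grid = 12L,
                                      tol = 1e-3, reference_D0 = 8, ...) {
  stopifnot(threshold > 0, threshold <= 1)
  labs <- vapply(panel, `[[`, character(1), "label")
  M_at <- function(D0) {
    cfg <- system_config(panel, D0 = D0, shared_dicer = shared_dicer)
    steady_mature(run_to_steady_state(cfg, ...))[labs]
  }
  refM <- M_at(reference_D0)
  fc_at <- function(D0) M_at(D0) / refM
  grid <- seq(D_range[1L], D_range[2L], length.out = n_grid)
  fc <- vapply(grid, fc_at, numeric(length(labs)))
  min_d <- vapply(seq_along(labs), function(i) {
    hit <- which(fc[i, ] >= threshold)
    if (!length(hit)) return(NA_real_)
    j <- hit[1L]
    if (j == 1L) return(grid[1L])
    lo <- grid[j - 1L]; hi <- grid[j]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (fc_at(mid)[[i]] >= threshold) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  data.frame(species = labs, min_dicer = min_d)
}

#' One in-silico overexpression or knockout run
#'
#' Sets one panel species' initial concentration to `level` (5 nM
#' overexpression or 0 nM knockout in the published design), runs the
#' system to steady state at the given Dicer availability, and reports
#' every species' fold change of steady mature miRNA against the
#' unperturbed all-equal baseline.
#'
#' @inheritParams dicer_sweep
#' @param perturbed_label the species to perturb.
#' @param level new initial concentration for that species (nM).
#' @param D0 Dicer availability (nM); 1.55 nM is a regime with marked
#'   competition for the default panel.
#' @param baseline optional precomputed baseline mature vector (named, nM)
#'   to avoid re-running it across many perturbations.
#' @param ... passed to [run_to_steady_state()].
#' @return Named numeric vector of fold changes (one per species).
#' @export
perturbation_experiment <- function(panel, perturbed_label, level,
                                    D0 = 1.55, shared_dicer = TRUE,
                                    baseline = NULL, ...) {
  labs <- vapply(panel, `[[`, character(1), "label")
  if (!perturbed_label %in% labs) {
    stop("unknown species '", perturbed_label, "'", call. = FALSE)
  }
  if (is.null(baseline)) {
    cfg0 <- system_config(panel, D0 = D0, shared_dicer = shared_dicer)
    baseline <- steady_mature(run_to_steady_state(cfg0, ...))
  }
  pp <- set_species_P0(panel, perturbed_label, level)
  cfg <- system_config(pp, D0 = D0, shared_dicer = shared_dicer)
  M <- steady_mature(run_to_steady_state(cfg, ...))[labs]
  fc <- ifelse(baseline[labs] > 0, M / baseline[labs],
               ifelse(M == 0, NA_real_, NA_real_))
  stats::setNames(fc, labs)
}

#' Full perturbation matrix
#'
#' Perturbs each panel species in turn (rows) and collects all species'
#' fold changes (columns) against the unperturbed baseline.
#'
#' @inheritParams perturbation_experiment
#' @return An n x n matrix of fold changes; rows = perturbed species,
#'   columns = responding species. Attribute `level` records the
#'   perturbation.
#' @export
#' @examples
#' \donttest{
#' pm <- perturbation_matrix(competition_panel(), level = 0)
#' diag(pm) # knockouts mature nothing
#' }
perturbation_matrix <- function(panel, level, D0 = 1.55,
                                shared_dicer = TRUE, ...) {
  labs <- vapply(panel, `[[`, character(1), "label")
  cfg0 <- system_config(panel, D0 = D0, shared_dicer = shared_dicer)
  baseline <- steady_mature(run_to_steady_state(cfg0, ...))
  rows <- lapply(labs, function(lab) {
    perturbation_experiment(panel, lab, level, D0 = D0,
                            shared_dicer = shared_dicer,
                            baseline = baseline, ...)
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(perturbed = labs, species = labs)
  structure(m, level = level, D0 = D0, shared_dicer = shared_dicer)
}
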