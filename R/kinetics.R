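# State vector layout for n species: [P_1..P_n, PD_1..PD_n, S_1..S_n,
# M_1..M_n, D]. All concentrations in nM, time in seconds.

state_index <- function(n) {
  list(P = seq_len(n), PD = n + seq_len(n), S = 2L * n + seq_len(n),
       M = 3L * n + seq_len(n), D = 4L * n + 1L)
}

initial_state <- function(config) {
  n <- length(config$species)
  y0 <- numeric(4L * n + 1L)
  y0[seq_len(n)] <- config_P0(config)
  y0[4L * n + 1L] <- config$D0
  y0
}

#' Mass-action derivatives of the maturation system
#'
#' Right-hand side of the ODE system. Each pre-miRNA species P binds free
#' Dicer D reversibly (rates `k_a`, `k_b`) to form a transient complex PD
#' that is cleaved at rate `k_d` into mature miRNA M (releasing Dicer), or
#' binds irreversibly at rate `k_c` into a stalled complex S that
#' permanently sequesters both molecules. With several species sharing the
#' pool, the Dicer equation sums the binding/release fluxes over species so
#' that total Dicer D + sum(PD_i + S_i) is conserved.
#'
#' @param state numeric state vector `(P_1..P_n, PD_1..PD_n, S_1..S_n,
#'   M_1..M_n, D)` in nM.
#' @param config a [system_config()] with `n` species.
#' @return Numeric derivative vector of the same length (nM/s).
#' @export
#' @examples
#' cfg <- system_config(
#'   list(species_spec("let7", 1, dicing_rates_let7("wt"))), D0 = 5)
#' dicer_derivatives(c(1, 0, 0, 0, 5), cfg)
dicer_derivatives <- function(state, config) {
  n <- length(config$species)
  if (length(state) != 4L * n + 1L) {
    stop("state has length ", length(state), " but config implies ",
         4L * n + 1L, call. = FALSE)
  }
  if (!all(is.finite(state))) stop("non-finite state entries", call. = FALSE)
  rates <- config_rates(config)
  deriv_from_rates(state, rates)
}

# vectorized rhs shared by dicer_derivatives and the deSolve callback
deriv_from_rates <- function(state, rates) {
  n <- nrow(rates)
  P <- state[seq_len(n)]
  PD <- state[n + seq_len(n)]
  D <- state[4L * n + 1L]
  ka <- rates[, "k_a"]; kb <- rates[, "k_b"]
  kc <- rates[, "k_c"]; kd <- rates[, "k_d"]
  bind <- (ka + kc) * P * D          # total P-consuming flux
  dP <- kb * PD - bind
  dPD <- ka * P * D - (kb + kd) * PD
  dS <- kc * P * D
  dM <- kd * PD
  dD <- sum((kb + kd) * PD) - sum(bind)
  unname(c(dP, dPD, dS, dM, dD))
}

# integrate one shared-pool system over 'times'; returns deSolve matrix
integrate_system <- function(config, times, rtol, atol) {
  rates <- config_rates(config)
  y0 <- initial_state(config)
  rhs <- function(t, y, parms) list(deriv_from_rates(y, rates))
  out <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1L] < 0) {
    stop("ODE integration failed for species {",
         paste(config_labels(config), collapse = ", "),
         "} (lsoda istate ", attr(out, "istate")[1L], ")", call. = FALSE)
  }
  guard <- 10 * (atol + rtol * max(sum(config_P0(config)), config$D0, 1))
  if (min(out[, -1L]) < -guard) {
    stop("integration produced concentrations below -", signif(guard, 3),
         " nM; tighten tolerances", call. = FALSE)
  }
  out
}

# deSolve matrix -> tidy long data.frame
trajectory_frame <- function(out, config) {
  n <- length(config$species)
  labs <- config_labels(config)
  idx <- state_index(n)
  times <- out[, 1L]
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      time_s = times,
      species = labs[i],
      P = out[, 1L + idx$P[i]],
      PD = out[, 1L + idx$PD[i]],
      S = out[, 1L + idx$S[i]],
      M = out[, 1L + idx$M[i]],
      D = out[, 1L + idx$D],
      row.names = NULL
    )
  }))
}

#' Simulate the maturation kinetics
#'
#' Integrates the mass-action system with a stiff-capable adaptive solver
#' (`deSolve::lsoda`). With `shared_dicer = FALSE` in the config, each
#' species is integrated in its own system with the full Dicer pool `D0`
#' (the no-competition control), and the `D` column reports that species'
#' own free-Dicer pool.
#'
#' @param config a [system_config()].
#' @param t_end horizon in seconds (> 0).
#' @param times optional explicit output grid in seconds (must start at 0);
#'   default 200 evenly spaced points.
#' @param rtol,atol solver tolerances. The dicing rate of wild-type let-7
#'   (~1e4 /s) makes the system stiff; loose tolerances visibly violate
#'   the conservation laws.
#' @return A `dicer_trajectory`: a long data.frame with columns `time_s`,
#'   `species`, `P`, `PD`, `S`, `M`, `D`, carrying the config as an
#'   attribute.
#' @export
#' @examples
#' cfg <- system_config(
#'   list(species_spec("let7", 1, dicing_rates_let7("wt"))), D0 = 5)
#' traj <- simulate_kinetics(cfg, t_end = 3600)
#' tail(subset(traj, species == "let7"))
simulate_kinetics <- function(config, t_end, times = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(config, "system_config"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0) {
    stop("'t_end' must be a single positive number of seconds", call. = FALSE)
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = 200L)
  if (times[1L] != 0) stop("output grid must start at time 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("output grid must be strictly increasing", call. = FALSE)
  }

  if (config$shared_dicer || length(config$species) == 1L) {
    out <- integrate_system(config, times, rtol, atol)
    df <- trajectory_frame(out, config)
  } else {
    df <- do.call(rbind, lapply(config$species, function(sp) {
      sub <- system_config(list(sp), D0 = config$D0, shared_dicer = TRUE)
      trajectory_frame(integrate_system(sub, times, rtol, atol), sub)
    }))
  }
  structure(df, class = c("dicer_trajectory", "data.frame"),
            config = config, rtol = rtol, atol = atol)
}

#' Integrate to steady state
#'
#' Runs the system on a logarithmically spaced probe grid until the
#' largest absolute derivative over all state variables falls below
#' `steady_tol`, or `t_max` is reached. The default horizon is 3000 min,
#' long enough for either free Dicer or every free pre-miRNA pool to be
#' exhausted in all regimes studied here.
#'
#' @inheritParams simulate_kinetics
#' @param steady_tol derivative threshold (nM/s) declaring steady state.
#' @param t_max hard cap in seconds (default 180000 s = 3000 min).
#' @param n_probes number of logarithmic probe times.
#' @return A `steady_state` object: list with `state` (data.frame
#'   `species`, `P`, `PD`, `S`, `M`, `D`), `converged`, `t_end`, and the
#'   config. For a shared pool the `D` column repeats the single free-Dicer
#'   concentration; for isolated pools it is per-species.
#' @export
run_to_steady_state <- function(config, steady_tol = 1e-9, t_max = 180000,
                                n_probes = 200L, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(config, "system_config"))
  if (t_max <= 0) stop("'t_max' must be positive", call. = FALSE)

  single <- function(cfg) {
    times <- c(0, 10^seq(-2, log10(t_max), length.out = n_probes))
    out <- integrate_system(cfg, times, rtol, atol)
    rates <- config_rates(cfg)
    dmax <- apply(out[, -1L, drop = FALSE], 1L,
                  function(y) max(abs(deriv_from_rates(y, rates))))
    hit <- which(dmax < steady_tol)
    row <- if (length(hit)) hit[1L] else nrow(out)
    list(state = out[row, -1L], converged = length(hit) > 0,
         t_end = out[row, 1L])
  }

  if (config$shared_dicer || length(config$species) == 1L) {
    res <- single(config)
    n <- length(config$species)
    idx <- state_index(n)
    st <- data.frame(species = config_labels(config),
                     P = res$state[idx$P], PD = res$state[idx$PD],
                     S = res$state[idx$S], M = res$state[idx$M],
                     D = res$state[idx$D], row.names = NULL)
    conv <- res$converged
    t_end <- res$t_end
  } else {
    parts <- lapply(config$species, function(sp) {
      sub <- system_config(list(sp), D0 = config$D0, shared_dicer = TRUE)
      r <- single(sub)
      cbind(data.frame(species = sp$label, P = r$state[1L], PD = r$state[2L],
                       S = r$state[3L], M = r$state[4L], D = r$state[5L],
                       row.names = NULL),
            converged = r$converged, t_end = r$t_end)
    })
    all <- do.call(rbind, parts)
    st <- all[, c("species", "P", "PD", "S", "M", "D")]
    conv <- all(all$converged)
    t_end <- max(all$t_end)
  }
  structure(list(state = st, converged = conv, t_end = t_end,
                 config = config),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> t_end=%g s, converged=%s\n", x$t_end,
              x$converged))
  print(x$state, ...)
  invisible(x)
}

#' Steady-state mature miRNA per species
#'
#' @param ss a `steady_state` from [run_to_steady_state()].
#' @return Named numeric vector of mature miRNA concentrations (nM).
#' @export
steady_mature <- function(ss) {
  stopifnot(inherits(ss, "steady_state"))
  stats::setNames(ss$state$M, ss$state$species)
}

#' Closed-form diced fraction when Dicer is never limiting
#'
#' Treating one pre-miRNA molecule's fate as a Markov chain P -> PD ->
#' {mature, back to P} versus P -> stalled, the probability of eventual
#' maturation is `q = k_a k_d / (k_a k_d + k_c (k_b + k_d))`, independent
#' of the Dicer concentration as long as free Dicer never reaches zero.
#' Under that condition the steady-state M/P0 equals `q`; callers must
#' check it (total stall demand `(1 - q) P0` summed over species must stay
#' below `D0`, see [stall_demand()]).
#'
#' @param rates a [rate_set()].
#' @return The diced fraction `q` in \[0, 1\].
#' @export
#' @examples
#' closed_form_diced_fraction(dicing_rates_let7("wt")) # ~0.3029
closed_form_diced_fraction <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  num <- rates$k_a * rates$k_d
  den <- num + rates$k_c * (rates$k_b + rates$k_d)
  if (den == 0) {
    stop("diced fraction undefined: k_a*k_d + k_c*(k_b + k_d) is zero",
         call. = FALSE)
  }
  num / den
}

#' Total Dicer demand of the stalling sink
#'
#' Each pre-miRNA molecule that ends up stalled permanently sequesters one
#' Dicer. Summing the closed-form stalled fraction `(1 - q_i) P0_i` over
#' species gives the total Dicer consumed if the pool were unlimited; when
#' this demand is below `D0`, free Dicer is never exhausted and every
#' species attains its closed-form diced fraction.
#'
#' @param config a [system_config()].
#' @return Total stall demand in nM.
#' @export
stall_demand <- function(config) {
  stopifnot(inherits(config, "system_config"))
  sum(vapply(config$species, function(sp) {
    (1 - closed_form_diced_fraction(sp$rates)) * sp$P0
  }, numeric(1)))
}

#' Check conservation laws on a trajectory
#'
#' Per-species mass conservation (P + PD + S + M = P0) and, for a shared
#' pool, Dicer conservation (D + sum(PD_i + S_i) = D0) at every output
#' time.
#'
#' @param traj a `dicer_trajectory`.
#' @return Invisibly, a list with the maximum absolute violations
#'   `mass` and `dicer`.
#' @export
conservation_error <- function(traj) {
  stopifnot(inherits(traj, "dicer_trajectory"))
  config <- attr(traj, "config")
  P0 <- stats::setNames(config_P0(config), config_labels(config))
  tot <- traj$P + traj$PD + traj$S + traj$M
  mass <- max(abs(tot - P0[traj$species]))
  if (config$shared_dicer || length(config$species) == 1L) {
    bound <- tapply(traj$PD + traj$S, traj$time_s, sum)
    D <- tapply(traj$D, traj$time_s, `[`, 1L)
    dicer <- max(abs(D + bound - config$D0))
  } else {
    bysp <- split(traj, traj$species)
    dicer <- max(vapply(bysp, function(d) {
      max(abs(d$D + d$PD + d$S - config$D0))
    }, numeric(1)))
  }
  invisible(list(mass = mass, dicer = dicer))
}
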