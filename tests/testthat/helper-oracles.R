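# Independent test oracles. These deliberately re-derive results with
# their own arithmetic instead of calling package internals.

# Fixed-step RK4 integration of the mass-action system. km is an n x 4
# matrix with columns k_a, k_b, k_c, k_d.
rk4_final_state <- function(P0, D0, km, t_end, dt) {
  n <- length(P0)
  y <- c(P0, rep(0, 3L * n), D0)
  deriv <- function(y) {
    P <- y[1:n]; PD <- y[n + 1:n]; D <- y[4L * n + 1L]
    ka <- km[, 1L]; kb <- km[, 2L]; kc <- km[, 3L]; kd <- km[, 4L]
    c(kb * PD - (ka + kc) * P * D,
      ka * P * D - (kb + kd) * PD,
      kc * P * D,
      kd * PD,
      sum((kb + kd) * PD) - sum((ka + kc) * P * D))
  }
  for (s in seq_len(ceiling(t_end / dt))) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Exhaustive enumeration of all non-crossing inter-strand matchings of an
# antiparallel duplex, with unit weights on WC/GU pairs. Returns the
# bond-probability matrix in (seq5 position) x (seq3 position) order.
brute_force_bpp <- function(seq5, seq3) {
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  X <- strsplit(seq5, "")[[1L]]
  Yr <- rev(strsplit(seq3, "")[[1L]])
  m <- length(X); n <- length(Yr)
  count <- matrix(0, m, n); total <- 0
  rec <- function(i, minj, bonds) {
    if (i > m) {
      total <<- total + 1
      for (b in bonds) count[b[1L], b[2L]] <<- count[b[1L], b[2L]] + 1
      return(invisible())
    }
    rec(i + 1L, minj, bonds)
    if (minj <= n) {
      for (k in minj:n) {
        if (ok(X[i], Yr[k])) rec(i + 1L, k + 1L, c(bonds, list(c(i, k))))
      }
    }
  }
  rec(1L, 1L, list())
  (count / total)[, n:1, drop = FALSE]
}

# Closed-form OLS via the normal equations, with slope SE and Pearson r.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  r <- sxy / sqrt(sxx * syy)
  list(slope = slope, intercept = intercept, slope_se = se, r = r)
}

# random single- or multi-species config with moderate, non-stiff rates
random_config <- function(n_species = 1L, shared_dicer = TRUE,
                          rate_cap = c(0.5, 5, 0.5, 5)) {
  sp <- lapply(seq_len(n_species), function(i) {
    species_spec(paste0("s", i), stats::runif(1, 0.2, 3),
                 rate_set(stats::runif(1, 0.01, rate_cap[1L]),
                          stats::runif(1, 0, rate_cap[2L]),
                          stats::runif(1, 0.01, rate_cap[3L]),
                          stats::runif(1, 0.05, rate_cap[4L])))
  })
  system_config(sp, D0 = stats::runif(1, 0.5, 10),
                shared_dicer = shared_dicer)
}

wt_single_config <- function(P0 = 1, D0 = 5) {
  system_config(list(species_spec("let7", P0, dicing_rates_let7("wt"))),
                D0 = D0)
}

# association_result fixture from published-style summary numbers
fake_association <- function(slope, se, n = 44L) {
  structure(list(n = n, r = NA_real_, p = NA_real_, intercept = 0,
                 slope = slope, slope_se = se),
            class = "association_result")
}
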