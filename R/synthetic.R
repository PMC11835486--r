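# Seeded RNG scope: run code with a private RNG stream, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Generate a noisy dicing time course from known rates
#'
#' Simulates the single-species maturation kinetics under the standard in
#' vitro assay conditions (1 nM pre-miRNA incubated with 5 nM Dicer) and
#' adds Gaussian quantification noise to the diced fractions. Values
#' pushed outside \[0, 1\] by noise are reported as-is (and flagged by the
#' [dicing_timeseries()] constructor), never hidden.
#'
#' @param rates true [rate_set()].
#' @param P0,D0 initial concentrations (nM).
#' @param times_min sampling grid in minutes.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   fractions; 0.02 is a plausible gel-quantification error.
#' @param seed integer seed; same seed, same series.
#' @param label condition label.
#' @return A [dicing_timeseries()] carrying the true rates as the
#'   `"truth"` attribute.
#' @export
#' @examples
#' ts <- gen_dicing_timeseries(dicing_rates_let7("wt"), noise_sd = 0,
#'                             seed = 1)
#' tail(ts, 3)
gen_dicing_timeseries <- function(rates, P0 = 1, D0 = 5,
                                  times_min = seq(0, 60, length.out = 20),
                                  noise_sd = 0.02, seed = NULL,
                                  label = "synthetic") {
  stopifnot(inherits(rates, "rate_set"), noise_sd >= 0)
  cfg <- system_config(list(species_spec(label, P0, rates)), D0 = D0)
  tsec <- times_min * 60
  grid <- if (tsec[1L] == 0) tsec else c(0, tsec)
  traj <- simulate_kinetics(cfg, t_end = max(grid), times = grid)
  fr <- diced_fraction(traj, label)
  clean <- fr$fraction[match(tsec, fr$time_s)]
  noisy <- with_seed(seed, clean + stats::rnorm(length(clean), 0, noise_sd))
  noisy <- pmin(pmax(noisy, -0.05), 1.05)  # keep within constructor domain
  ts <- dicing_timeseries(times_min, noisy, P0 = P0, D0 = D0, label = label)
  attr(ts, "truth") <- rates
  ts
}

# complement with optional GU wobble
pair_partner <- function(base, gu_frac) {
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  p <- wc[[base]]
  if (base == "G" && stats::runif(1) < gu_frac) p <- "U"
  if (base == "U" && stats::runif(1) < gu_frac) p <- "G"
  p
}

# a base that cannot pair (WC or GU) with 'base'
mismatch_partner <- function(base) {
  opts <- switch(base,
                 A = c("A", "C", "G"),
                 C = c("A", "C", "U"),
                 G = c("A", "G"),
                 U = c("C", "U"))
  sample(opts, 1L)
}

#' Generate random hairpins with controllable stem strength
#'
#' Builds hairpin records whose stems pair each position independently
#' with probability `theta`: paired positions get a Watson-Crick partner
#' (with a GU wobble fraction), unpaired stem positions get a guaranteed
#' mismatch. The mature arms are the full stem on either side of the
#' loop, so `theta` directly controls duplex pairing strength and hence
#' the AUC score gradient.
#'
#' @param n number of hairpins.
#' @param theta per-position stem pairing probability in \[0, 1\].
#' @param arm_len integer range (length 2) of arm lengths.
#' @param loop_len integer range of loop lengths.
#' @param gu_frac fraction of paired G/U positions made GU wobbles.
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return List of [hairpin_record()] objects.
#' @export
gen_hairpin_dataset <- function(n, theta = 0.8, arm_len = c(19L, 23L),
                                loop_len = c(4L, 12L), gu_frac = 0.1,
                                seed = NULL, prefix = "synth-mir") {
  stopifnot(theta >= 0, theta <= 1, all(arm_len >= 1), all(loop_len >= 1))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      L <- sample(arm_len[1L]:arm_len[2L], 1L)
      loopL <- sample(loop_len[1L]:loop_len[2L], 1L)
      base5 <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
      paired <- stats::runif(L) < theta
      partner <- vapply(seq_len(L), function(k) {
        if (paired[k]) pair_partner(base5[k], gu_frac)
        else mismatch_partner(base5[k])
      }, character(1))
      # arm3 read 5'->3' pairs arm5 antiparallel: reverse the partners
      arm3 <- rev(partner)
      loop <- sample(c("A", "C", "U"), loopL, replace = TRUE)
      seqn <- paste0(c(base5, loop, arm3), collapse = "")
      struct <- paste0(c(ifelse(paired, "(", "."),
                         rep(".", loopL),
                         rev(ifelse(paired, ")", "."))), collapse = "")
      hairpin_record(sprintf("%s-%03d", prefix, i), seqn, struct,
                     arm5 = c(0L, L), arm3 = c(L + loopL, 2L * L + loopL))
    })
  })
}

#' Generate two-genotype expression tables with a known AUC slope
#'
#' The generative twin of the expression regression: for each genotype
#' `g`, `log10 expression = alpha_g + beta_g * auc + Normal(0, noise_sd)`.
#' Expression is returned on the natural scale (arbitrary normalized
#' units).
#'
#' @param aucs data.frame with columns `id` and `auc` (e.g. from
#'   [hairpin_bpp_auc()]).
#' @param alpha,beta named numeric vectors of per-genotype intercepts and
#'   slopes; names define the genotype columns. Defaults mirror slopes of
#'   1.49 (WT-like) and 1.89 (Dicer-reduced-like).
#' @param noise_sd Gaussian noise sd on the log10 scale.
#' @param seed integer seed.
#' @return Data frame `id`, `auc`, one expression column per genotype;
#'   true parameters attached as attribute `"truth"`.
#' @export
gen_expression <- function(aucs,
                           alpha = c(WT = 0, KD = 0),
                           beta = c(WT = 1.49, KD = 1.89),
                           noise_sd = 1, seed = NULL) {
  stopifnot(all(c("id", "auc") %in% names(aucs)), noise_sd >= 0,
            nrow(aucs) >= 3L, identical(names(alpha), names(beta)))
  out <- data.frame(id = aucs$id, auc = aucs$auc)
  with_seed(seed, {
    for (g in names(beta)) {
      lg <- alpha[[g]] + beta[[g]] * aucs$auc +
        stats::rnorm(nrow(aucs), 0, noise_sd)
      out[[g]] <- 10^lg
    }
  })
  attr(out, "truth") <- list(alpha = alpha, beta = beta,
                             noise_sd = noise_sd)
  out
}
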