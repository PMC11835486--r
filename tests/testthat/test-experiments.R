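test_that("competition panel scales exactly one rate per species", {
  panel <- competition_panel()
  expect_length(panel, 8L)
  labs <- vapply(panel, `[[`, character(1), "label")
  expect_identical(labs, c("ka_hi", "ka_2hi", "kb_hi", "kb_2hi",
                           "kc_hi", "kc_2hi", "kd_hi", "kd_2hi"))
  wt <- unlist(unclass(dicing_rates_let7("wt")))
  for (i in seq_along(panel)) {
    r <- unlist(unclass(panel[[i]]$rates))
    ratio <- r / wt
    expect_equal(sum(ratio != 1), 1L)
    expect_equal(unname(ratio[ratio != 1]), if (i %% 2 == 1) 10 else 20)
    expect_equal(panel[[i]]$P0, 1)
  }
})

test_that("competition never helps and vanishes when Dicer is abundant", {
  panel <- competition_panel()
  grid <- c(0.5, 1.55, 3, 8)
  shared <- dicer_sweep(panel, D_grid = grid, shared_dicer = TRUE)
  isolated <- dicer_sweep(panel, D_grid = grid, shared_dicer = FALSE)
  merged <- merge(shared, isolated, by = c("D0", "species"),
                  suffixes = c("_shared", "_iso"))
  # scarcity ordering: a shared pool can only take Dicer away
  expect_true(all(merged$M_shared <= merged$M_iso + 1e-6))
  # abundance limit at 8 nM (total stall demand ~5 nM)
  at8 <- merged[merged$D0 == 8, ]
  expect_lt(max(abs(at8$M_shared - at8$M_iso)), 1e-3)
  # and every species attains its closed-form isolated fraction there
  q <- vapply(panel, function(s) closed_form_diced_fraction(s$rates),
              numeric(1))
  names(q) <- vapply(panel, `[[`, character(1), "label")
  expect_lt(max(abs(at8$M_shared - q[at8$species])), 1e-3)
  # isolated simulation is definitionally 8 independent single runs
  one <- run_to_steady_state(
    system_config(panel[1L], D0 = 0.5, shared_dicer = TRUE))
  expect_equal(isolated$M[isolated$D0 == 0.5 &
                            isolated$species == "ka_hi"],
               unname(steady_mature(one)), tolerance = 1e-9)
  # scarcity bound: under 0.5 nM Dicer everyone is below isolated values
  at05 <- merged[merged$D0 == 0.5, ]
  expect_true(all(at05$M_shared <= at05$M_iso + 1e-6))
  expect_true(all(at05$M_shared <= 1))
})

test_that("fold change is a ratio against the reference grid point", {
  res <- structure(
    data.frame(D0 = rep(c(1, 8), each = 2),
               P0 = NA_real_,
               species = rep(c("a", "b"), 2),
               M = c(0.1, 0.3, 0.2, 0.6)),
    class = c("sweep_result", "data.frame"))
  fc <- fold_change(res, list(D0 = 8))
  expect_equal(fc$fold_change[fc$D0 == 8], c(1, 1))
  expect_equal(fc$fold_change[fc$D0 == 1], c(0.5, 0.5))

  # zero reference with a non-zero numerator is missing, never infinite
  res$M[res$D0 == 8 & res$species == "a"] <- 0
  fc2 <- fold_change(res, list(D0 = 8))
  expect_true(all(is.na(fc2$fold_change[fc2$species == "a"])))
  expect_error(fold_change(res, list(D0 = 3)), "not on the grid")
})

test_that("joint pre-miRNA/Dicer sweep is referenced to the abundant condition", {
  panel <- competition_panel()
  fc <- premirna_dicer_sweep(panel, P0_grid = c(0, 2.5, 5),
                             D_grid = c(1, 8, 15))
  ref <- fc[fc$P0 == 5 & fc$D0 == 15, ]
  expect_equal(ref$fold_change, rep(1, 8))
  expect_true(all(fc$fold_change[fc$P0 == 0] == 0))
  # fold change is non-decreasing in Dicer at fixed pre-miRNA load
  for (sp in unique(fc$species)) {
    for (p0 in c(2.5, 5)) {
      sub <- fc[fc$species == sp & fc$P0 == p0, ]
      sub <- sub[order(sub$D0), ]
      expect_true(all(diff(sub$fold_change) > -1e-6))
    }
  }
  # M never exceeds the species' initial concentration
  expect_true(all(fc$M <= fc$P0 + 1e-9))
})

test_that("minimum-Dicer thresholds are bracketed and ordered by competition", {
  panel <- competition_panel()
  iso <- min_dicer_for_fold_change(panel, threshold = 0.5,
                                   shared_dicer = FALSE, n_grid = 8L,
                                   tol = 1e-2)
  sh <- min_dicer_for_fold_change(panel, threshold = 0.5,
                                  shared_dicer = TRUE, n_grid = 8L,
                                  tol = 1e-2)
  # isolated pools need no more Dicer than competitive ones
  both <- merge(iso, sh, by = "species", suffixes = c("_iso", "_shared"))
  ok <- !is.na(both$min_dicer_iso) & !is.na(both$min_dicer_shared)
  expect_true(any(ok))
  expect_true(all(both$min_dicer_iso[ok] <=
                    both$min_dicer_shared[ok] + 2e-2))

  # a species that cannot mature never reaches the threshold
  dead <- list(species_spec("dead", 1,
                            rate_set(0, 0.1, 0.01, 1)),
               species_spec("live", 1, dicing_rates_let7("wt")))
  res <- min_dicer_for_fold_change(dead, threshold = 0.5,
                                   shared_dicer = FALSE, n_grid = 6L,
                                   tol = 1e-2)
  expect_true(is.na(res$min_dicer[res$species == "dead"]))
  expect_false(is.na(res$min_dicer[res$species == "live"]))
})

test_that("perturbation experiments reproduce the knockout/overexpression structure", {
  panel <- competition_panel()

  # sham perturbation: identical to baseline
  sham <- perturbation_experiment(panel, "kc_hi", level = 1)
  expect_equal(unname(sham), rep(1, 8), tolerance = 1e-6)

  ko <- perturbation_matrix(panel, level = 0)
  expect_equal(unname(diag(ko)), rep(0, 8))
  expect_true(all(ko >= 0))

  oe <- perturbation_matrix(panel, level = 5)
  expect_true(all(diag(oe) > 1))
  expect_true(all(oe >= 0))

  # with a shared pool, removing a competitor frees Dicer: nobody loses
  off_diag <- ko[row(ko) != col(ko)]
  expect_true(all(off_diag >= 1 - 1e-6))

  # without competition, knocking out one species leaves the others
  # exactly unchanged
  ko_iso <- perturbation_matrix(panel, level = 0, shared_dicer = FALSE)
  expect_equal(unname(ko_iso[row(ko_iso) != col(ko_iso)]),
               rep(1, 56), tolerance = 1e-9)
  expect_equal(unname(diag(ko_iso)), rep(0, 8))
})

test_that("steady states conserve total pre-miRNA across perturbations", {
  panel <- competition_panel()
  for (level in c(0, 5)) {
    pp <- panel
    pp[[3L]] <- species_spec("kb_hi", level, pp[[3L]]$rates)
    cfg <- system_config(pp, D0 = 1.55)
    ss <- run_to_steady_state(cfg)
    tot <- sum(ss$state$P + ss$state$PD + ss$state$S + ss$state$M)
    expect_equal(tot, sum(vapply(pp, `[[`, numeric(1), "P0")),
                 tolerance = 1e-6)
  }
})

test_that("single-species sweeps agree with the closed form when Dicer is ample", {
  wt <- dicing_rates_let7("wt")
  sw <- single_species_sweep(wt, "k_a", scale_grid = c(1, 100),
                             D0_grid = 5, P0_grid = 1)
  q1 <- closed_form_diced_fraction(wt)
  r100 <- unclass(wt); r100$k_a <- r100$k_a * 100
  q100 <- closed_form_diced_fraction(do.call(rate_set, r100))
  expect_equal(sw$M[sw$scale == 1], q1, tolerance = 1e-4)
  expect_equal(sw$M[sw$scale == 100], q100, tolerance = 1e-4)

  sw0 <- single_species_sweep(wt, "k_c", scale_grid = 1, D0_grid = c(1, 5),
                              P0_grid = 0)
  expect_true(all(sw0$M == 0))
  expect_error(single_species_sweep(wt, "k_z"), "must be one of")
})
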