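test_that("direction sampling: subspace, normalization, uniformity", {
  fx <- fx_modes()
  ms <- fx$modes

  d1 <- sample_direction(ms, fx$picked[1], seed = 3)
  expect_lt(min(max(abs(d1$vector - ms$vectors[, fx$picked[1]])),
                max(abs(d1$vector + ms$vectors[, fx$picked[1]]))), 1e-10)

  for (seed in 1:20) {
    d <- sample_direction(ms, fx$picked, seed = seed)
    expect_lt(abs(sqrt(sum(d$vector^2)) - 1), 1e-10)
  }

  W <- with_seed(99, t(vapply(seq_len(10000), function(i)
    sample_direction(ms, fx$picked)$mode_weights, numeric(4))))
  C <- crossprod(W) / nrow(W)
  expect_lt(max(abs(C - diag(4) * 0.25)), 0.05 * 0.25 * 4)  # within 5% of I/4
  expect_error(sample_direction(ms, c(1, fx$picked)), "zero-mode")
})

test_that("displace_along achieves the requested RMSD exactly", {
  fx <- fx_modes()
  sys <- fx_system()
  s <- sys$structure
  d <- sample_direction(fx$modes, fx$picked, seed = 8)
  expect_identical(coords(displace_along(s, d, 0)), coords(s))
  for (target in c(0.5, 1.0, 2.5)) {
    s2 <- displace_along(s, d, target)
    expect_equal(sqrt(mean(rowSums((coords(s2) - coords(s))^2))), target,
                 tolerance = 1e-9)
  }
  ## uniform translation on equal masses: every atom moves by the target
  n <- n_atoms(s)
  tvec <- rep(c(1, 0, 0) * sqrt(s$atoms$mass[1]), n)
  tdir <- amdenm:::new_direction(as.vector(t(matrix(tvec, ncol = 3, byrow = TRUE))))
  s3 <- displace_along(s, tdir, 1)
  shifts <- coords(s3) - coords(s)
  expect_equal(shifts[, 1], rep(1, n), tolerance = 1e-9)
  expect_equal(shifts[, 2:3], matrix(0, n, 2), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("diversity filter matches a brute-force re-implementation", {
  fx <- fx_modes()
  sys <- fx_system()
  cfg <- excitation_config()
  cands <- with_seed(5, lapply(1:200, function(i)
    sample_direction(fx$modes, fx$picked, id = i)))

  expect_true(diversity_filter(cands[[1]], list(), sys$structure, cfg))
  expect_false(diversity_filter(cands[[1]], list(cands[[1]]), sys$structure, cfg))

  ## brute force: displaced coordinates computed independently per direction
  disp <- lapply(cands, function(d)
    coords(displace_along(sys$structure, d, cfg$filter_displacement)))
  acc_bf <- integer(0)
  for (i in seq_along(cands)) {
    ok <- TRUE
    for (j in acc_bf)
      if (sqrt(mean(rowSums((disp[[i]] - disp[[j]])^2))) <= cfg$filter_rmsd_min) {
        ok <- FALSE; break
      }
    if (ok) acc_bf <- c(acc_bf, i)
  }
  acc <- list(); acc_idx <- integer(0)
  for (i in seq_along(cands)) {
    if (diversity_filter(cands[[i]], acc, sys$structure, cfg)) {
      acc[[length(acc) + 1L]] <- cands[[i]]
      acc_idx <- c(acc_idx, i)
    }
  }
  expect_identical(acc_idx, acc_bf)
})

test_that("kinetic-energy injection is exact and has the closed-form speed", {
  fx <- fx_modes()
  sys <- fx_system()
  m <- sys$params$mass
  d <- sample_direction(fx$modes, fx$picked, seed = 12)

  st0 <- dynamics_state(coords(sys$structure),
                        init_velocities(m, 300, seed = 4))
  expect_identical(inject_kinetic_energy(st0, d, 0, m)$velocities,
                   st0$velocities)
  for (dE in c(0.5, 1.25, 4)) {
    st1 <- inject_kinetic_energy(st0, d, dE, m)
    dke <- kinetic_energy(st1$velocities, m) - kinetic_energy(st0$velocities, m)
    expect_lt(abs(dke - dE) / dE, 1e-9)
  }
  ## from rest: mass-weighted speed sqrt(2 dE) in AKMA energy units
  str <- dynamics_state(coords(sys$structure))
  st2 <- inject_kinetic_energy(str, d, 1.25, m)
  p <- sqrt(sum((st2$velocities * sqrt(m))^2))
  expect_equal(p, sqrt(2 * 1.25 * KCALMOL_TO_AKMA), tolerance = 1e-9)
})

test_that("excitation cycle: null perturbation, duration, forward bias", {
  fx <- fx_diatomic(k = 100, r0 = 3)
  dvec <- c(-1, 0, 0, 1, 0, 0) / sqrt(2)
  d <- amdenm:::new_direction(dvec)
  cfg <- excitation_config(delta_E = 0, temperature = 1e-12, friction = 0,
                           n_excitations = 1)
  st <- dynamics_state(coords(fx$structure), temperature_target = 1e-12,
                       friction = 0)
  rep0 <- amdenm:::new_replica(d, coords(fx$structure))
  out <- run_excitation_cycle(fx$params, st, rep0, cfg)
  expect_equal(out$replica$conformations[[1]], coords(fx$structure),
               tolerance = 1e-12)
  ## segment duration: (frames - 1) * frame dt = t_exc
  expect_equal((n_frames(out$segment) - 1) * out$segment$dt, cfg$t_exc)

  ## injection biases motion along the direction (sign test over 50 cycles)
  sys <- fx_system()
  ms <- fx_modes()
  dirn <- sample_direction(ms$modes, ms$picked, seed = 2)
  cfg2 <- excitation_config(n_excitations = 50)
  st2 <- dynamics_state(coords(sys$structure),
                        init_velocities(sys$params$mass, 300, seed = 6),
                        temperature_target = 300, friction = 1)
  rep2 <- run_replica(sys$params, st2, dirn, cfg2, seed = 31)
  expect_gt(mean(rep2$log$projection), 0)
  ## energy bookkeeping invariant: every injection exact
  expect_true(all(abs(rep2$log$delta_ke - cfg2$delta_E) / cfg2$delta_E < 1e-9))
})

test_that("adaptation triggers exactly on the displacement AND angle rule", {
  cfg <- excitation_config()
  cases <- list(list(proj = 0.6, ang = 75, want = TRUE),
                list(proj = 0.6, ang = 45, want = FALSE),
                list(proj = 0.4, ang = 75, want = FALSE),
                list(proj = 0.5, ang = 60.0001, want = TRUE),  # >= 0.5 and > 60
                list(proj = 0.5, ang = 60, want = FALSE),
                list(proj = 0.4999, ang = 179, want = FALSE))
  for (cs in cases) {
    rep <- fx_replica_history(cs$proj, cs$ang)
    out <- maybe_update_direction(rep, cfg, rep(110, 4))
    expect_identical(out$updated, cs$want)
    if (cs$want) {
      expect_equal(out$replica$update_count, 1L)
      expect_lt(abs(sqrt(sum(out$replica$current_direction$vector^2)) - 1), 1e-10)
      expect_equal(out$replica$segment_start_coords, rep$conformations[[1]])
    }
  }
  bare <- amdenm:::new_replica(amdenm:::new_direction(c(1, rep(0, 11))),
                               matrix(0, 4, 3))
  expect_error(maybe_update_direction(bare, cfg, rep(110, 4)), "state error")
})

test_that("adaptation never triggers when the angle bound is maximal", {
  sys <- fx_system()
  ms <- fx_modes()
  dirn <- sample_direction(ms$modes, ms$picked, seed = 9)
  cfg <- excitation_config(n_excitations = 10, adapt_max_angle = 179.999)
  st <- dynamics_state(coords(sys$structure),
                       init_velocities(sys$params$mass, 300, seed = 1),
                       temperature_target = 300, friction = 1)
  rep <- run_replica(sys$params, st, dirn, cfg, seed = 7)
  expect_identical(rep$update_count, 0L)
})

test_that("replicas store one conformation per excitation, deterministically", {
  sys <- fx_system()
  ms <- fx_modes()
  dirn <- sample_direction(ms$modes, ms$picked, seed = 14)
  st <- dynamics_state(coords(sys$structure),
                       init_velocities(sys$params$mass, 300, seed = 2),
                       temperature_target = 300, friction = 1)
  cfg1 <- excitation_config(n_excitations = 1)
  r1 <- run_replica(sys$params, st, dirn, cfg1, seed = 5)
  expect_length(r1$conformations, 1)

  cfg5 <- excitation_config(n_excitations = 5)
  ra <- run_replica(sys$params, st, dirn, cfg5, seed = 6)
  rb <- run_replica(sys$params, st, dirn, cfg5, seed = 6)
  expect_length(ra$conformations, 5)
  expect_identical(ra$conformations, rb$conformations)
  expect_identical(ra$log, rb$log)
})

test_that("campaigns: counting identity, pairwise re-verification, saturation", {
  sys <- fx_system()
  ms <- fx_modes()
  cfg <- excitation_config(n_excitations = 2)
  camp <- run_campaign(sys$params, sys$structure, ms$modes, ms$picked,
                       n_replicas = 3, config = cfg, seed = 21)
  expect_equal(camp$total_conformations, 3 * 2)
  expect_length(campaign_trajectory(camp)$coords[, 1, 1], 6)

  ## every accepted pair satisfies the displaced-RMSD criterion (brute force)
  disp <- lapply(camp$directions, function(d)
    coords(displace_along(sys$structure, d, cfg$filter_displacement)))
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(sqrt(mean(rowSums((disp[[i]] - disp[[j]])^2))),
              cfg$filter_rmsd_min)

  ## minimal campaign
  c1 <- run_campaign(sys$params, sys$structure, ms$modes, ms$picked,
                     n_replicas = 1, config = excitation_config(n_excitations = 1),
                     seed = 3)
  expect_equal(c1$total_conformations, 1)

  ## one-mode subspace saturates: only +/- one direction exists
  cfg_sat <- excitation_config(n_excitations = 1, candidate_cap_factor = 10L)
  expect_error(run_campaign(sys$params, sys$structure, ms$modes, ms$picked[1],
                            n_replicas = 5, config = cfg_sat, seed = 2),
               "saturation")
})
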