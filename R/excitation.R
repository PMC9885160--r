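#' Excitation-protocol configuration
#'
#' Holds every numeric parameter of the excitation method: the kinetic
#' energy injected per excitation, the length of each excitation segment,
#' the number of excitations per replica, the diversity filter's
#' displacement amplitude and minimum pairwise RMSD, and the adaptive
#' direction-update thresholds.
#'
#' @param delta_E Kinetic-energy injection per excitation, kcal/mol
#'   (default 1.25).
#' @param t_exc Excitation segment length, ps (default 0.2).
#' @param n_excitations Excitations per replica (default 200).
#' @param filter_displacement Displacement amplitude used by the diversity
#'   filter, Angstrom RMSD (default 1.0).
#' @param filter_rmsd_min Minimum displaced-structure RMSD between accepted
#'   directions, Angstrom (default 1.15).
#' @param adapt_min_displacement Minimum projected displacement that arms
#'   the direction update, Angstrom (default 0.5).
#' @param adapt_max_angle Angle (degrees, in (0, 180)) beyond which the
#'   effective displacement counts as deviated (default 60).
#' @param dt Integrator time step, ps (default 0.002).
#' @param temperature Thermostat target during segments, K.
#' @param friction Langevin damping, 1/ps.
#' @param segment_stride Frame stride within a segment used for the
#'   segment-average position (default 1 = every step).
#' @param candidate_cap_factor Campaign draws at most
#'   `candidate_cap_factor * n_replicas` candidates before raising a
#'   saturation error (default 100).
#' @return Object of class `excitation_config`.
#' @export
excitation_config <- function(delta_E = 1.25, t_exc = 0.2,
                              n_excitations = 200,
                              filter_displacement = 1.0,
                              filter_rmsd_min = 1.15,
                              adapt_min_displacement = 0.5,
                              adapt_max_angle = 60,
                              dt = 0.002, temperature = 300, friction = 1,
                              segment_stride = 1L,
                              candidate_cap_factor = 100L) {
  if (delta_E < 0) stop("delta_E must be >= 0")
  if (any(c(t_exc, n_excitations, filter_displacement, filter_rmsd_min,
            adapt_min_displacement, dt) <= 0))
    stop("config values must be positive")
  if (adapt_max_angle <= 0 || adapt_max_angle >= 180)
    stop("adapt_max_angle must be in (0, 180)")
  structure(list(delta_E = delta_E, t_exc = t_exc,
                 n_excitations = as.integer(n_excitations),
                 filter_displacement = filter_displacement,
                 filter_rmsd_min = filter_rmsd_min,
                 adapt_min_displacement = adapt_min_displacement,
                 adapt_max_angle = adapt_max_angle,
                 dt = dt, temperature = temperature, friction = friction,
                 segment_stride = as.integer(segment_stride),
                 candidate_cap_factor = as.integer(candidate_cap_factor)),
            class = "excitation_config")
}

new_direction <- function(vector, mode_weights = NULL, id = NA) {
  nrm <- sqrt(sum(vector^2))
  if (nrm < 1e-300) stop("domain error: zero direction")
  structure(list(vector = vector / nrm, mode_weights = mode_weights, id = id),
            class = "excitation_direction")
}

#' Sample a random excitation direction from selected modes
#'
#' Mode-combination weights are drawn uniformly on the unit hypersphere of
#' the selected-mode subspace (sign included).  Because the eigenvectors
#' are orthonormal in the mass-weighted metric, the resulting direction is
#' unit-norm in that metric.
#'
#' @param modes A mode set from [diagonalize_hessian()].
#' @param mode_indices Indices of the modes to combine; must all be
#'   nonzero modes.
#' @param seed Optional integer seed; default uses the caller's RNG stream.
#' @param id Optional identifier stored on the direction.
#' @return An `excitation_direction` (field `vector` is the mass-weighted
#'   3N direction, unit norm; `mode_weights` the drawn coefficients).
#' @export
sample_direction <- function(modes, mode_indices, seed = NULL, id = NA) {
  mode_indices <- as.integer(mode_indices)
  if (length(mode_indices) == 0) stop("mode_indices must be nonempty")
  if (any(mode_indices <= modes$n_zero))
    stop("validation error: zero-mode index supplied")
  with_seed(seed, {
    w <- stats::rnorm(length(mode_indices))
    w <- w / sqrt(sum(w^2))
    v <- as.vector(modes$vectors[, mode_indices, drop = FALSE] %*% w)
    new_direction(v, mode_weights = w, id = id)
  })
}

## Cartesian displacement field of a mass-weighted direction, scaled so a
## displacement of amplitude t has coordinate RMSD exactly t (unfitted).
unit_rmsd_displacement <- function(direction, masses) {
  d <- matrix(direction$vector, ncol = 3, byrow = TRUE) / sqrt(masses)
  d / sqrt(mean(rowSums(d^2)))
}

#' Displace a structure along an excitation direction
#'
#' The mass-weighted direction is converted to Cartesian displacements
#' (divide by \eqn{\sqrt{m_i}}) and scaled so the unfitted all-atom RMSD
#' between input and output equals `target_rmsd`.
#'
#' @param structure An [md_structure()].
#' @param direction An `excitation_direction`.
#' @param target_rmsd Displacement amplitude, Angstrom RMSD (>= 0).
#' @return Displaced [md_structure()].
#' @export
displace_along <- function(structure, direction, target_rmsd) {
  if (target_rmsd < 0) stop("domain error: target_rmsd must be >= 0")
  if (target_rmsd == 0) return(structure)
  d <- unit_rmsd_displacement(direction, structure$atoms$mass)
  coords(structure) <- coords(structure) + target_rmsd * d
  structure
}

#' Sequential direction-diversity filter
#'
#' Displaces the reference structure by `config$filter_displacement` along
#' the candidate and along every previously accepted direction; the
#' candidate is accepted iff the minimum unfitted RMSD between its
#' displaced structure and every accepted displaced structure exceeds
#' `config$filter_rmsd_min`.  An empty accepted list accepts vacuously.
#'
#' @param candidate An `excitation_direction`.
#' @param accepted List of accepted `excitation_direction`s (may be empty).
#' @param structure Reference [md_structure()].
#' @param config An [excitation_config()].
#' @return Logical: accept?
#' @export
diversity_filter <- function(candidate, accepted, structure, config) {
  if (length(accepted) == 0) return(TRUE)
  m <- structure$atoms$mass
  amp <- config$filter_displacement
  dc <- amp * unit_rmsd_displacement(candidate, m)
  for (a in accepted) {
    da <- amp * unit_rmsd_displacement(a, m)
    if (sqrt(mean(rowSums((dc - da)^2))) <= config$filter_rmsd_min)
      return(FALSE)
  }
  TRUE
}

#' Inject kinetic energy along a direction
#'
#' Adds a velocity increment along the direction (additive, positive-root
#' convention): with mass-weighted momenta \eqn{p_i = \sqrt{m_i} v_i} and
#' unit direction \eqn{q}, the increment \eqn{\delta q} solves
#' \eqn{\tfrac12\delta^2 + (p\cdot q)\,\delta = \Delta E} with the positive
#' root, so the kinetic-energy gain equals `delta_E` exactly.
#'
#' @param state A [dynamics_state()].
#' @param direction An `excitation_direction` (mass-weighted).
#' @param delta_E Energy to inject, kcal/mol (>= 0).
#' @param masses Per-atom masses, amu.
#' @return Updated [dynamics_state()].
#' @export
inject_kinetic_energy <- function(state, direction, delta_E, masses) {
  if (delta_E < 0) stop("delta_E must be >= 0")
  if (delta_E == 0) return(state)
  q <- direction$vector
  sm <- sqrt(masses)
  p <- as.vector(t(state$velocities * sm))      # mass-weighted, 3N ordering
  b <- sum(p * q)
  disc <- b^2 + 2 * delta_E * KCALMOL_TO_AKMA
  if (disc < 0) stop("internal error: no real root for injection")
  delta <- -b + sqrt(disc)
  dv <- matrix(delta * q, ncol = 3, byrow = TRUE) / sm
  state$velocities <- state$velocities + dv
  state
}

new_replica <- function(direction, start_coords, id = NA) {
  structure(list(current_direction = direction,
                 segment_start_coords = start_coords,
                 excitation_count = 0L, update_count = 0L,
                 conformations = list(),
                 last_segment_mean = NULL,
                 last_projection = NA_real_, last_angle = NA_real_,
                 log = NULL, id = id),
            class = "replica_state")
}

#' One excitation-relaxation cycle
#'
#' Injects `config$delta_E` along the replica's current direction, runs
#' `t_exc` of Langevin dynamics, stores the end-of-segment conformation and
#' records the displacement bookkeeping used by the adaptive update: the
#' net displacement is measured from `segment_start_coords` (which only
#' resets when the direction is updated); its projection onto the
#' direction is the "theoretical" displaced distance (Angstrom, RMSD
#' scale), and the angle between the net displacement and the direction is
#' the deviation of the effective from the theoretical displacement.
#'
#' @param params [force_field_params()].
#' @param state Current [dynamics_state()].
#' @param replica A replica state (from [run_replica()] internals).
#' @param config [excitation_config()].
#' @return List: `state`, `replica`, `segment` (the segment trajectory).
#' @export
run_excitation_cycle <- function(params, state, replica, config) {
  m <- params$mass
  ke0 <- kinetic_energy(state$velocities, m)
  state <- inject_kinetic_energy(state, replica$current_direction,
                                 config$delta_E, m)
  ke1 <- kinetic_energy(state$velocities, m)

  n_steps <- max(1L, round(config$t_exc / config$dt))
  seg <- run_langevin(params, state, n_steps = n_steps, dt = config$dt,
                      stride = config$segment_stride)
  state <- seg$state
  x_end <- state$coordinates
  seg_mean <- apply(seg$trajectory$coords, c(2, 3), mean)

  d <- unit_rmsd_displacement(replica$current_direction, m)
  dx <- x_end - replica$segment_start_coords
  n <- nrow(dx)
  proj <- sum(dx * d) / n                       # |d|^2 = n (unit RMSD scale)
  nrm_dx <- sqrt(sum(dx^2)); nrm_d <- sqrt(sum(d^2))
  ang <- if (nrm_dx < 1e-12) NA_real_ else
    acos(clamp(sum(dx * d) / (nrm_dx * nrm_d), -1, 1)) * 180 / pi

  replica$excitation_count <- replica$excitation_count + 1L
  replica$conformations[[replica$excitation_count]] <- x_end
  replica$last_segment_mean <- seg_mean
  replica$last_projection <- proj
  replica$last_angle <- ang
  replica$log <- rbind(replica$log, data.frame(
    cycle = replica$excitation_count, ke_before = ke0, ke_after = ke1,
    delta_ke = ke1 - ke0, projection = proj, angle_deg = ang,
    updated = FALSE))
  list(state = state, replica = replica, segment = seg$trajectory)
}

#' Adaptive direction update check
#'
#' The direction is updated iff the projected displacement since the
#' segment anchor is at least `adapt_min_displacement` AND the effective
#' displacement deviates from the theoretical one by more than
#' `adapt_max_angle`.  The new direction is the (mass-weighted,
#' normalized) difference between the average position over the last
#' segment and the anchor position; the anchor then resets to the current
#' coordinates.
#'
#' @param replica Replica state with at least one completed cycle.
#' @param config [excitation_config()].
#' @param masses Per-atom masses, amu.
#' @return List: `replica`, `updated` (logical).
#' @export
maybe_update_direction <- function(replica, config, masses) {
  if (replica$excitation_count < 1L || is.null(replica$last_segment_mean))
    stop("state error: no displacement history recorded")
  proj <- replica$last_projection
  ang <- replica$last_angle
  trig <- is.finite(proj) && is.finite(ang) &&
    proj >= config$adapt_min_displacement && ang > config$adapt_max_angle
  if (!trig) return(list(replica = replica, updated = FALSE))
  dx <- replica$last_segment_mean - replica$segment_start_coords
  vmw <- as.vector(t(dx * sqrt(masses)))
  replica$current_direction <- new_direction(vmw, id = replica$id)
  replica$segment_start_coords <-
    replica$conformations[[replica$excitation_count]]
  replica$update_count <- replica$update_count + 1L
  replica$log$updated[nrow(replica$log)] <- TRUE
  list(replica = replica, updated = TRUE)
}

#' Run one excitation replica
#'
#' `n_excitations` excitation-relaxation cycles with an adaptation check
#' after every cycle.  Deterministic under a fixed seed.
#'
#' @param params [force_field_params()].
#' @param start A [dynamics_state()] giving the replica's starting
#'   coordinates and velocities.
#' @param direction Initial `excitation_direction` (normally one that
#'   passed the diversity filter).
#' @param config [excitation_config()].
#' @param seed Integer seed.
#' @return Completed replica state: `conformations` (one N x 3 matrix per
#'   excitation), `log` (per-cycle injections, projections, angles,
#'   updates), `update_count`.
#' @export
run_replica <- function(params, start, direction, config, seed = NULL) {
  replica <- new_replica(direction, start$coordinates, id = direction$id)
  state <- start
  with_seed(seed, {
    for (cyc in seq_len(config$n_excitations)) {
      res <- tryCatch(
        run_excitation_cycle(params, state, replica, config),
        error = function(e)
          stop(sprintf("replica %s cycle %d: %s", replica$id, cyc,
                       conditionMessage(e)), call. = FALSE))
      state <- res$state
      replica <- res$replica
      replica <- maybe_update_direction(replica, config, params$mass)$replica
    }
  })
  replica$final_state <- state
  replica
}

#' Run an excitation campaign
#'
#' Draws candidate directions from the selected modes, filters them
#' sequentially for diversity until `n_replicas` are accepted (with a cap
#' of `candidate_cap_factor * n_replicas` draws), then runs each replica.
#' With `dry_run = TRUE` no directions are sampled and no dynamics is run:
#' the driver only performs the campaign bookkeeping (replica and
#' conformation counting), which makes production-scale accounting
#' testable in seconds.
#'
#' @param params [force_field_params()] (ignored in a dry run).
#' @param structure Reference [md_structure()].
#' @param modes Mode set (ignored in a dry run).
#' @param mode_indices Modes to combine (ignored in a dry run).
#' @param n_replicas Number of replicas (>= 1).
#' @param config [excitation_config()].
#' @param seed Integer master seed; per-replica seeds are derived from it.
#' @param start Optional [dynamics_state()]; default zero velocities at the
#'   structure's coordinates.
#' @param dry_run Logical: bookkeeping only.
#' @return Object of class `campaign_result`: `replicas`, `directions`,
#'   `total_conformations`, `n_candidates_drawn`, `config`.
#' @export
run_campaign <- function(params, structure, modes, mode_indices,
                         n_replicas, config = excitation_config(),
                         seed = 1, start = NULL, dry_run = FALSE) {
  stopifnot(n_replicas >= 1)
  if (dry_run) {
    replicas <- lapply(seq_len(n_replicas), function(i)
      list(id = i, n_conformations = config$n_excitations))
    out <- list(replicas = replicas, directions = NULL,
                total_conformations = as.integer(n_replicas) * config$n_excitations,
                n_candidates_drawn = 0L, config = config, dry_run = TRUE)
    class(out) <- "campaign_result"
    return(out)
  }
  cap <- config$candidate_cap_factor * n_replicas
  accepted <- list()
  drawn <- 0L
  with_seed(seed, {
    while (length(accepted) < n_replicas) {
      if (drawn >= cap)
        stop(sprintf("saturation error: %d/%d directions accepted after %d draws (acceptance rate %.2f)",
                     length(accepted), n_replicas, drawn,
                     length(accepted) / drawn))
      drawn <- drawn + 1L
      cand <- sample_direction(modes, mode_indices, id = length(accepted) + 1L)
      if (diversity_filter(cand, accepted, structure, config))
        accepted[[length(accepted) + 1L]] <- cand
    }
  })
  start <- start %||% dynamics_state(coords(structure),
                                     temperature_target = config$temperature,
                                     friction = config$friction)
  replicas <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    replicas[[r]] <- run_replica(params, start, accepted[[r]], config,
                                 seed = derive_seed(seed, r))
  }
  total <- sum(vapply(replicas, function(x) x$excitation_count, integer(1)))
  out <- list(replicas = replicas, directions = accepted,
              total_conformations = total, n_candidates_drawn = drawn,
              config = config, dry_run = FALSE)
  class(out) <- "campaign_result"
  out
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("<campaign_result> %d replicas, %d conformations%s\n",
              length(x$replicas), x$total_conformations,
              if (isTRUE(x$dry_run)) " (dry run)" else ""))
  invisible(x)
}

#' Diversity-filter audit: minimum pairwise displaced-structure RMSD
#'
#' Draws `n_candidates` random directions from the selected modes, runs the
#' sequential diversity filter, displaces the reference structure by
#' `config$filter_displacement` along every accepted direction, and returns
#' the minimum pairwise RMSD over all accepted pairs — the quantity the
#' filter is designed to bound from below.
#'
#' @param structure Reference [md_structure()].
#' @param modes Mode set.
#' @param mode_indices Modes to combine.
#' @param n_candidates Number of candidate directions to draw.
#' @param config [excitation_config()].
#' @param seed Integer seed.
#' @return List: `min_pairwise_rmsd` (Angstrom), `n_accepted`,
#'   `n_candidates`.
#' @export
diversity_min_pairwise_rmsd <- function(structure, modes, mode_indices,
                                        n_candidates = 500,
                                        config = excitation_config(),
                                        seed = 1) {
  accepted <- list()
  with_seed(seed, {
    for (i in seq_len(n_candidates)) {
      cand <- sample_direction(modes, mode_indices, id = i)
      if (diversity_filter(cand, accepted, structure, config))
        accepted[[length(accepted) + 1L]] <- cand
    }
  })
  k <- length(accepted)
  if (k < 2) stop("fewer than two accepted directions; cannot form pairs")
  disp <- lapply(accepted, function(d)
    coords(displace_along(structure, d, config$filter_displacement)))
  mn <- Inf
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    mn <- min(mn, sqrt(mean(rowSums((disp[[i]] - disp[[j]])^2))))
  list(min_pairwise_rmsd = mn, n_accepted = k, n_candidates = n_candidates)
}

#' Stack campaign conformations into a trajectory
#'
#' @param campaign A (non-dry) `campaign_result`.
#' @param dt Nominal frame spacing to record, ps.
#' @return An [md_trajectory()] of all stored conformations, replicas
#'   concatenated in order.
#' @export
campaign_trajectory <- function(campaign, dt = NULL) {
  stopifnot(inherits(campaign, "campaign_result"), !isTRUE(campaign$dry_run))
  frames <- unlist(lapply(campaign$replicas, function(r) r$conformations),
                   recursive = FALSE)
  md_trajectory(frames, dt = dt %||% campaign$config$t_exc)
}
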