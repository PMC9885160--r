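#' Staged minimization schedule
#'
#' A list of stages, each a method (`"sd"` steepest descent or `"cg"`
#' conjugate gradient), a step count and a harmonic positional restraint
#' constant applied toward the input coordinates (CHARMM convention,
#' `k |x - x0|^2`; `k = 0` means unrestrained).
#'
#' @param stages List of lists with fields `method`, `steps`, `restraint_k`.
#' @return Object of class `minimization_schedule`.
#' @export
minimization_schedule <- function(stages) {
  for (st in stages) {
    stopifnot(st$method %in% c("sd", "cg"), st$steps > 0, st$restraint_k >= 0)
  }
  structure(list(stages = stages), class = "minimization_schedule")
}

#' The default restrained minimization ladder
#'
#' Steepest descent with the positional restraint constant stepped down
#' 10, 1, 0.1 kcal/mol/A^2 every 500 steps, then 200 conjugate-gradient
#' steps at 0.1, then a short unrestrained stage (100 sd + 200 cg).
#'
#' @param sd_steps,cg_steps Steps per restrained sd stage and for the
#'   restrained cg stage.
#' @return A [minimization_schedule()].
#' @export
default_minimization_schedule <- function(sd_steps = 500, cg_steps = 200) {
  minimization_schedule(list(
    list(method = "sd", steps = sd_steps, restraint_k = 10),
    list(method = "sd", steps = sd_steps, restraint_k = 1),
    list(method = "sd", steps = sd_steps, restraint_k = 0.1),
    list(method = "cg", steps = cg_steps, restraint_k = 0.1),
    list(method = "sd", steps = 100, restraint_k = 0),
    list(method = "cg", steps = cg_steps, restraint_k = 0)
  ))
}

#' Staged energy minimization with positional restraints
#'
#' Runs the schedule's stages in order.  Restraints act toward the input
#' coordinates.  Steepest descent uses a backtracking step (energy is
#' non-increasing within an sd stage); conjugate gradient delegates to
#' [stats::optim()] (method "CG").
#'
#' @param params [force_field_params()].
#' @param xyz Starting N x 3 coordinates.
#' @param schedule A [minimization_schedule()]; default the restrained
#'   ladder of [default_minimization_schedule()].
#' @return List: `coordinates` (final N x 3), `log` (data.frame with one
#'   row per stage: method, steps, restraint_k, start/end energy).
#' @export
minimize_energy <- function(params, xyz,
                            schedule = default_minimization_schedule()) {
  stopifnot(inherits(schedule, "minimization_schedule"))
  x <- as.matrix(xyz)
  ref <- x
  n <- nrow(x)
  log <- NULL
  for (si in seq_along(schedule$stages)) {
    st <- schedule$stages[[si]]
    p <- params
    p$restraint <- if (st$restraint_k > 0) list(k = st$restraint_k, ref = ref) else NULL
    e0 <- potential_energy(p, x)$total
    if (!is.finite(e0))
      stop(sprintf("divergence error: non-finite energy entering stage %d", si))
    if (st$method == "sd") {
      alpha <- 1e-3
      pe <- potential_energy(p, x)
      for (step in seq_len(st$steps)) {
        g <- -pe$forces
        xn <- x - alpha * g
        pen <- potential_energy(p, xn)
        if (!is.finite(pen$total))
          stop(sprintf("divergence error: stage %d step %d", si, step))
        if (pen$total <= pe$total) {
          x <- xn; pe <- pen; alpha <- alpha * 1.2
        } else {
          alpha <- alpha / 2
          if (alpha < 1e-12) break
        }
      }
      e1 <- pe$total
    } else {
      fn <- function(v) potential_energy(p, matrix(v, n, 3))$total
      gr <- function(v) -as.vector(potential_energy(p, matrix(v, n, 3))$forces)
      opt <- stats::optim(as.vector(x), fn, gr, method = "CG",
                          control = list(maxit = st$steps))
      if (opt$value <= e0) x <- matrix(opt$par, n, 3)
      e1 <- min(opt$value, e0)
    }
    log <- rbind(log, data.frame(stage = si, method = st$method,
                                 steps = st$steps, restraint_k = st$restraint_k,
                                 energy_start = e0, energy_end = e1))
  }
  list(coordinates = x, log = log)
}

#' Dynamics state
#'
#' @param coordinates N x 3 matrix, Angstrom.
#' @param velocities N x 3 matrix, Angstrom/ps; default zeros.
#' @param time Elapsed time, ps.
#' @param temperature_target Thermostat target, K.
#' @param friction Langevin damping coefficient, 1/ps.
#' @return Object of class `dynamics_state`.
#' @export
dynamics_state <- function(coordinates, velocities = NULL, time = 0,
                           temperature_target = 300, friction = 1) {
  coordinates <- as.matrix(coordinates)
  if (is.null(velocities)) velocities <- matrix(0, nrow(coordinates), 3)
  velocities <- as.matrix(velocities)
  stopifnot(all(dim(coordinates) == dim(velocities)),
            all(is.finite(coordinates)), all(is.finite(velocities)),
            friction >= 0)
  structure(list(coordinates = coordinates, velocities = velocities,
                 time = time, temperature_target = temperature_target,
                 friction = friction),
            class = "dynamics_state")
}

#' Draw Maxwell-Boltzmann velocities
#' @param masses Per-atom masses, amu.
#' @param temperature K.
#' @param seed Optional integer seed.
#' @return N x 3 velocity matrix, Angstrom/ps.
#' @export
init_velocities <- function(masses, temperature, seed = NULL) {
  n <- length(masses)
  sd <- sqrt(KB_KCALMOL * temperature * KCALMOL_TO_AKMA / masses)
  with_seed(seed, matrix(stats::rnorm(3 * n, sd = rep(sd, 3)), ncol = 3))
}

#' Langevin dynamics (BAOAB discretization)
#'
#' The BAOAB splitting of the Langevin equation; with `friction = 0` the
#' noise term vanishes and the scheme reduces to velocity Verlet, so NVE
#' runs use the same entry point.  Deterministic under a fixed seed.
#'
#' @param params [force_field_params()].
#' @param state A [dynamics_state()].
#' @param n_steps Number of integration steps.
#' @param dt Time step, ps (default 0.002 ps = 2 fs).
#' @param seed Optional integer seed for the thermostat noise.
#' @param stride Save a frame every `stride` steps (frame 1 is the initial
#'   state).
#' @return List: `trajectory` (an [md_trajectory()]) and `state` (final
#'   [dynamics_state()]).
#' @export
run_langevin <- function(params, state, n_steps, dt = 0.002, seed = NULL,
                         stride = 10L) {
  stopifnot(inherits(state, "dynamics_state"), dt > 0, n_steps >= 1)
  m <- params$mass
  x <- state$coordinates
  v <- state$velocities
  gam <- state$friction
  kT <- KB_KCALMOL * state$temperature_target * KCALMOL_TO_AKMA
  c1 <- exp(-gam * dt)
  c2 <- sqrt((1 - c1^2) * kT / m)        # per-atom noise sd, A/ps
  n <- nrow(x)
  inv_m <- KCALMOL_TO_AKMA / m           # converts kcal/mol/A to A/ps^2 per amu

  n_saved <- floor(n_steps / stride) + 1L
  arr <- array(NA_real_, dim = c(n_saved, n, 3))
  arr[1, , ] <- x
  fi <- 1L

  with_seed(seed, {
    Fc <- potential_energy(params, x)$forces
    for (step in seq_len(n_steps)) {
      v <- v + (0.5 * dt * inv_m) * Fc
      x <- x + (0.5 * dt) * v
      if (gam > 0) {
        v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), ncol = 3)
      }
      x <- x + (0.5 * dt) * v
      if (!all(is.finite(x)))
        stop(sprintf("blow-up error: non-finite coordinates at step %d", step))
      Fc <- potential_energy(params, x)$forces
      v <- v + (0.5 * dt * inv_m) * Fc
      if (step %% stride == 0L) {
        fi <- fi + 1L
        arr[fi, , ] <- x
      }
    }
  })
  newstate <- dynamics_state(x, v, time = state$time + n_steps * dt,
                             temperature_target = state$temperature_target,
                             friction = gam)
  list(trajectory = md_trajectory(arr[seq_len(fi), , , drop = FALSE],
                                  dt = dt * stride),
       state = newstate)
}
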