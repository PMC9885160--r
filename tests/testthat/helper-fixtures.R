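## Fixtures are built in code; nothing is read from disk.

## Default synthetic two-domain system (52 beads), built once per file.
fx_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_two_domain_system(synthetic_spec())
    cache
  }
})

## Diatomic on the x axis: CHARMM bond constant k (stiffness 2k), length r0.
fx_diatomic <- function(k = 10, r0 = 3, mass = 110) {
  s <- md_structure(c("CA", "CA"), 1:2, rbind(c(0, 0, 0), c(r0, 0, 0)),
                    mass = mass, eps = 0, charge = 0)
  p <- force_field_params(s, bonds = data.frame(i = 1, j = 2, k = k, r0 = r0))
  list(structure = s, params = p)
}

## Random non-collinear bead cluster fully connected by network springs at
## their observed lengths (a force-field realization of a uniform ENM).
fx_cluster <- function(n = 5, k_bond = 0.5, seed = 3, sd = 3) {
  xyz <- with_seed(seed, matrix(stats::rnorm(3 * n, sd = sd), n, 3))
  s <- md_structure(rep("CA", n), seq_len(n), xyz, eps = 0, charge = 0)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  r0 <- sqrt(rowSums((xyz[pr[, 2], , drop = FALSE] -
                        xyz[pr[, 1], , drop = FALSE])^2))
  p <- force_field_params(s, bonds = data.frame(i = pr[, 1], j = pr[, 2],
                                                k = k_bond, r0 = r0))
  list(structure = s, params = p)
}

## Random proper rotation matrix.
fx_rotation <- function(seed = 1) {
  with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

## ENM modes of the default synthetic system plus the 4 tail-selected modes.
fx_modes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- fx_system()
      ms <- diagonalize_hessian(build_enm_hessian(sys$structure),
                                sys$structure$atoms$mass)
      tail_sel <- select_atoms(sys$structure, "resid 41:52")
      cache <<- list(modes = ms, tail = tail_sel,
                     picked = select_modes(ms, tail_sel, 4))
    }
    cache
  }
})

## Construct a replica state with prescribed displacement history, for
## exercising the adaptation rule in isolation.
fx_replica_history <- function(projection, angle_deg, n_atoms = 4) {
  x0 <- matrix(0, n_atoms, 3)
  dirvec <- rep(0, 3 * n_atoms); dirvec[1] <- 1
  rep <- amdenm:::new_replica(
    amdenm:::new_direction(dirvec), x0, id = "hist")
  rep$excitation_count <- 1L
  rep$conformations[[1]] <- x0 + 0.1
  rep$last_segment_mean <- x0 + 0.05
  rep$last_projection <- projection
  rep$last_angle <- angle_deg
  rep$log <- data.frame(cycle = 1L, ke_before = 0, ke_after = 0,
                        delta_ke = 0, projection = projection,
                        angle_deg = angle_deg, updated = FALSE)
  rep
}
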