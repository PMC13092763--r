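#' NEB parameters
#'
#' @param force_tol Convergence threshold on the maximum per-atom NEB force
#'   norm, eV/Angstrom (default 1e-3 Ha/Bohr converted, 0.0514221).
#' @param max_iterations Band iteration cap (default 1000).
#' @param k_min,k_max Spring-constant bounds, eV/Angstrom^2 (defaults
#'   0.972 and 9.72).
#' @param energy_weighted Use energy-weighted springs (default TRUE);
#'   otherwise all springs sit at `k_min`.
#' @param ci_activation_fraction Climbing image activates once the maximum
#'   band force falls to `force_tol / ci_activation_fraction`, i.e. the
#'   band is within `1/fraction` of its threshold (default 0.8).
#' @param mmf_switch_force Climbing-image force (eV/Angstrom) below which
#'   the band is frozen and minimum-mode-following refinement takes over
#'   (default 0.5).
#' @param mode_tangent_min_overlap Minimum |cosine| between the first
#'   converged dimer mode and the NEB tangent; a mode below this overlap
#'   is rejected in favor of the tangent (default 0.8).
#' @param mmf_max_iterations Translation-step cap for the refinement walk
#'   (default 500).
#' @param dimer_delta Finite-difference dimer separation, Angstrom
#'   (default 1e-3).
#' @param dimer_rotations Rotation cap per translation step (default 10).
#' @param snapshot_every Record full band coordinates into the history
#'   every this many iterations (default 1; raise to thin the history).
#' @return An object of class `neb_params`.
#' @export
neb_params <- function(force_tol = hartree_bohr_to_ev_ang(1e-3),
                       max_iterations = 1000L,
                       k_min = 0.972, k_max = 9.72,
                       energy_weighted = TRUE,
                       ci_activation_fraction = 0.8,
                       mmf_switch_force = 0.5,
                       mode_tangent_min_overlap = 0.8,
                       mmf_max_iterations = 500L,
                       dimer_delta = 1e-3,
                       dimer_rotations = 10L,
                       snapshot_every = 1L) {
  stopifnot(k_min > 0, k_min <= k_max,
            ci_activation_fraction > 0, ci_activation_fraction <= 1,
            force_tol > 0)
  structure(list(force_tol = force_tol, max_iterations = as.integer(max_iterations),
                 k_min = k_min, k_max = k_max, energy_weighted = energy_weighted,
                 ci_activation_fraction = ci_activation_fraction,
                 mmf_switch_force = mmf_switch_force,
                 mode_tangent_min_overlap = mode_tangent_min_overlap,
                 mmf_max_iterations = as.integer(mmf_max_iterations),
                 dimer_delta = dimer_delta,
                 dimer_rotations = as.integer(dimer_rotations),
                 snapshot_every = as.integer(snapshot_every)),
            class = "neb_params")
}

#' Upwinded (improved) path tangent
#'
#' Points toward the higher-energy neighbor; at local energy extrema the
#' two segment vectors are mixed with energy-difference weights so the
#' tangent switches smoothly. Returned with unit norm.
#'
#' @param E_prev,E_here,E_next Image energies, eV.
#' @param R_prev,R_here,R_next Image coordinates (length-3N vectors or
#'   N x 3 matrices).
#' @return Unit tangent as a length-3N numeric vector.
#' @export
improved_tangent <- function(E_prev, E_here, E_next, R_prev, R_here, R_next) {
  as_vec <- function(R) if (is.matrix(R)) as.numeric(t(R)) else as.numeric(R)
  rp <- as_vec(R_prev); rh <- as_vec(R_here); rn <- as_vec(R_next)
  seg_f <- rn - rh
  seg_b <- rh - rp
  if (sqrt(sum(seg_f^2)) < 1e-14 || sqrt(sum(seg_b^2)) < 1e-14)
    stop("coincident neighboring images: tangent undefined")
  if (E_next > E_here && E_here > E_prev) {
    tau <- seg_f
  } else if (E_next < E_here && E_here < E_prev) {
    tau <- seg_b
  } else {
    dmax <- max(abs(E_next - E_here), abs(E_prev - E_here))
    dmin <- min(abs(E_next - E_here), abs(E_prev - E_here))
    if (dmax == 0 && dmin == 0) {
      tau <- rn - rp                     # flat: plain central difference
    } else if (E_next > E_prev) {
      tau <- dmax * seg_f + dmin * seg_b
    } else {
      tau <- dmin * seg_f + dmax * seg_b
    }
  }
  tau / sqrt(sum(tau^2))
}

#' Energy-weighted spring constant
#'
#' `k_i = k_min + (k_max - k_min) * max(E_i - E_ref, 0) / (E_max - E_ref)`,
#' clamped to `[k_min, k_max]`; when `E_max <= E_ref` (flat or inverted
#' band) the function returns `k_min`. Springs stiffen between high-energy
#' images so images concentrate near the barrier.
#'
#' @param E_i Image energy, eV.
#' @param E_ref Reference energy (the higher of the two endpoint
#'   energies), eV.
#' @param E_max Band maximum energy, eV.
#' @param params A [neb_params()] supplying `k_min`, `k_max`.
#' @return Spring constant, eV/Angstrom^2.
#' @export
energy_weighted_spring <- function(E_i, E_ref, E_max, params = neb_params()) {
  if (E_max <= E_ref) return(params$k_min)
  frac <- max(E_i - E_ref, 0) / (E_max - E_ref)
  min(max(params$k_min + (params$k_max - params$k_min) * frac, params$k_min),
      params$k_max)
}

#' Climbing-image force
#'
#' Inverts the parallel component of the true force at the climbing image:
#' `F_CI = -g + 2 (g . tau) tau` for gradient `g`, driving the image
#' uphill along the tangent while relaxing perpendicular to it.
#'
#' @param gradient Length-3N energy gradient (`= -force`).
#' @param tangent Unit length-3N tangent.
#' @return Length-3N climbing force.
#' @export
climbing_force <- function(gradient, tangent) {
  -gradient + 2 * sum(gradient * tangent) * tangent
}

# Per-image tangents, spring constants and segment lengths for a band
# whose images carry energies; uniform_k overrides energy weighting.
band_geometry <- function(images, params, uniform_k = NULL) {
  m <- length(images)
  energies <- vapply(images, function(im) im$energy, numeric(1))
  xs <- lapply(images, flatten_positions)
  seg_len <- vapply(seq_len(m - 1L), function(j)
    sqrt(sum((xs[[j + 1L]] - xs[[j]])^2)), numeric(1))
  tangents <- vector("list", m)
  for (i in 2L:(m - 1L)) {
    tangents[[i]] <- improved_tangent(energies[i - 1L], energies[i], energies[i + 1L],
                                      xs[[i - 1L]], xs[[i]], xs[[i + 1L]])
  }
  if (!is.null(uniform_k)) {
    k_img <- rep(uniform_k, m)
  } else if (params$energy_weighted) {
    E_ref <- max(energies[1L], energies[m])
    E_max <- max(energies)
    k_img <- vapply(energies, energy_weighted_spring, numeric(1),
                    E_ref = E_ref, E_max = E_max, params = params)
  } else {
    k_img <- rep(params$k_min, m)
  }
  k_seg <- (k_img[-m] + k_img[-1L]) / 2
  list(energies = energies, xs = xs, tangents = tangents,
       k_seg = k_seg, seg_len = seg_len)
}

#' Per-image NEB forces
#'
#' For interior non-climbing images, the perpendicular component of the
#' true force plus the tangent-projected spring force
#' `(k_fwd d_fwd - k_bwd d_bwd) tau`; for the active climbing image, the
#' [climbing_force()]; endpoints receive zero. The perpendicular and
#' parallel components are returned alongside the totals so projection
#' identities can be audited from recorded histories.
#'
#' @param state Band state: list with `images` (energies and forces
#'   populated), `tangents`, `k_seg`, `seg_len`, optional `climbing_index`.
#' @param params A [neb_params()].
#' @return List with `total`, `perp`, `spring` — each a per-image list of
#'   length-3N vectors (zero vectors at the endpoints).
#' @export
neb_forces <- function(state, params = neb_params()) {
  images <- state$images
  m <- length(images)
  if (any(vapply(images, function(im) is.null(im$energy) || is.null(im$forces), logical(1))))
    stop("band state not populated: evaluate energies and forces first")
  nz <- length(flatten_positions(images[[1L]]))
  zero <- numeric(nz)
  total <- perp <- spring <- rep(list(zero), m)
  for (i in 2L:(m - 1L)) {
    tau <- state$tangents[[i]]
    f_true <- as.numeric(t(images[[i]]$forces))
    f_par <- sum(f_true * tau)
    f_perp <- f_true - f_par * tau
    f_spr <- (state$k_seg[i] * state$seg_len[i] -
                state$k_seg[i - 1L] * state$seg_len[i - 1L]) * tau
    perp[[i]] <- f_perp
    spring[[i]] <- f_spr
    if (!is.null(state$climbing_index) && i == state$climbing_index) {
      total[[i]] <- climbing_force(-f_true, tau)
    } else {
      total[[i]] <- f_perp + f_spr
    }
  }
  list(total = total, perp = perp, spring = spring)
}

# Generic frozen-endpoint band relaxation on an arbitrary per-image
# surface (used by IDPP/SIDPP). Plain uniform springs, no climbing.
relax_band_on <- function(images, surface_fn, spring_constant, force_tol,
                          max_iterations, max_move) {
  m <- length(images)
  if (m < 3L) return(images)
  # degenerate band (identical endpoints): nothing to relax
  total_len <- sum(vapply(seq_len(m - 1L), function(j)
    sqrt(sum((images[[j + 1L]]$positions - images[[j]]$positions)^2)), numeric(1)))
  if (total_len < 1e-10) return(images)
  n <- n_atoms(images[[1L]])
  template <- images[[1L]]
  for (k in c(1L, m)) {
    ev <- surface_fn(k, images[[k]])
    images[[k]]$energy <- ev$energy
    images[[k]]$forces <- ev$forces
  }
  interior <- 2L:(m - 1L)
  pack <- function(imgs) unlist(lapply(imgs[interior], flatten_positions))
  unpack <- function(x) {
    per <- 3L * n
    for (idx in seq_along(interior)) {
      k <- interior[idx]
      images[[k]] <<- with_positions(template, x[((idx - 1L) * per + 1L):(idx * per)])
    }
  }
  force_fn <- function(x) {
    unpack(x)
    for (k in interior) {
      ev <- surface_fn(k, images[[k]])
      images[[k]]$energy <<- ev$energy
      images[[k]]$forces <<- ev$forces
    }
    geo <- band_geometry(images, params = NULL, uniform_k = spring_constant)
    st <- list(images = images, tangents = geo$tangents,
               k_seg = geo$k_seg, seg_len = geo$seg_len, climbing_index = NULL)
    nf <- neb_forces(st, params = neb_params())
    unlist(nf$total[interior])
  }
  res <- force_field_drive(force_fn, pack(images), max_move = max_move,
                           force_tol = force_tol, max_iterations = max_iterations)
  unpack(res$x)
  for (k in interior) {
    ev <- surface_fn(k, images[[k]])
    images[[k]]$energy <- ev$energy
    images[[k]]$forces <- ev$forces
  }
  images
}

#' Hybrid CI-NEB / minimum-mode-following band optimization
#'
#' Phase 1 relaxes the whole band on the NEB forces (energy-weighted
#' springs by default). Once the maximum band force falls to
#' `force_tol / ci_activation_fraction`, the highest-energy interior image
#' becomes the climbing image and its parallel force component is
#' inverted. When the climbing image's force norm drops below
#' `mmf_switch_force`, the band is frozen and a minimum-mode-following
#' walker ([mmf_refine()]) detaches from the discretized path to converge
#' the saddle; the refined saddle is re-inserted at the climbing position.
#' Terminates when the climbing-image force reaches `force_tol` or at the
#' iteration cap (flagged, not silent).
#'
#' @param path List of configurations from path generation; endpoints
#'   minimized. Endpoints never move.
#' @param spec A [potential_spec()].
#' @param params A [neb_params()].
#' @return List with `state` (final band state: `images`, `tangents`,
#'   `springs`, `climbing_index`, `phase`, `iteration`, `max_force`,
#'   `converged`) and `history` (per-iteration records of phase, energies,
#'   maximum force, image coordinates, tangents and force components).
#' @export
optimize_band <- function(path, spec, params = neb_params()) {
  m <- length(path)
  if (m < 3L) stop("a band needs at least three images")
  images <- path
  for (k in c(1L, m)) {
    ev <- evaluate_potential(spec, images[[k]])
    images[[k]]$energy <- ev$energy
    images[[k]]$forces <- ev$forces
  }
  n <- n_atoms(images[[1L]])
  template <- images[[1L]]
  interior <- 2L:(m - 1L)
  per <- 3L * n
  history <- list()
  phase <- "neb"
  climbing_index <- NULL
  iteration <- 0L
  converged <- FALSE
  st_opt <- lbfgs_state(20L)

  eval_interior <- function() {
    for (k in interior) {
      ev <- evaluate_potential(spec, images[[k]])
      images[[k]]$energy <<- ev$energy
      images[[k]]$forces <<- ev$forces
    }
  }
  set_interior <- function(x) {
    for (idx in seq_along(interior)) {
      k <- interior[idx]
      images[[k]] <<- with_positions(template, x[((idx - 1L) * per + 1L):(idx * per)])
    }
  }
  pack_interior <- function() unlist(lapply(images[interior], flatten_positions))

  x <- pack_interior()
  g_prev <- NULL; x_prev <- NULL
  geo <- NULL; nf <- NULL
  tr <- 0.1                             # adaptive trust radius, Angstrom
  max_force_prev <- Inf

  max_over <- function(vecs) max(vapply(vecs[interior], max_atom_disp, numeric(1)))

  while (iteration < params$max_iterations) {
    eval_interior()
    geo <- band_geometry(images, params)
    state <- list(images = images, tangents = geo$tangents,
                  k_seg = geo$k_seg, seg_len = geo$seg_len,
                  climbing_index = climbing_index)
    nf <- neb_forces(state, params)
    max_force <- max_over(nf$total)
    if (phase == "neb" && max_force <= params$force_tol / params$ci_activation_fraction) {
      phase <- "ci_neb"
      climbing_index <- interior[which.max(geo$energies[interior])]
      state$climbing_index <- climbing_index
      nf <- neb_forces(state, params)
      max_force <- max_over(nf$total)
      lbfgs_reset(st_opt)
    }
    record <- (iteration %% params$snapshot_every == 0L)
    if (record) {
      history[[length(history) + 1L]] <- list(
        iteration = iteration, phase = phase, climbing_index = climbing_index,
        energies = geo$energies, max_force = max_force,
        positions = lapply(images, function(im) im$positions),
        tangents = geo$tangents[interior],
        f_perp = nf$perp[interior], f_spring = nf$spring[interior])
    }
    if (phase == "ci_neb") {
      ci_force <- max_atom_disp(nf$total[[climbing_index]])
      if (ci_force <= params$force_tol) { converged <- TRUE; break }
      if (ci_force <= params$mmf_switch_force) {
        phase <- "mmf"
        refined <- mmf_refine(spec, images[[climbing_index]],
                              geo$tangents[[climbing_index]], params)
        images[[climbing_index]] <- refined
        x <- pack_interior()
        geo <- band_geometry(images, params)
        converged <- max_atom_force(refined$forces) <= params$force_tol
        history[[length(history) + 1L]] <- list(
          iteration = iteration, phase = phase, climbing_index = climbing_index,
          energies = geo$energies,
          max_force = max_atom_force(refined$forces),
          positions = lapply(images, function(im) im$positions),
          tangents = NULL, f_perp = NULL, f_spring = NULL)
        break
      }
    }
    # quasi-Newton step on the stacked interior coordinates; growing
    # residual force drops the curvature memory and halves the trust
    # radius (tangent switches make the field only piecewise smooth)
    if (max_force > 1.5 * max_force_prev) {
      lbfgs_reset(st_opt)
      x_prev <- NULL; g_prev <- NULL
      tr <- max(tr / 2, 1e-3)
    } else {
      tr <- min(tr * 1.05, 0.1)
    }
    max_force_prev <- max_force
    g <- -unlist(nf$total[interior])
    if (!is.null(x_prev)) lbfgs_push(st_opt, x - x_prev, g - g_prev)
    step <- lbfgs_direction(st_opt, g)
    if (sum(step * g) > 0) { lbfgs_reset(st_opt); step <- lbfgs_direction(st_opt, g) }
    disp <- max_atom_disp(step)
    if (disp > tr) step <- step * (tr / disp)
    x_prev <- x; g_prev <- g
    x <- x + step
    set_interior(x)
    iteration <- iteration + 1L
  }
  if (phase != "mmf") {
    eval_interior()
    geo <- band_geometry(images, params)
  }
  final_state <- list(images = images, tangents = geo$tangents,
                      springs = geo$k_seg, k_seg = geo$k_seg,
                      seg_len = geo$seg_len,
                      climbing_index = climbing_index, phase = phase,
                      iteration = iteration,
                      max_force = if (!is.null(climbing_index))
                        max_atom_force(images[[climbing_index]]$forces)
                      else max(vapply(images[interior], function(im)
                        max_atom_force(im$forces), numeric(1))),
                      converged = converged)
  class(final_state) <- "band_state"
  list(state = final_state, history = history)
}

#' Lowest-curvature mode by finite-difference dimer rotation
#'
#' Rotates a two-point dimer of separation `delta` about its center to
#' minimize the curvature estimate, using the standard one-point Fourier
#' expansion of curvature versus rotation angle in the plane spanned by
#' the current mode and the rotational force. Returns the converged mode
#' and the central-difference curvature
#' `C = (F(x - delta v) - F(x + delta v)) . v / (2 delta)`, negative along
#' a descent-to-saddle direction.
#'
#' @param spec A [potential_spec()].
#' @param center `configuration` at the dimer midpoint.
#' @param seed_mode Unit length-3N starting mode.
#' @param delta Dimer separation, Angstrom.
#' @param max_rotations Rotation cap; non-convergence is flagged, not an
#'   error.
#' @param angle_tol Stop when the optimal rotation angle falls below this
#'   (radians).
#' @return List with `mode` (unit length-3N), `curvature` (eV/Angstrom^2),
#'   `rotations`, `converged`.
#' @export
dimer_lowest_mode <- function(spec, center, seed_mode, delta = 1e-3,
                              max_rotations = 100L, angle_tol = 1e-5) {
  x0 <- flatten_positions(center)
  n <- n_atoms(center)
  v <- seed_mode / sqrt(sum(seed_mode^2))
  force_at <- function(x) as.numeric(t(evaluate_potential(spec, with_positions(center, x))$forces))
  F0 <- force_at(x0)
  rotations <- 0L
  converged <- FALSE
  while (rotations < max_rotations) {
    F1 <- force_at(x0 + delta * v)
    dF <- F1 - F0
    C0 <- -sum(dF * v) / delta
    frot <- dF - sum(dF * v) * v
    fr_norm <- sqrt(sum(frot^2))
    if (fr_norm / delta < 1e-10) { converged <- TRUE; break }
    theta_dir <- frot / fr_norm
    dCdtheta <- -2 * sum(dF * theta_dir) / delta
    theta_t <- pi / 8
    v_t <- v * cos(theta_t) + theta_dir * sin(theta_t)
    F1t <- force_at(x0 + delta * v_t)
    C_t <- -sum((F1t - F0) * v_t) / delta
    b1 <- dCdtheta / 2
    a1 <- (C0 - C_t + b1 * sin(2 * theta_t)) / (1 - cos(2 * theta_t))
    theta_ext <- 0.5 * atan2(b1, a1)
    # pick the curvature minimum of the two extrema
    cur_at <- function(th) a1 * cos(2 * th) + b1 * sin(2 * th)
    if (cur_at(theta_ext) > cur_at(theta_ext + pi / 2)) theta_ext <- theta_ext + pi / 2
    theta_ext <- ((theta_ext + pi / 2) %% pi) - pi / 2   # wrap to (-pi/2, pi/2]
    v <- v * cos(theta_ext) + theta_dir * sin(theta_ext)
    v <- v / sqrt(sum(v^2))
    rotations <- rotations + 1L
    if (abs(theta_ext) < angle_tol) { converged <- TRUE; break }
  }
  Fp <- force_at(x0 + delta * v)
  Fm <- force_at(x0 - delta * v)
  curvature <- sum((Fm - Fp) * v) / (2 * delta)
  list(mode = v, curvature = curvature, rotations = rotations,
       converged = converged)
}

#' Minimum-mode-following saddle refinement
#'
#' Walks a single configuration to a first-order saddle by repeatedly
#' (i) estimating the lowest-curvature mode with a rotating dimer and
#' (ii) taking a bounded quasi-Newton step on the mode-inverted effective
#' force `F - 2 (F . v) v`. On the first iteration the mode search is
#' seeded with the NEB tangent, and a converged mode whose overlap
#' |cosine| with that tangent falls below `mode_tangent_min_overlap` is
#' rejected in favor of the tangent; afterwards each step is seeded with
#' the previous mode.
#'
#' @param spec A [potential_spec()].
#' @param start Starting `configuration` (typically the climbing image).
#' @param neb_tangent Unit length-3N NEB tangent at the start.
#' @param params A [neb_params()].
#' @return The saddle-candidate `configuration` with energy/forces set and
#'   attributes `curvature` (negative at a valid saddle) and `converged`.
#'   Converging to a point of positive lowest curvature is an error.
#' @export
mmf_refine <- function(spec, start, neb_tangent, params = neb_params()) {
  n <- n_atoms(start)
  x <- flatten_positions(start)
  v <- neb_tangent / sqrt(sum(neb_tangent^2))
  st <- lbfgs_state(20L)
  g_prev <- NULL; x_prev <- NULL
  first <- TRUE
  iterations <- 0L
  converged <- FALSE
  curvature <- NA_real_
  repeat {
    cfg <- with_positions(start, x)
    ev <- evaluate_potential(spec, cfg)
    f_true <- as.numeric(t(ev$forces))
    if (max_atom_force(ev$forces) <= params$force_tol) { converged <- TRUE; break }
    if (iterations >= params$mmf_max_iterations) break
    dl <- dimer_lowest_mode(spec, cfg, v, delta = params$dimer_delta,
                            max_rotations = params$dimer_rotations)
    if (first && abs(sum(dl$mode * neb_tangent)) < params$mode_tangent_min_overlap) {
      v <- neb_tangent
    } else {
      v <- dl$mode
    }
    curvature <- dl$curvature
    first <- FALSE
    f_eff <- f_true - 2 * sum(f_true * v) * v
    g <- -f_eff
    if (!is.null(x_prev)) lbfgs_push(st, x - x_prev, g - g_prev)
    step <- lbfgs_direction(st, g)
    if (sum(step * g) > 0) { lbfgs_reset(st); step <- lbfgs_direction(st, g) }
    disp <- max_atom_disp(step)
    if (disp > 0.1) step <- step * (0.1 / disp)
    x_prev <- x; g_prev <- g
    x <- x + step
    iterations <- iterations + 1L
  }
  cfg <- with_positions(start, x)
  ev <- evaluate_potential(spec, cfg)
  cfg$energy <- ev$energy
  cfg$forces <- ev$forces
  dl_final <- dimer_lowest_mode(spec, cfg, v, delta = params$dimer_delta,
                                max_rotations = 50L)
  if (converged && dl_final$curvature >= 0)
    stop("minimum-mode refinement converged to a non-saddle (positive lowest curvature)")
  attr(cfg, "curvature") <- dl_final$curvature
  attr(cfg, "converged") <- converged
  cfg
}
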