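#' Convert Hartree/Bohr to eV/Angstrom
#'
#' Uses CODATA 2018 constants (Hartree = 27.211386245988 eV, Bohr =
#' 0.529177210903 Angstrom). The conventional force-convergence threshold
#' of 1e-3 Ha/Bohr converts to 0.0514221 eV/Angstrom.
#'
#' @param value Force in Hartree/Bohr.
#' @return Force in eV/Angstrom.
#' @export
hartree_bohr_to_ev_ang <- function(value) {
  value * 27.211386245988 / 0.529177210903
}

#' Minimization parameters
#'
#' @param force_tol Convergence threshold on the maximum per-atom force
#'   norm, eV/Angstrom. Default is 1e-3 Ha/Bohr converted (0.0514221).
#' @param max_iterations Iteration cap (default 2000).
#' @param max_move Maximum displacement of any single atom per accepted
#'   step, Angstrom (default 0.1). Oversized quasi-Newton steps are
#'   rescaled uniformly so the direction is preserved.
#' @param history_size L-BFGS memory (default 20).
#' @return An object of class `minimize_params`.
#' @export
minimize_params <- function(force_tol = hartree_bohr_to_ev_ang(1e-3),
                            max_iterations = 2000L, max_move = 0.1,
                            history_size = 20L) {
  stopifnot(force_tol > 0, max_move > 0, max_iterations >= 1L)
  structure(list(force_tol = force_tol, max_iterations = as.integer(max_iterations),
                 max_move = max_move, history_size = as.integer(history_size)),
            class = "minimize_params")
}

max_atom_force <- function(forces) max(sqrt(rowSums(forces^2)))

max_atom_disp <- function(step_vec) {
  m <- matrix(step_vec, ncol = 3L, byrow = TRUE)
  max(sqrt(rowSums(m^2)))
}

# Shared L-BFGS two-loop machinery. `h0` is the initial inverse-Hessian
# scale (Angstrom^2/eV); after the first curvature pair it is replaced by
# the standard s.y/y.y scaling.
lbfgs_state <- function(history_size, h0 = 1 / 70) {
  env <- new.env(parent = emptyenv())
  env$s <- list(); env$y <- list(); env$h0 <- h0
  env$m <- history_size
  env
}

lbfgs_reset <- function(st) { st$s <- list(); st$y <- list(); invisible(st) }

lbfgs_push <- function(st, s, y) {
  sy <- sum(s * y)
  if (!is.finite(sy) || sy <= 1e-12 * sqrt(sum(s^2) * sum(y^2))) return(invisible(st))
  st$s[[length(st$s) + 1L]] <- s
  st$y[[length(st$y) + 1L]] <- y
  if (length(st$s) > st$m) { st$s <- st$s[-1L]; st$y <- st$y[-1L] }
  invisible(st)
}

lbfgs_direction <- function(st, g) {
  k <- length(st$s)
  q <- g
  if (k == 0L) return(-st$h0 * q)
  alpha <- numeric(k); rho <- numeric(k)
  for (i in k:1) {
    rho[i] <- 1 / sum(st$y[[i]] * st$s[[i]])
    alpha[i] <- rho[i] * sum(st$s[[i]] * q)
    q <- q - alpha[i] * st$y[[i]]
  }
  gamma <- sum(st$s[[k]] * st$y[[k]]) / sum(st$y[[k]] * st$y[[k]])
  z <- gamma * q
  for (i in 1:k) {
    beta <- rho[i] * sum(st$y[[i]] * z)
    z <- z + st$s[[i]] * (alpha[i] - beta)
  }
  -z
}

#' Bounded-step L-BFGS geometry minimization
#'
#' Quasi-Newton descent on a potential-energy surface with (i) a hard cap
#' on the per-atom displacement of every accepted step (oversized steps are
#' rescaled, direction preserved), (ii) backtracking on any energy
#' increase so accepted energies are non-increasing, and (iii) convergence
#' declared when the maximum per-atom force norm drops to `force_tol`.
#' Fully deterministic: identical inputs give identical trajectories.
#'
#' @param spec A [potential_spec()].
#' @param start Starting `configuration`.
#' @param params A [minimize_params()].
#' @return List with `config` (final configuration, energy/forces set),
#'   `trajectory` (list of accepted configurations, including start),
#'   `converged` flag and `iterations` count. Hitting the iteration cap is
#'   flagged (`converged = FALSE`), never silent.
#' @export
lbfgs_minimize <- function(spec, start, params = minimize_params()) {
  stopifnot_configuration(start)
  n <- n_atoms(start)
  x <- flatten_positions(start)
  ev <- evaluate_potential(spec, start)
  e <- ev$energy; f <- ev$forces
  cfg <- start; cfg$energy <- e; cfg$forces <- f
  trajectory <- list(cfg)
  st <- lbfgs_state(params$history_size)
  g <- -as.numeric(t(f))
  iterations <- 0L
  converged <- max_atom_force(f) <= params$force_tol

  while (!converged && iterations < params$max_iterations) {
    step <- lbfgs_direction(st, g)
    if (sum(step * g) > 0) {           # not a descent direction: reset
      lbfgs_reset(st)
      step <- lbfgs_direction(st, g)
    }
    disp <- max_atom_disp(step)
    if (disp > params$max_move) step <- step * (params$max_move / disp)
    accepted <- FALSE
    for (bt in 1:40) {
      x_new <- x + step
      ev_new <- tryCatch(
        evaluate_potential(spec, with_positions(start, x_new)),
        error = function(cond) NULL)
      if (!is.null(ev_new) && is.finite(ev_new$energy) && ev_new$energy <= e) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break               # stuck: stop with last good state
    g_new <- -as.numeric(t(ev_new$forces))
    lbfgs_push(st, x_new - x, g_new - g)
    x <- x_new; e <- ev_new$energy; f <- ev_new$forces; g <- g_new
    cfg <- with_positions(start, x); cfg$energy <- e; cfg$forces <- f
    trajectory[[length(trajectory) + 1L]] <- cfg
    iterations <- iterations + 1L
    converged <- max_atom_force(f) <= params$force_tol
  }
  list(config = cfg, trajectory = trajectory, converged = converged,
       iterations = iterations)
}

# Quasi-Newton stepper for force fields that are not gradients of a scalar
# objective (NEB forces, mode-inverted dimer forces, IDPP band
# relaxation): no line search; instead an adaptive trust radius under the
# hard per-atom displacement cap. Whenever the residual force grows, the
# curvature memory (poisoned by tangent switches or mode rotation) is
# dropped and the trust radius halved; steady progress relaxes it back.
# Used internally by the band and pathgen machinery.
force_field_drive <- function(force_fn, x0, max_move, force_tol, max_iterations,
                              history_size = 20L, callback = NULL) {
  x <- x0
  st <- lbfgs_state(history_size)
  f <- force_fn(x)
  g <- -f
  iterations <- 0L
  converged <- max_atom_disp(f) <= force_tol
  tr <- max_move
  f_norm_prev <- max_atom_disp(f)
  x_prev <- NULL; g_prev <- NULL
  while (!converged && iterations < max_iterations) {
    if (!is.null(x_prev)) lbfgs_push(st, x - x_prev, g - g_prev)
    step <- lbfgs_direction(st, g)
    if (sum(step * g) > 0) { lbfgs_reset(st); step <- lbfgs_direction(st, g) }
    disp <- max_atom_disp(step)
    if (disp > tr) step <- step * (tr / disp)
    x_prev <- x; g_prev <- g
    x <- x + step
    f <- force_fn(x)
    if (any(!is.finite(f))) stop("non-finite forces during force-field drive")
    g <- -f
    f_norm <- max_atom_disp(f)
    if (f_norm > 1.5 * f_norm_prev) {
      lbfgs_reset(st)
      x_prev <- NULL; g_prev <- NULL
      tr <- max(tr / 2, 1e-3)
    } else {
      tr <- min(tr * 1.05, max_move)
    }
    f_norm_prev <- f_norm
    iterations <- iterations + 1L
    if (!is.null(callback)) callback(x, f, iterations)
    converged <- f_norm <= force_tol
  }
  list(x = x, forces = f, converged = converged, iterations = iterations)
}
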