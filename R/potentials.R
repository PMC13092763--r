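#' Potential-energy-surface registry
#'
#' Surfaces are pluggable: a potential is a function
#' `function(config, parameters)` returning `list(energy = <eV>,
#' forces = <N x 3 eV/Angstrom>)`. Two analytic surfaces ship with the
#' package: `muller_brown` (the canonical 2D two-saddle benchmark, one
#' particle, z ignored) and `morse_cluster` (pairwise Morse with
#' species-pair parameters). External surfaces can be registered through
#' the same contract.
#'
#' @name potentials
NULL

.potential_registry <- new.env(parent = emptyenv())

#' Register a potential-energy surface
#'
#' @param name Identifier used in [potential_spec()].
#' @param fn Function `(config, parameters) -> list(energy, forces)`.
#' @export
register_potential <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .potential_registry)
  invisible(name)
}

#' Describe a potential-energy surface
#'
#' @param name Registered surface name (e.g. `"muller_brown"`,
#'   `"morse_cluster"`).
#' @param parameters Named list of surface parameters; merged over the
#'   surface's defaults at evaluation time.
#' @return An object of class `potential_spec`.
#' @export
potential_spec <- function(name, parameters = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, parameters = parameters), class = "potential_spec")
}

#' Evaluate a potential-energy surface
#'
#' @param spec A [potential_spec()].
#' @param config A [configuration()].
#' @return List with `energy` (eV) and `forces` (N x 3, eV/Angstrom).
#' @export
evaluate_potential <- function(spec, config) {
  if (!inherits(spec, "potential_spec")) spec <- do.call(potential_spec, as.list(spec))
  stopifnot_configuration(config)
  if (!exists(spec$name, envir = .potential_registry, inherits = FALSE))
    stop(sprintf("unknown potential '%s'; registered: %s", spec$name,
                 paste(ls(.potential_registry), collapse = ", ")))
  fn <- get(spec$name, envir = .potential_registry, inherits = FALSE)
  out <- fn(config, spec$parameters)
  if (!is.finite(out$energy) || !all(is.finite(out$forces)))
    stop(sprintf("potential '%s' returned non-finite energy or forces", spec$name))
  out
}

#' Central-difference forces (testing oracle)
#'
#' Negated central-difference gradient of the energy; agrees with the
#' analytic forces to O(h^2).
#'
#' @param spec A [potential_spec()].
#' @param config A [configuration()].
#' @param h Displacement step in (0, 0.1] Angstrom.
#' @return N x 3 matrix of finite-difference forces, eV/Angstrom.
#' @export
finite_difference_forces <- function(spec, config, h = 1e-5) {
  stopifnot(h > 0, h <= 0.1)
  n <- n_atoms(config)
  x0 <- flatten_positions(config)
  e_at <- function(x) evaluate_potential(spec, with_positions(config, x))$energy
  g <- numeric(3L * n)
  for (k in seq_along(g)) {
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    g[k] <- (e_at(xp) - e_at(xm)) / (2 * h)
  }
  unflatten_positions(-g, n)
}

# ---- Mueller-Brown surface -------------------------------------------------

# Standard four-Gaussian parameterization; treated as eV over Angstrom
# coordinates so the whole pipeline runs in one unit system. One particle;
# the z coordinate is ignored (zero force).
mb_defaults <- list(
  A  = c(-200, -100, -170, 15),
  a  = c(-1, -1, -6.5, 0.7),
  b  = c(0, 0, 11, 0.6),
  cc = c(-10, -10, -6.5, 0.7),
  x0 = c(1, 0, -0.5, -1),
  y0 = c(0, 0.5, 1.5, 1)
)

muller_brown_eval <- function(config, parameters) {
  if (n_atoms(config) != 1L)
    stop("muller_brown expects exactly one particle")
  p <- utils::modifyList(mb_defaults, parameters %||% list())
  x <- config$positions[1L, 1L]; y <- config$positions[1L, 2L]
  dx <- x - p$x0; dy <- y - p$y0
  ex <- p$A * exp(p$a * dx^2 + p$b * dx * dy + p$cc * dy^2)
  e <- sum(ex)
  dEdx <- sum(ex * (2 * p$a * dx + p$b * dy))
  dEdy <- sum(ex * (p$b * dx + 2 * p$cc * dy))
  list(energy = e, forces = matrix(c(-dEdx, -dEdy, 0), nrow = 1L))
}

# ---- Pairwise Morse cluster ------------------------------------------------

# Per species-pair (De, a, re); the default table realizes a three-atom
# "surrogate isomerization": a stiff C--N scaffold whose equilibrium length
# exceeds the sum of the H--C and H--N bond lengths, so the proton cannot
# bind both centers at once. The hop between the two single-bond minima
# crosses a lone first-order saddle near the scaffold midpoint.
morse_default_pairs <- list(
  "C-N" = c(De = 8.0, a = 3.0, re = 3.2),
  "C-H" = c(De = 4.5, a = 4.0, re = 1.1),
  "H-N" = c(De = 3.8, a = 4.0, re = 1.0),
  "H-H" = c(De = 4.5, a = 1.9, re = 0.74),
  "default" = c(De = 1.0, a = 1.7, re = 2.0)
)

morse_pair_key <- function(s1, s2) paste(sort(c(s1, s2)), collapse = "-")

morse_pair_params <- function(parameters) {
  pairs <- morse_default_pairs
  user <- parameters$pairs %||% list()
  for (nm in names(user)) {
    v <- user[[nm]]
    key <- morse_pair_key(strsplit(nm, "-")[[1]][1], strsplit(nm, "-")[[1]][2])
    pairs[[key]] <- c(De = as.numeric(v[["De"]] %||% v[[1]]),
                      a = as.numeric(v[["a"]] %||% v[[2]]),
                      re = as.numeric(v[["re"]] %||% v[[3]]))
  }
  pairs
}

morse_cluster_eval <- function(config, parameters) {
  n <- n_atoms(config)
  if (n < 2L) stop("morse_cluster needs at least two atoms")
  pairs <- morse_pair_params(parameters %||% list())
  pos <- config$positions
  energy <- 0
  forces <- matrix(0, n, 3L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dvec <- pos[i, ] - pos[j, ]
      d <- sqrt(sum(dvec^2))
      if (d < 1e-8) stop("coincident atoms in morse_cluster")
      key <- morse_pair_key(config$species[i], config$species[j])
      p <- pairs[[key]] %||% pairs[["default"]]
      ex <- exp(-p[["a"]] * (d - p[["re"]]))
      energy <- energy + p[["De"]] * (ex^2 - 2 * ex)
      # dV/dd = De * (-2 a ex^2 + 2 a ex)
      dVdd <- 2 * p[["De"]] * p[["a"]] * (ex - ex^2)
      fvec <- -dVdd * dvec / d
      forces[i, ] <- forces[i, ] + fvec
      forces[j, ] <- forces[j, ] - fvec
    }
  }
  list(energy = energy, forces = forces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

register_builtin_potentials <- function() {
  register_potential("muller_brown", muller_brown_eval)
  register_potential("morse_cluster", morse_cluster_eval)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_potentials()
}
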