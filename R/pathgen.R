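#' Path-generation parameters
#'
#' @param n_images Total image count including endpoints (default 18).
#' @param alpha Sequential-growth step-size parameter in (0, 1): each new
#'   image is seeded at fraction `alpha` of the way from its frontier
#'   toward the opposite frontier (default 0.33).
#' @param mode One of `"sidpp"` (sequential growth, default), `"idpp"`
#'   (all-at-once interpolation then relaxation) or `"linear"`.
#' @param idpp_force_tol Convergence threshold for the image-dependent
#'   pair-potential relaxation (default 0.01, objective units per
#'   Angstrom).
#' @param idpp_max_iter Relaxation iteration cap per growth step / run
#'   (default 200).
#' @param spring_constant Uniform spring constant used for band relaxation
#'   on the pair-potential surface (default 5).
#' @return An object of class `pathgen_params`.
#' @export
pathgen_params <- function(n_images = 18L, alpha = 0.33, mode = c("sidpp", "idpp", "linear"),
                           idpp_force_tol = 0.01, idpp_max_iter = 200L,
                           spring_constant = 5) {
  mode <- match.arg(mode)
  n_images <- as.integer(n_images)
  if (n_images < 3L) stop("n_images must be at least 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  structure(list(n_images = n_images, alpha = alpha, mode = mode,
                 idpp_force_tol = idpp_force_tol,
                 idpp_max_iter = as.integer(idpp_max_iter),
                 spring_constant = spring_constant),
            class = "pathgen_params")
}

#' Interpolated pair-distance targets
#'
#' Entry (i, j) is the linear interpolation
#' `(1 - fraction) * d_ij(R) + fraction * d_ij(P)` between the endpoint
#' distance matrices; the diagonal is zero.
#'
#' @param R,P Aligned endpoint `configuration`s, same composition.
#' @param fraction Interpolation fraction in \[0, 1\].
#' @return Symmetric N x N matrix, Angstrom.
#' @export
pair_distance_targets <- function(R, P, fraction) {
  if (!same_composition(R, P)) stop("inconsistent endpoint composition")
  stopifnot(fraction >= 0, fraction <= 1)
  (1 - fraction) * pairwise_distances(R$positions) +
    fraction * pairwise_distances(P$positions)
}

#' Image-dependent pair-potential objective
#'
#' The interpolation surface `S = sum_(i<j) d_ij^-4 (t_ij - d_ij)^2` with
#' analytic forces `-grad S` (the distance-dependent weight is
#' differentiated too). `S` is zero exactly when every pair distance meets
#' its target. Structures with a single atom have no pairs and evaluate to
#' zero energy and forces.
#'
#' @param config A `configuration`.
#' @param targets Symmetric N x N target-distance matrix, zero diagonal.
#' @return List with `energy` and `forces` in the objective's units.
#' @export
idpp_objective <- function(config, targets) {
  stopifnot_configuration(config)
  n <- n_atoms(config)
  targets <- as.matrix(targets)
  if (!all(dim(targets) == n)) stop("targets must be N x N")
  pos <- config$positions
  energy <- 0
  forces <- matrix(0, n, 3L)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dvec <- pos[i, ] - pos[j, ]
        d <- sqrt(sum(dvec^2))
        if (d < 1e-6) stop("coincident atoms: singular pair-potential weight")
        t_ij <- targets[i, j]
        w <- d^-4
        energy <- energy + w * (t_ij - d)^2
        # dS/dd = -4 d^-5 (t-d)^2 - 2 d^-4 (t-d)
        dSdd <- -4 * d^-5 * (t_ij - d)^2 - 2 * w * (t_ij - d)
        fvec <- -dSdd * dvec / d
        forces[i, ] <- forces[i, ] + fvec
        forces[j, ] <- forces[j, ] - fvec
      }
    }
  }
  list(energy = energy, forces = forces)
}

#' Linear Cartesian interpolation between endpoints
#'
#' @param R,P Aligned endpoint `configuration`s.
#' @param n_images Total frame count including endpoints (>= 3).
#' @return List of `n_images` configurations; the first and last are exact
#'   copies of the endpoints.
#' @export
interpolate_linear <- function(R, P, n_images) {
  n_images <- as.integer(n_images)
  if (n_images < 3L) stop("n_images must be at least 3")
  if (!same_composition(R, P)) stop("inconsistent endpoint composition")
  out <- vector("list", n_images)
  out[[1L]] <- R; out[[n_images]] <- P
  for (k in 2L:(n_images - 1L)) {
    f <- (k - 1) / (n_images - 1)
    out[[k]] <- with_positions(R, (1 - f) * R$positions + f * P$positions)
  }
  out
}

# Relax the interior images of `images` on the pair-potential surface with
# plain (uniform) springs and frozen endpoints; per-image targets use the
# index-based arc fraction. Reuses the band projection machinery.
idpp_relax_interior <- function(images, R, P, params) {
  m <- length(images)
  if (m < 3L) return(images)
  targets <- lapply(seq_len(m), function(k)
    pair_distance_targets(R, P, (k - 1) / (m - 1)))
  surface <- function(k, config) idpp_objective(config, targets[[k]])
  relax_band_on(images, surface, spring_constant = params$spring_constant,
                force_tol = params$idpp_force_tol,
                max_iterations = params$idpp_max_iter,
                max_move = 0.1)
}

#' Standard IDPP initial path
#'
#' Linear Cartesian seed, then all interior images relaxed together on the
#' image-dependent pair-potential surface (plain springs, frozen
#' endpoints).
#'
#' @param R,P Aligned endpoint `configuration`s.
#' @param params A [pathgen_params()].
#' @return List of `params$n_images` configurations.
#' @export
idpp_path <- function(R, P, params = pathgen_params()) {
  images <- interpolate_linear(R, P, params$n_images)
  idpp_relax_interior(images, R, P, params)
}

#' Sequential IDPP (SIDPP) initial path
#'
#' Grows the band from the bare endpoint pair: one image is inserted at a
#' time, alternating between the reactant and the product side (reactant
#' first). Each new image is seeded at fraction `alpha` along the straight
#' segment from its side's frontier (the most recently fixed image on that
#' side) toward the opposite frontier; after every insertion all interior
#' images are re-relaxed on the pair-potential surface before the next
#' insertion. Growth stops at `n_images` total; the endpoints never move.
#' The incremental growth keeps every intermediate collision-free, which
#' simultaneous interpolation cannot guarantee for rearrangements whose
#' straight-line paths clash atoms.
#'
#' @param R,P Aligned endpoint `configuration`s.
#' @param params A [pathgen_params()].
#' @param growth_log Optional environment; when supplied, a character
#'   vector `$sides` records the insertion side sequence (instrumentation
#'   for tests).
#' @return List of `params$n_images` configurations; first and last are
#'   the input endpoints unchanged.
#' @export
sidpp_path <- function(R, P, params = pathgen_params(), growth_log = NULL) {
  if (!same_composition(R, P)) stop("inconsistent endpoint composition")
  images <- list(R, P)
  frontier_r <- 1L                       # index of reactant-side frontier
  side <- "reactant"
  while (length(images) < params$n_images) {
    frontier_p <- frontier_r + 1L        # product-side frontier is adjacent
    pos_r <- images[[frontier_r]]$positions
    pos_p <- images[[frontier_p]]$positions
    if (side == "reactant") {
      seed <- pos_r + params$alpha * (pos_p - pos_r)
      at <- frontier_r + 1L
    } else {
      seed <- pos_p + params$alpha * (pos_r - pos_p)
      at <- frontier_p
    }
    new_img <- with_positions(R, seed)
    images <- append(images, list(new_img), after = at - 1L)
    if (side == "reactant") frontier_r <- frontier_r + 1L
    if (!is.null(growth_log)) growth_log$sides <- c(growth_log$sides, side)
    images <- idpp_relax_interior(images, R, P, params)
    side <- if (side == "reactant") "product" else "reactant"
  }
  images[[1L]] <- R
  images[[length(images)]] <- P
  images
}

#' Generate an initial path
#'
#' Dispatches on `params$mode` (`sidpp`, `idpp` or `linear`).
#'
#' @inheritParams sidpp_path
#' @return List of configurations.
#' @export
generate_path <- function(R, P, params = pathgen_params()) {
  switch(params$mode,
         sidpp = sidpp_path(R, P, params),
         idpp = idpp_path(R, P, params),
         linear = interpolate_linear(R, P, params$n_images))
}
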