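#' Deterministic test-system fixtures
#'
#' Generates endpoint pairs (plus the matching potential) for the built-in
#' surfaces so every pipeline stage can be exercised without external
#' data. Endpoints are placed near — deliberately not at — the basins so
#' minimization has work to do. The same `(name, seed, size)` always
#' yields the identical fixture; randomness never leaks into the caller's
#' RNG state.
#'
#' @param name One of `"mb_particle"` (single particle on the 2D
#'   benchmark surface), `"morse_dimer"`, `"surrogate_triatomic"` (the
#'   H/C/N proton-hop surrogate) or `"random_cluster"`.
#' @param seed Integer seed (used by `random_cluster` and the jitter).
#' @param size Atom count, `random_cluster` only.
#' @return List with `reactant`, `product` (`configuration`s) and
#'   `potential` (a [potential_spec()]).
#' @export
make_fixture <- function(name = c("mb_particle", "morse_dimer",
                                  "surrogate_triatomic", "random_cluster"),
                         seed = 1L, size = 6L) {
  name <- match.arg(name)
  switch(name,
    mb_particle = list(
      # near (not at) the two outer basins of the benchmark surface
      reactant = configuration("X", matrix(c(-0.50, 1.50, 0), 1L)),
      product = configuration("X", matrix(c(0.70, 0.10, 0), 1L)),
      potential = potential_spec("muller_brown")
    ),
    morse_dimer = list(
      # H2-like pair, stretched/compressed about the 0.74 A equilibrium
      reactant = configuration(c("H", "H"), rbind(c(0, 0, 0), c(0.90, 0, 0))),
      product = configuration(c("H", "H"), rbind(c(0, 0, 0), c(0.65, 0, 0))),
      potential = potential_spec("morse_cluster")
    ),
    surrogate_triatomic = list(
      # proton on the C side vs the N side of a stiff long C--N scaffold
      reactant = configuration(c("C", "N", "H"),
                               rbind(c(0, 0, 0), c(3.2, 0, 0), c(1.15, 0.05, 0))),
      product = configuration(c("C", "N", "H"),
                              rbind(c(0, 0, 0), c(3.2, 0, 0), c(2.15, -0.05, 0))),
      potential = potential_spec("morse_cluster")
    ),
    random_cluster = with_preserved_seed(seed, {
      size <- as.integer(size)
      if (size < 2L) stop("random_cluster needs size >= 2")
      species <- rep(c("H", "C"), length.out = size)
      # rejection-sample positions with a minimum separation
      repeat {
        pos <- matrix(stats::runif(size * 3L, 0, 2.5), size)
        if (size == 1L || min(stats::dist(pos)) > 0.8) break
      }
      jitter <- matrix(stats::rnorm(size * 3L, sd = 0.05), size)
      perm <- species_preserving_permutation(species)
      Q <- random_rotation()
      prod_pos <- (pos + jitter)[perm, , drop = FALSE] %*% t(Q)
      prod_pos <- sweep(prod_pos, 2L, stats::runif(3L, -1, 1), `+`)
      list(
        reactant = configuration(species, pos),
        product = configuration(species[perm], prod_pos),
        potential = potential_spec("morse_cluster")
      )
    })
  )
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  A <- matrix(stats::rnorm(9L), 3L)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

species_preserving_permutation <- function(species) {
  perm <- seq_along(species)
  for (sp in unique(species)) {
    ix <- which(species == sp)
    if (length(ix) > 1L) perm[ix] <- sample(ix)
  }
  perm
}

#' Write a fixture to disk
#'
#' Emits `reactant.xyz`, `product.xyz` and a YAML run-configuration stub
#' pointing at them.
#'
#' @param fixture A fixture from [make_fixture()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the config path.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rp <- file.path(dir, "reactant.xyz")
  pp <- file.path(dir, "product.xyz")
  write_xyz(fixture$reactant, rp)
  write_xyz(fixture$product, pp)
  cfg <- list(reactant = rp, product = pp,
              potential = list(name = fixture$potential$name),
              workdir = file.path(dir, "run"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

#' Newton stationary-point oracle
#'
#' Independent verification tool: damped Newton iteration on the analytic
#' gradient with a central finite-difference Hessian (`h = 1e-4`), run to
#' `||g|| < 1e-10`, followed by a Morse-index count of negative Hessian
#' eigenvalues. Singular directions (the benchmark surface's flat z axis,
#' rigid-body modes of clusters) are handled by a pseudoinverse Newton
#' step and excluded from the index by an eigenvalue threshold. The oracle
#' deliberately shares no code with the band or refinement modules.
#'
#' @param spec A [potential_spec()].
#' @param start Starting `configuration`.
#' @param h Finite-difference step for the Hessian, Angstrom.
#' @param tol Gradient-norm convergence target.
#' @param max_iter Iteration cap; divergence is an oracle failure (error).
#' @param zero_tol Eigenvalues in `(-zero_tol, zero_tol)` count as
#'   singular, not negative.
#' @return List with `config` (stationary point, energy set), `index`
#'   (Morse index), `eigenvalues` (Hessian spectrum).
#' @export
newton_stationary_oracle <- function(spec, start, h = 1e-4, tol = 1e-10,
                                     max_iter = 200L, zero_tol = 1e-5) {
  n <- n_atoms(start)
  x <- flatten_positions(start)
  grad_at <- function(x) -as.numeric(t(evaluate_potential(spec, with_positions(start, x))$forces))
  hess_at <- function(x) {
    k <- length(x)
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      H[, j] <- (grad_at(xp) - grad_at(xm)) / (2 * h)
    }
    (H + t(H)) / 2
  }
  pinv_solve <- function(H, g, rcond = 1e-8) {
    sv <- svd(H)
    keep <- sv$d > rcond * max(sv$d)
    dinv <- ifelse(keep, 1 / sv$d, 0)
    sv$v %*% (dinv * (t(sv$u) %*% g))
  }
  g <- grad_at(x)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(g^2)) < tol) break
    H <- hess_at(x)
    step <- -as.numeric(pinv_solve(H, g))
    sn <- sqrt(sum(step^2))
    if (sn > 0.25) step <- step * (0.25 / sn)   # damping for far starts
    x <- x + step
    g <- grad_at(x)
    if (it == max_iter && sqrt(sum(g^2)) >= tol)
      stop("Newton oracle failed to converge (test-infrastructure error)")
  }
  H <- hess_at(x)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  cfg <- with_positions(start, x)
  out <- evaluate_potential(spec, cfg)
  cfg$energy <- out$energy
  cfg$forces <- out$forces
  list(config = cfg, index = sum(ev < -zero_tol), eigenvalues = ev)
}
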