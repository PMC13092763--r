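# Independent oracles and shared (lazily computed, cached) expensive runs.
# Oracles deliberately avoid the code paths they verify.

# -- deterministic RNG helpers ----------------------------------------------

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

random_rotation_oracle <- function() {
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# -- exhaustive permutation x Kabsch alignment oracle -----------------------

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

brute_force_rmsd <- function(X, Y, species) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  best <- Inf
  for (p in all_permutations(seq_len(n))) {
    if (any(species != species[p])) next
    Q <- kabsch_rotation(Xc, Yc[p, , drop = FALSE])
    r <- sqrt(sum((Xc - Yc[p, , drop = FALSE] %*% t(Q))^2) / n)
    if (r < best) best <- r
  }
  best
}

# -- quadratic test surface with a known Hessian ----------------------------

register_quadratic_surface <- function(H, x_center) {
  register_potential("quadratic_test", function(config, parameters) {
    x <- as.numeric(t(config$positions)) - x_center
    g <- as.numeric(H %*% x)
    list(energy = 0.5 * sum(x * g),
         forces = matrix(-g, ncol = 3, byrow = TRUE))
  })
  invisible(NULL)
}

# -- steepest-descent MEP trace from a saddle (oracle for band geometry) ----

flat_pos <- function(cfg) as.numeric(t(cfg$positions))

cfg_at <- function(template, x) {
  configuration(template$species, matrix(x, ncol = 3, byrow = TRUE),
                cell = template$cell)
}

# The MEP is the gradient-flow (steepest-descent) trajectory from the
# saddle; the transverse directions are stiff, so it is integrated with
# an implicit solver rather than explicit Euler.
mep_trace_from_saddle <- function(spec, saddle_cfg, unstable_mode,
                                  t_end = 50, n_times = 4000L) {
  deriv <- function(t, x, parms) {
    list(as.numeric(t(evaluate_potential(spec, cfg_at(saddle_cfg, x))$forces)))
  }
  times <- c(0, exp(seq(log(1e-4), log(t_end), length.out = n_times)))
  trace_side <- function(sign_dir) {
    x0 <- flat_pos(saddle_cfg) + sign_dir * 1e-2 * unstable_mode
    sol <- deSolve::lsoda(x0, times, deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-10)
    unname(sol[, -1, drop = FALSE])
  }
  left <- trace_side(-1)
  rbind(left[rev(seq_len(nrow(left))), , drop = FALSE],
        matrix(flat_pos(saddle_cfg), 1),
        trace_side(1))
}

# distance from a point to a polyline, with projection onto segments
dist_to_polyline <- function(pt, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- sweep(a, 2, pt, `-`)
  denom <- rowSums(ab^2)
  t <- ifelse(denom > 0, pmin(pmax(-rowSums(ap * ab) / denom, 0), 1), 0)
  closest <- a + ab * t
  min(sqrt(rowSums(sweep(closest, 2, pt)^2)))
}

# -- shared cached runs -----------------------------------------------------

.cache <- new.env(parent = emptyenv())

# Benchmark-surface pipeline: fixtures -> minimize -> (trivial alignment)
# -> sequential growth -> CI-NEB -> minimum-mode refinement. The 2D
# benchmark uses 12 images and a 5e-3 eV/A force threshold scaled to its
# (large) energy scale.
mb_pipeline <- function() {
  if (is.null(.cache$mb)) {
    fx <- make_fixture("mb_particle")
    mp <- minimize_params()
    rmin <- lbfgs_minimize(fx$potential, fx$reactant, mp)$config
    pmin <- lbfgs_minimize(fx$potential, fx$product, mp)$config
    path <- sidpp_path(rmin, pmin, pathgen_params(n_images = 12))
    np <- neb_params(force_tol = 1e-3, max_iterations = 12000)
    res <- optimize_band(path, fx$potential, np)
    .cache$mb <- list(fixture = fx, reactant = rmin, product = pmin,
                      path = path, result = res, params = np)
  }
  .cache$mb
}

mb_saddle_oracle <- function() {
  if (is.null(.cache$mb_saddle)) {
    run <- mb_pipeline()
    ci <- run$result$state$images[[run$result$state$climbing_index]]
    .cache$mb_saddle <- newton_stationary_oracle(run$fixture$potential, ci)
  }
  .cache$mb_saddle
}

# Full benchmark-surface MEP: steepest-descent traces from both oracle
# saddles, concatenated.
mb_full_mep <- function() {
  if (is.null(.cache$mb_mep)) {
    mb <- potential_spec("muller_brown")
    saddle_starts <- list(c(-0.7, 0.6, 0), c(0.2, 0.3, 0))
    traces <- lapply(saddle_starts, function(s0) {
      or <- newton_stationary_oracle(mb, configuration("X", matrix(s0, 1)))
      stopifnot(or$index == 1)
      mode <- dimer_lowest_mode(mb, or$config, c(1, 0, 0), max_rotations = 200)$mode
      mep_trace_from_saddle(mb, or$config, mode)
    })
    .cache$mb_mep <- do.call(rbind, traces)
  }
  .cache$mb_mep
}

# Orchestrator demo on the triatomic surrogate: initial run, no-op rerun,
# reactant edit + rerun. Cached because three full pipeline passes are
# shared between the orchestrator unit tests and the acceptance suite.
orchestrator_demo <- function() {
  if (is.null(.cache$orch)) {
    wd <- tempfile("nebflow-orch-")
    dir.create(wd)
    fx <- make_fixture("surrogate_triatomic")
    write_xyz(fx$reactant, file.path(wd, "reactant.xyz"))
    write_xyz(fx$product, file.path(wd, "product.xyz"))
    cfg <- run_config(file.path(wd, "reactant.xyz"), file.path(wd, "product.xyz"),
                      potential = fx$potential, workdir = file.path(wd, "run"))
    first <- run_pipeline(cfg)
    second <- run_pipeline(cfg)
    R <- read_xyz(file.path(wd, "reactant.xyz"))[[1]]
    R$positions[3, 2] <- R$positions[3, 2] + 0.01
    write_xyz(R, file.path(wd, "reactant.xyz"))
    third <- run_pipeline(cfg)
    .cache$orch <- list(wd = wd, config = cfg, first = first, second = second,
                        third = third)
  }
  .cache$orch
}
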