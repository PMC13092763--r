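#' Alignment parameters
#'
#' @param k_max Candidate-generation strictness, 1/Angstrom. Candidate
#'   rotation starts are built from atom-pair frames whose pair separation
#'   is at least `1/k_max`; a larger `k_max` admits more (and more
#'   degenerate) frames, i.e. a more exhaustive search. Default 1.8.
#' @param multistart_count Cap on the number of candidate rotation starts.
#' @param convergence_tol Stop the assignment/rotation alternation when the
#'   RMSD improves by less than this (Angstrom).
#' @param max_atoms Hard feasibility cap on N; the joint
#'   rotation-permutation search is impractical for extended systems.
#' @return An object of class `align_params`.
#' @export
align_params <- function(k_max = 1.8, multistart_count = 1000L,
                         convergence_tol = 1e-10, max_atoms = 256L) {
  stopifnot(k_max > 0, multistart_count >= 1L, convergence_tol > 0)
  structure(list(k_max = k_max, multistart_count = as.integer(multistart_count),
                 convergence_tol = convergence_tol, max_atoms = as.integer(max_atoms)),
            class = "align_params")
}

#' Optimal proper rotation between two centered point sets (Kabsch)
#'
#' Returns the rotation `Q` in SO(3) minimizing `||X - Q Y||_F` for
#' centroid-centered `X`, `Y`. Reflections are excluded by the usual
#' determinant correction.
#'
#' @param X,Y Numeric N x 3 matrices with centroids at the origin.
#' @return 3 x 3 proper rotation matrix.
#' @export
kabsch_rotation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L)
    stop("kabsch_rotation: X and Y must be matching N x 3 matrices")
  M <- crossprod(Y, X)            # sum_i y_i x_i^T
  sv <- svd(M)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) for a square cost
# matrix; returns assign[i] = column matched to row i. Deterministic scan
# order gives lowest-index preference among ties.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  if (n == 1L) return(1L)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      u[p[n + 1L]] <- u[p[n + 1L]] + delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j]] <- j
  assign
}

#' Species-constrained optimal assignment
#'
#' Finds the permutation `perm` minimizing `sum_i ||X[i,] - Y[perm[i],]||^2`
#' subject to `species[i] == species[perm[i]]`. Solved exactly (Hungarian
#' algorithm per species block), not greedily.
#'
#' @param X,Y Numeric N x 3 coordinate matrices.
#' @param species Character vector for `X`'s rows.
#' @param species_y Character vector for `Y`'s rows (defaults to `species`).
#' @return Integer permutation: row `i` of `X` is matched to row `perm[i]`
#'   of `Y`.
#' @export
optimal_assignment <- function(X, Y, species, species_y = species) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(sort(species), sort(species_y)))
    stop("inconsistent endpoint composition")
  n <- nrow(X)
  perm <- integer(n)
  for (sp in unique(species)) {
    ix <- which(species == sp)
    iy <- which(species_y == sp)
    if (length(ix) == 1L) { perm[ix] <- iy; next }
    block <- matrix(0, length(ix), length(iy))
    for (a in seq_along(ix))
      block[a, ] <- colSums((t(Y[iy, , drop = FALSE]) - X[ix[a], ])^2)
    assign <- hungarian_assign(block)
    perm[ix] <- iy[assign]
  }
  perm
}

# Orthonormal frame from two (centered) position vectors; NULL when
# degenerate (zero-length or collinear).
frame_from_vectors <- function(v1, v2, eps = 1e-8) {
  n1 <- sqrt(sum(v1^2))
  if (n1 < eps) return(NULL)
  e1 <- v1 / n1
  w <- v2 - sum(v2 * e1) * e1
  n2 <- sqrt(sum(w^2))
  if (n2 < eps) return(NULL)
  e2 <- w / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

# Candidate rotation starts for the joint search: identity, the naive
# Kabsch fit, and frame-matching rotations built from species-compatible
# atom pairs (separation >= 1/k_max) in reference and mobile.
candidate_rotations <- function(Xc, Yc, species_x, species_y, params) {
  cands <- list(diag(3))
  n <- nrow(Xc)
  if (identical(species_x, species_y))
    cands[[length(cands) + 1L]] <- kabsch_rotation(Xc, Yc)
  if (n >= 2L) {
    min_sep <- 1 / params$k_max
    pair_ok <- function(P, i, j) sqrt(sum((P[i, ] - P[j, ])^2)) >= min_sep
    ref_pairs <- list(); mob_pairs <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (pair_ok(Xc, i, j)) ref_pairs[[length(ref_pairs) + 1L]] <- c(i, j)
      if (pair_ok(Yc, i, j)) mob_pairs[[length(mob_pairs) + 1L]] <- c(i, j)
    }
    for (rp in ref_pairs) {
      Fr <- frame_from_vectors(Xc[rp[1], ], Xc[rp[2], ])
      if (is.null(Fr)) next
      for (mp in mob_pairs) {
        if (species_x[rp[1]] != species_y[mp[1]] ||
            species_x[rp[2]] != species_y[mp[2]]) next
        Fm <- frame_from_vectors(Yc[mp[1], ], Yc[mp[2], ])
        if (is.null(Fm)) next
        cands[[length(cands) + 1L]] <- Fr %*% t(Fm)
        if (length(cands) >= params$multistart_count) return(cands)
      }
    }
  }
  cands
}

#' Joint rotation-permutation alignment
#'
#' Aligns `mobile` onto `reference` by alternating exact species-constrained
#' assignment and Kabsch rotation from multiple deterministic rotation
#' starts, keeping the best permutation-invariant RMSD found. The returned
#' transform maps mobile atom `perm[i]` onto reference atom `i`:
#' `Q %*% mobile$positions[perm[i], ] + t ~ reference$positions[i, ]`.
#'
#' @param mobile,reference `configuration` objects with identical species
#'   multisets.
#' @param params An [align_params()].
#' @return Object of class `alignment_result` with fields `rotation` (3 x 3,
#'   det +1), `permutation` (integer, reference index -> mobile index),
#'   `translation` (length 3, Angstrom) and `rmsd` (Angstrom, the
#'   per-atom-normalized residual at the optimum).
#' @export
ira_align <- function(mobile, reference, params = align_params()) {
  stopifnot_configuration(mobile); stopifnot_configuration(reference)
  if (!same_composition(mobile, reference))
    stop("inconsistent endpoint composition")
  n <- n_atoms(mobile)
  if (n > params$max_atoms)
    stop(sprintf("alignment infeasible: %d atoms exceeds the %d-atom cap",
                 n, params$max_atoms))
  cx <- colMeans(reference$positions); cy <- colMeans(mobile$positions)
  Xc <- sweep(reference$positions, 2L, cx)
  Yc <- sweep(mobile$positions, 2L, cy)
  spx <- reference$species; spy <- mobile$species

  refine <- function(Q) {
    rmsd_prev <- Inf
    perm <- seq_len(n)
    for (iter in 1:60) {
      Yrot <- Yc %*% t(Q)
      perm <- optimal_assignment(Xc, Yrot, spx, spy)
      Q <- kabsch_rotation(Xc, Yc[perm, , drop = FALSE])
      resid <- Xc - Yc[perm, , drop = FALSE] %*% t(Q)
      rmsd <- sqrt(sum(resid^2) / n)
      if (rmsd_prev - rmsd < params$convergence_tol) break
      rmsd_prev <- rmsd
    }
    list(Q = Q, perm = perm, rmsd = rmsd)
  }

  best <- NULL
  for (Q0 in candidate_rotations(Xc, Yc, spx, spy, params)) {
    cand <- refine(Q0)
    if (is.null(best) || cand$rmsd < best$rmsd) best <- cand
  }
  translation <- as.numeric(cx - best$Q %*% cy)
  structure(list(rotation = best$Q, permutation = best$perm,
                 translation = translation, rmsd = best$rmsd),
            class = "alignment_result")
}

#' Apply an alignment result to the mobile configuration
#'
#' Reorders, rotates and translates `mobile` into the reference frame and
#' atom ordering.
#'
#' @param result An `alignment_result` from [ira_align()].
#' @param mobile The configuration that was aligned.
#' @return The transformed `configuration` (energies/forces dropped).
#' @export
apply_alignment <- function(result, mobile) {
  stopifnot_configuration(mobile)
  pos <- mobile$positions[result$permutation, , drop = FALSE] %*% t(result$rotation)
  pos <- sweep(pos, 2L, result$translation, `+`)
  out <- mobile
  out$species <- mobile$species[result$permutation]
  out$positions <- pos
  out$energy <- NULL
  if (!is.null(out$forces))
    out$forces <- mobile$forces[result$permutation, , drop = FALSE] %*% t(result$rotation)
  out
}

#' Permutation-invariant RMSD
#'
#' `d(X, Xref) = min over Q in SO(3), species-preserving permutations Pi of
#' sqrt( ||X - Q Xref Pi||_F^2 / N )`, with both structures
#' centroid-centered. Always at most the naive (identity rotation and
#' permutation) RMSD.
#'
#' @param X,Xref `configuration` objects with identical species multisets.
#' @param params An [align_params()].
#' @return Scalar RMSD, Angstrom.
#' @export
permutation_invariant_rmsd <- function(X, Xref, params = align_params()) {
  ira_align(mobile = Xref, reference = X, params = params)$rmsd
}

#' Two-stage endpoint preparation
#'
#' Stage 1 centers both raw endpoints in the cell and aligns the product
#' onto the reactant (establishing a consistent atom mapping); stage 2
#' minimizes both endpoints on the chosen surface, then re-aligns the
#' minimized product onto the minimized reactant to correct any mapping
#' drift introduced by relaxation. The final RMSD is returned for
#' verification and logging.
#'
#' @param reactant,product Raw endpoint `configuration`s, same composition.
#' @param align_params An [align_params()].
#' @param min_params A [minimize_params()].
#' @param spec A [potential_spec()].
#' @param cell_lengths Simulation cell edges, Angstrom (default 25^3).
#' @return List with `reactant`, `product` (prepared endpoints) and `rmsd`
#'   (final permutation-invariant RMSD between them, Angstrom).
#' @export
two_stage_prepare <- function(reactant, product, align_params = nebflow::align_params(),
                              min_params = minimize_params(), spec,
                              cell_lengths = c(25, 25, 25)) {
  if (!same_composition(reactant, product))
    stop("inconsistent endpoint composition")
  # stage 1: center + align raw endpoints
  r1 <- center_in_cell(reactant, cell_lengths)
  p1 <- center_in_cell(product, cell_lengths)
  a1 <- ira_align(mobile = p1, reference = r1, params = align_params)
  p1 <- center_in_cell(apply_alignment(a1, p1), cell_lengths)
  # stage 2: minimize, then re-align
  rmin <- lbfgs_minimize(spec, r1, min_params)$config
  pmin <- lbfgs_minimize(spec, p1, min_params)$config
  a2 <- ira_align(mobile = pmin, reference = rmin, params = align_params)
  pfin <- apply_alignment(a2, pmin)
  pfin$energy <- pmin$energy
  list(reactant = rmin, product = pfin, rmsd = a2$rmsd)
}
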