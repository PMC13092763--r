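#' Scalar reaction coordinates for a band
#'
#' Three variants: `index` (0, 1, ..., m-1), `path_length` (cumulative
#' inter-image Frobenius distances) and `rmsd_reactant`
#' (permutation-invariant RMSD of each image to image 1). With
#' `normalize_per_atom = TRUE` (default) path-length segments are divided
#' by `sqrt(N)` so both coordinate families share the per-atom RMSD
#' normalization and `r_i <= s_i` holds; with `FALSE`, raw Frobenius norms
#' are used.
#'
#' @param band Non-empty list of configurations.
#' @param mode One of `"index"`, `"path_length"`, `"rmsd_reactant"`.
#' @param align_params An [align_params()] (used by `rmsd_reactant`).
#' @param normalize_per_atom Divide path-length segments by `sqrt(N)`.
#' @return Numeric vector of coordinates, one per image.
#' @export
profile_coordinates <- function(band, mode = c("index", "path_length", "rmsd_reactant"),
                                align_params = nebflow::align_params(),
                                normalize_per_atom = TRUE) {
  mode <- match.arg(mode)
  m <- length(band)
  if (!m) stop("empty band")
  switch(mode,
    index = as.numeric(seq_len(m) - 1L),
    path_length = {
      scale <- if (normalize_per_atom) sqrt(n_atoms(band[[1L]])) else 1
      segs <- if (m == 1L) numeric(0) else vapply(seq_len(m - 1L), function(j)
        sqrt(sum((band[[j + 1L]]$positions - band[[j]]$positions)^2)) / scale,
        numeric(1))
      cumsum(c(0, segs))
    },
    rmsd_reactant = vapply(band, permutation_invariant_rmsd, numeric(1),
                           Xref = band[[1L]], params = align_params)
  )
}

#' Tangential force values for profile nodes
#'
#' The component of the true force along the band tangent at each interior
#' image, `F . tau`; endpoints (where the band defines no tangent) get 0,
#' consistent with minimized endpoints.
#'
#' @param state A band state from [optimize_band()] (`$state`).
#' @return Numeric vector, one value per image, eV/Angstrom.
#' @export
tangential_forces <- function(state) {
  m <- length(state$images)
  out <- numeric(m)
  for (i in 2L:(m - 1L)) {
    f <- as.numeric(t(state$images[[i]]$forces))
    out[i] <- sum(f * state$tangents[[i]])
  }
  out
}

#' Derivative-constrained energy-profile interpolation
#'
#' Piecewise-cubic Hermite curve through `(coordinate, energy)` nodes with
#' the slope at node `i` fixed to the negated tangential force,
#' `dE/ds|_i = -F_par,i`. When the stored tangential force is the true
#' force's tangent component `F . tau = -dE/ds`, the negation restores the
#' physical slope. The curve passes through every node exactly.
#'
#' @param points Data frame with columns `coordinate` (strictly
#'   increasing), `energy`, `tangential_force`.
#' @return A function `f(x, deriv = 0)` evaluating the curve (`deriv = 0`)
#'   or its derivative (`deriv = 1`).
#' @export
constrained_profile_interpolation <- function(points) {
  s <- points$coordinate
  e <- points$energy
  slope <- -points$tangential_force
  if (length(s) < 2L) stop("need at least two profile points")
  if (any(diff(s) <= 0)) stop("duplicate or non-increasing coordinates")
  function(x, deriv = 0) {
    idx <- findInterval(x, s, rightmost.closed = TRUE, all.inside = TRUE)
    h <- s[idx + 1L] - s[idx]
    t <- (x - s[idx]) / h
    if (deriv == 0) {
      h00 <- 2 * t^3 - 3 * t^2 + 1
      h10 <- t^3 - 2 * t^2 + t
      h01 <- -2 * t^3 + 3 * t^2
      h11 <- t^3 - t^2
      h00 * e[idx] + h10 * h * slope[idx] + h01 * e[idx + 1L] + h11 * h * slope[idx + 1L]
    } else if (deriv == 1) {
      d00 <- (6 * t^2 - 6 * t) / h
      d10 <- 3 * t^2 - 4 * t + 1
      d01 <- (-6 * t^2 + 6 * t) / h
      d11 <- 3 * t^2 - 2 * t
      d00 * e[idx] + d10 * slope[idx] + d01 * e[idx + 1L] + d11 * slope[idx + 1L]
    } else stop("deriv must be 0 or 1")
  }
}

#' Decompose endpoint RMSDs into progress and deviation
#'
#' Planar triangulation placing the reactant at `s = 0` and the product at
#' `s = D` on the progress axis: `s = (r^2 - p^2 + D^2) / (2 D)`,
#' `d = sqrt(max(r^2 - s^2, 0))`. The clamp guards numerical
#' triangle-inequality violations.
#'
#' @param r RMSD to the reactant, Angstrom (>= 0).
#' @param p RMSD to the product, Angstrom (>= 0).
#' @param D Endpoint-to-endpoint RMSD, Angstrom (> 0).
#' @return Named numeric vector `c(s = ..., d = ...)`.
#' @export
sd_decomposition <- function(r, p, D) {
  if (D <= 0) stop("endpoints coincide: D must be positive")
  if (r < 0 || p < 0) stop("RMSDs must be non-negative")
  s <- (r^2 - p^2 + D^2) / (2 * D)
  d <- sqrt(max(r^2 - s^2, 0))
  c(s = s, d = d)
}

#' Project configurations onto the 2D (s, d) RMSD landscape
#'
#' For every sample, the permutation-invariant RMSDs to the reactant (`r`)
#' and product (`p`) are triangulated via [sd_decomposition()] into
#' reaction progress `s` and orthogonal deviation `d`; sample energies are
#' carried through. All band-history frames are usable as samples. The 2D
#' projection conventionally uses a stricter alignment (`k_max = 14`) than
#' endpoint preparation so landscapes are comparable across systems.
#'
#' @param samples List of configurations with energies set.
#' @param R,P Reactant and product configurations (`R != P`).
#' @param align_params An [align_params()]; default `k_max = 14`.
#' @return Data frame with columns `s`, `d`, `energy`.
#' @export
landscape_points <- function(samples, R, P,
                             align_params = nebflow::align_params(k_max = 14)) {
  D <- permutation_invariant_rmsd(P, R, align_params)
  if (D <= 0) stop("endpoints coincide: D must be positive")
  out <- data.frame(s = numeric(length(samples)), d = numeric(length(samples)),
                    energy = numeric(length(samples)))
  for (k in seq_along(samples)) {
    smp <- samples[[k]]
    r <- permutation_invariant_rmsd(smp, R, align_params)
    p <- permutation_invariant_rmsd(smp, P, align_params)
    sd <- sd_decomposition(r, p, D)
    out$s[k] <- sd[["s"]]; out$d[k] <- sd[["d"]]
    out$energy[k] <- smp$energy %||% NA_real_
  }
  out
}

#' Export a 1D profile as TSV
#'
#' @param band Band images (energies set).
#' @param state Band state (for tangential forces); optional.
#' @param path Output TSV path.
#' @param mode Coordinate variant, see [profile_coordinates()].
#' @param align_params An [align_params()].
#' @return Invisibly, the data frame written.
#' @export
write_profile_tsv <- function(band, state = NULL, path,
                              mode = "path_length",
                              align_params = nebflow::align_params()) {
  coord <- profile_coordinates(band, mode, align_params)
  tf <- if (!is.null(state)) tangential_forces(state) else rep(NA_real_, length(band))
  df <- data.frame(coordinate = coord,
                   energy = vapply(band, function(b) b$energy %||% NA_real_, numeric(1)),
                   tangential_force = tf)
  header <- sprintf("# coordinate (%s), energy (eV), tangential_force (eV/A)", mode)
  writeLines(header, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                      col.names = TRUE, quote = FALSE, append = TRUE))
  invisible(df)
}

#' Export a 2D landscape as TSV
#'
#' @param points Data frame from [landscape_points()].
#' @param path Output TSV path.
#' @return Invisibly, `points`.
#' @export
write_landscape_tsv <- function(points, path) {
  writeLines("# s (A), d (A), energy (eV)", path)
  suppressWarnings(utils::write.table(points, path, sep = "\t", row.names = FALSE,
                                      col.names = TRUE, quote = FALSE, append = TRUE))
  invisible(points)
}
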