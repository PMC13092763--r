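#' Read a (multi-frame) extended XYZ file
#'
#' Parses the widely used extended-XYZ dialect: an atom-count line, a
#' comment line of `key=value` tokens (`Lattice="..."`,
#' `Properties=species:S:1:pos:R:3[:forces:R:3]`, `energy=<eV>`), then one
#' line per atom (`symbol x y z [fx fy fz]`). Multiple frames are
#' concatenated.
#'
#' @param path File to read.
#' @return A list of [configuration()] objects, one per frame, species order
#'   preserved.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("malformed atom count at line %d: '%s'", i, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated frame starting at line %d", i))
    comment <- lines[i + 1L]
    fields <- parse_xyz_comment(comment)
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    ncols <- vapply(toks, length, integer(1))
    if (any(ncols < 4L))
      stop(sprintf("malformed atom line at line %d", i + 1L + which(ncols < 4L)[1L]))
    has_forces <- all(ncols >= 7L)
    species <- vapply(toks, `[[`, character(1), 1L)
    num <- function(k) vapply(toks, function(t) as.numeric(t[[k]]), numeric(1))
    positions <- cbind(num(2L), num(3L), num(4L))
    forces <- if (has_forces) cbind(num(5L), num(6L), num(7L)) else NULL
    configs[[length(configs) + 1L]] <- configuration(
      species = species, positions = positions, cell = fields$cell,
      energy = fields$energy, forces = forces, label = fields$label
    )
    i <- i + 2L + n
  }
  if (!length(configs)) stop(sprintf("no frames found in %s", path))
  configs
}

parse_xyz_comment <- function(comment) {
  out <- list(cell = NULL, energy = NULL, label = "")
  # key=value tokens, values optionally double-quoted
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|[^[:space:]]+)', comment)
  toks <- regmatches(comment, m)[[1]]
  kv <- list()
  for (tok in toks) {
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1L, eq - 1L)
    val <- substr(tok, eq + 1L, nchar(tok))
    val <- gsub('^"|"$', "", val)
    kv[[key]] <- val
  }
  if (!is.null(kv$Lattice)) {
    v <- as.numeric(strsplit(trimws(kv$Lattice), "[[:space:]]+")[[1]])
    if (length(v) == 9L && all(is.finite(v)))
      out$cell <- matrix(v, nrow = 3L, byrow = TRUE)
  }
  if (!is.null(kv$energy)) {
    e <- suppressWarnings(as.numeric(kv$energy))
    if (is.finite(e)) out$energy <- e
  }
  if (!is.null(kv$label)) out$label <- kv$label
  out
}

#' Write configurations as multi-frame extended XYZ
#'
#' @param configs A `configuration` or non-empty list of them.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(configs, path) {
  if (is_configuration(configs)) configs <- list(configs)
  if (!length(configs)) stop("refusing to write an empty configuration list")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cfg in configs) {
    stopifnot_configuration(cfg)
    n <- n_atoms(cfg)
    props <- "Properties=species:S:1:pos:R:3"
    if (!is.null(cfg$forces)) props <- paste0(props, ":forces:R:3")
    comment <- props
    if (!is.null(cfg$cell)) {
      lat <- paste(sprintf("%.10f", as.numeric(t(cfg$cell))), collapse = " ")
      comment <- sprintf('Lattice="%s" %s', lat, comment)
    }
    if (!is.null(cfg$energy))
      comment <- sprintf("%s energy=%.14g", comment, cfg$energy)
    if (nzchar(cfg$label))
      comment <- sprintf('%s label="%s"', comment, cfg$label)
    writeLines(as.character(n), con)
    writeLines(comment, con)
    for (a in seq_len(n)) {
      line <- sprintf("%-3s %.14f %.14f %.14f", cfg$species[a],
                      cfg$positions[a, 1L], cfg$positions[a, 2L], cfg$positions[a, 3L])
      if (!is.null(cfg$forces))
        line <- sprintf("%s %.14f %.14f %.14f", line,
                        cfg$forces[a, 1L], cfg$forces[a, 2L], cfg$forces[a, 3L])
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Center a configuration in an orthorhombic cell
#'
#' Translates the geometry so its geometric centroid sits at the cell
#' midpoint; interatomic distances are untouched. The returned
#' configuration carries the cell.
#'
#' @param config A `configuration`.
#' @param cell_lengths Length-3 positive vector of cell edges, Angstrom.
#' @return The translated `configuration`.
#' @export
center_in_cell <- function(config, cell_lengths) {
  stopifnot_configuration(config)
  cell_lengths <- as.numeric(cell_lengths)
  if (length(cell_lengths) != 3L || any(!is.finite(cell_lengths)) || any(cell_lengths <= 0))
    stop("cell_lengths must be three positive numbers")
  centroid <- colMeans(config$positions)
  shift <- cell_lengths / 2 - centroid
  config$positions <- sweep(config$positions, 2L, shift, `+`)
  config$cell <- diag(cell_lengths)
  config
}
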