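#' Default run configuration
#'
#' Assembles the full nested parameter set for a pipeline run. Presets
#' bundle suggested parameters by system size: `small` (5-20 atoms: 14
#' images, 0.051 eV/A force threshold, k_max 1.8/A, 25 A cell), `medium`
#' (20-50 atoms: 18 images, 0.051, k_max 2.5, 27 A) and `complex` (50+
#' atoms: 24 images, 0.026, k_max 4.0, 35 A). Explicit keys always win
#' over the preset.
#'
#' @param reactant_path,product_path Endpoint XYZ files.
#' @param potential A [potential_spec()] or list with `name`/`parameters`.
#' @param workdir Run directory for stage outputs and the manifest.
#' @param preset Optional `"small"`, `"medium"` or `"complex"`.
#' @param overrides Named list of nested overrides (e.g.
#'   `list(path = list(n_images = 12))`).
#' @return Nested configuration list of class `run_config`.
#' @export
run_config <- function(reactant_path, product_path,
                       potential = potential_spec("morse_cluster"),
                       workdir = "neb_run", preset = NULL, overrides = list()) {
  base <- list(
    reactant = reactant_path,
    product = product_path,
    potential = list(name = potential$name, parameters = potential$parameters),
    cell = c(25, 25, 25),
    align = list(k_max = 1.8, multistart_count = 1000L, convergence_tol = 1e-10),
    minimize = list(force_tol = hartree_bohr_to_ev_ang(1e-3),
                    max_iterations = 2000L, max_move = 0.1, history_size = 20L),
    path = list(mode = "sidpp", n_images = 18L, alpha = 0.33,
                idpp_force_tol = 0.01, idpp_max_iter = 200L),
    neb = list(force_tol = hartree_bohr_to_ev_ang(1e-3), max_iterations = 1000L,
               k_min = 0.972, k_max = 9.72, energy_weighted = TRUE,
               ci_activation_fraction = 0.8, mmf_switch_force = 0.5,
               mode_tangent_min_overlap = 0.8, snapshot_every = 10L),
    visualize = list(k_max_2d = 14),
    workdir = workdir
  )
  if (!is.null(preset)) {
    p <- switch(match.arg(preset, c("small", "medium", "complex")),
      small = list(path = list(n_images = 14L), align = list(k_max = 1.8),
                   neb = list(force_tol = 0.051), cell = c(25, 25, 25)),
      medium = list(path = list(n_images = 18L), align = list(k_max = 2.5),
                    neb = list(force_tol = 0.051), cell = c(27, 27, 27)),
      complex = list(path = list(n_images = 24L), align = list(k_max = 4.0),
                     neb = list(force_tol = 0.026), cell = c(35, 35, 35)))
    base <- modify_nested(base, p)
  }
  base <- modify_nested(base, overrides)
  class(base) <- "run_config"
  base
}

modify_nested <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_nested(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Missing keys are filled from [run_config()] defaults; a `preset` key is
#' applied first.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$reactant) || is.null(y$product))
    stop("config must name reactant and product endpoint files")
  pot <- potential_spec(y$potential$name %||% "morse_cluster",
                        y$potential$parameters %||% list())
  run_config(y$reactant, y$product, potential = pot,
             workdir = y$workdir %||% "neb_run", preset = y$preset,
             overrides = y[setdiff(names(y), c("reactant", "product", "potential",
                                               "workdir", "preset"))])
}

stage_path <- function(config, stage, file = "") {
  file.path(config$workdir, "results", stage, file)
}

# Static stage table: dependencies, the input files each stage hashes and
# the parameter subtrees that invalidate it. minimize_P deliberately
# consumes the *centered* product (a function of the product file and the
# cell only), so edits to the reactant never invalidate it; the rigid
# transform dropped here is fully re-established by align_post, and the
# minimizer is exactly equivariant under rigid transforms.
stage_table <- function(config) {
  list(
    align_pre = list(
      deps = character(0),
      files = c(config$reactant, config$product),
      subtrees = c("cell", "align"),
      outputs = c("reactant_centered.xyz", "product_centered.xyz",
                  "product_aligned.xyz", "rmsd.txt")),
    minimize_R = list(
      deps = "align_pre",
      files = stage_path(config, "align_pre", "reactant_centered.xyz"),
      subtrees = c("minimize", "potential"),
      outputs = c("minimized.xyz", "trajectory.xyz")),
    minimize_P = list(
      deps = "align_pre",
      files = stage_path(config, "align_pre", "product_centered.xyz"),
      subtrees = c("minimize", "potential"),
      outputs = c("minimized.xyz", "trajectory.xyz")),
    align_post = list(
      deps = c("minimize_R", "minimize_P"),
      files = c(stage_path(config, "minimize_R", "minimized.xyz"),
                stage_path(config, "minimize_P", "minimized.xyz")),
      subtrees = "align",
      outputs = c("endpoints.xyz", "rmsd.txt")),
    pathgen = list(
      deps = "align_post",
      files = stage_path(config, "align_post", "endpoints.xyz"),
      subtrees = "path",
      outputs = "band_initial.xyz"),
    band = list(
      deps = "pathgen",
      files = stage_path(config, "pathgen", "band_initial.xyz"),
      subtrees = c("neb", "potential"),
      outputs = c("band_final.xyz", "history.tsv", "snapshots.xyz")),
    visualize = list(
      deps = "band",
      files = c(stage_path(config, "band", "band_final.xyz"),
                stage_path(config, "band", "snapshots.xyz")),
      subtrees = "visualize",
      outputs = c("profile_index.tsv", "profile_path_length.tsv",
                  "profile_rmsd.tsv", "landscape.tsv"))
  )
}

#' Build the stage plan
#'
#' Topologically ordered stage list with dependencies: the two endpoint
#' minimizations depend on the pre-alignment and are mutually independent
#' (parallelizable); post-alignment needs both; path generation, band
#' optimization and visualization follow in sequence.
#'
#' @param config A `run_config`.
#' @return Data frame with columns `stage`, `deps`, `concurrent_group`.
#' @export
build_dag <- function(config) {
  tab <- stage_table(config)
  data.frame(
    stage = names(tab),
    deps = vapply(tab, function(s) paste(s$deps, collapse = ","), character(1)),
    concurrent_group = ifelse(names(tab) %in% c("minimize_R", "minimize_P"),
                              "minimize", ""),
    row.names = NULL
  )
}

#' Content hashes for a stage's inputs
#'
#' MD5 digests of each input file's bytes plus a digest of the relevant
#' parameter subtree (canonicalized by recursively sorted JSON
#' serialization). Byte-identical inputs always give identical digests;
#' modification times are ignored.
#'
#' @param paths Character vector of input files (must be readable).
#' @param params_subtree Structured parameter values for the stage.
#' @return Named character vector of digests.
#' @export
hash_inputs <- function(paths, params_subtree = NULL) {
  if (length(paths) && any(!file.exists(paths)))
    stop(sprintf("missing input file(s): %s",
                 paste(paths[!file.exists(paths)], collapse = ", ")))
  out <- if (length(paths)) tools::md5sum(paths) else character(0)
  names(out) <- paths
  if (!is.null(params_subtree)) {
    canon <- jsonlite::toJSON(sort_nested(params_subtree), auto_unbox = TRUE,
                              digits = NA)
    tmp <- tempfile()
    writeLines(as.character(canon), tmp)
    out <- c(out, params = unname(tools::md5sum(tmp)))
    unlink(tmp)
  }
  out
}

sort_nested <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, sort_nested)
  } else x
}

read_manifest <- function(config) {
  mf <- file.path(config$workdir, "manifest.json")
  if (file.exists(mf)) jsonlite::read_json(mf) else list()
}

write_manifest <- function(config, manifest) {
  mf <- file.path(config$workdir, "manifest.json")
  tmp <- paste0(mf, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, mf)
}

#' Execute the pipeline
#'
#' Runs stages in topological order. A stage executes only when any of
#' its input hashes differs from the stored manifest (or `force_rerun`);
#' otherwise it is reported `up_to_date`. The manifest is rewritten
#' atomically after every stage, so an interrupted run resumes with
#' exactly the remaining stages. A stage failure is recorded and halts
#' everything downstream of it; upstream results are preserved.
#'
#' @param config A `run_config` (see [run_config()], [read_run_config()]).
#' @param force_rerun Execute every stage regardless of hashes.
#' @param targets Optional character vector restricting execution to these
#'   stages (their upstream dependencies are still consulted).
#' @param dry_run Print the plan; execute nothing.
#' @return Data frame of stage records: `stage`, `status` (`ran`,
#'   `up_to_date`, `failed`, `skipped`, `pending`), `log`.
#' @export
run_pipeline <- function(config, force_rerun = FALSE, targets = NULL,
                         dry_run = FALSE) {
  if (!file.exists(config$reactant)) stop(sprintf("missing input: %s", config$reactant))
  if (!file.exists(config$product)) stop(sprintf("missing input: %s", config$product))
  tab <- stage_table(config)
  if (dry_run) {
    plan <- build_dag(config)
    return(cbind(plan, status = "pending", log = ""))
  }
  dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(config)
  records <- data.frame(stage = names(tab), status = "pending", log = "",
                        stringsAsFactors = FALSE)
  failed_upstream <- character(0)
  for (stage in names(tab)) {
    row <- which(records$stage == stage)
    info <- tab[[stage]]
    if (length(intersect(info$deps, failed_upstream))) {
      records$status[row] <- "skipped"
      records$log[row] <- "upstream failure"
      failed_upstream <- c(failed_upstream, stage)
      next
    }
    if (!is.null(targets) && !(stage %in% targets) &&
        !any(vapply(targets, function(t) stage %in% upstream_closure(tab, t), logical(1)))) {
      records$status[row] <- "skipped"
      records$log[row] <- "not targeted"
      next
    }
    hashes <- tryCatch(
      as.list(hash_inputs(info$files, config[info$subtrees])),
      error = function(cond) conditionMessage(cond))
    if (is.character(hashes) && length(hashes) == 1L && !is.list(hashes)) {
      records$status[row] <- "failed"; records$log[row] <- hashes
      failed_upstream <- c(failed_upstream, stage)
      next
    }
    stored <- manifest[[stage]]$input_hashes
    outputs_exist <- all(file.exists(stage_path(config, stage, info$outputs)))
    if (!force_rerun && !is.null(stored) &&
        identical(lapply(stored, as.character), lapply(hashes, as.character)) &&
        outputs_exist) {
      records$status[row] <- "up_to_date"
      next
    }
    res <- tryCatch({
      dir.create(stage_path(config, stage), recursive = TRUE, showWarnings = FALSE)
      execute_stage(stage, config)
      "ok"
    }, error = function(cond) conditionMessage(cond))
    if (identical(res, "ok")) {
      records$status[row] <- "ran"
      manifest[[stage]] <- list(input_hashes = hashes,
                                outputs = file.path("results", stage, info$outputs),
                                status = "ran")
      write_manifest(config, manifest)
    } else {
      records$status[row] <- "failed"
      records$log[row] <- res
      manifest[[stage]] <- list(input_hashes = NULL, outputs = NULL, status = "failed")
      write_manifest(config, manifest)
      failed_upstream <- c(failed_upstream, stage)
    }
  }
  records
}

upstream_closure <- function(tab, stage) {
  out <- stage
  repeat {
    more <- unique(unlist(lapply(out, function(s) tab[[s]]$deps)))
    new <- setdiff(more, out)
    if (!length(new)) return(out)
    out <- c(out, new)
  }
}

config_align_params <- function(config, k_max = NULL) {
  a <- config$align
  align_params(k_max = k_max %||% a$k_max %||% 1.8,
               multistart_count = a$multistart_count %||% 1000L,
               convergence_tol = a$convergence_tol %||% 1e-10)
}

config_potential <- function(config) {
  potential_spec(config$potential$name, config$potential$parameters %||% list())
}

execute_stage <- function(stage, config) {
  out <- function(file) stage_path(config, stage, file)
  switch(stage,
    align_pre = {
      R <- read_xyz(config$reactant)[[1L]]
      P <- read_xyz(config$product)[[1L]]
      if (!same_composition(R, P)) stop("inconsistent endpoint composition")
      Rc <- center_in_cell(R, config$cell)
      Pc <- center_in_cell(P, config$cell)
      al <- ira_align(mobile = Pc, reference = Rc,
                      params = config_align_params(config))
      write_xyz(Rc, out("reactant_centered.xyz"))
      write_xyz(Pc, out("product_centered.xyz"))
      write_xyz(center_in_cell(apply_alignment(al, Pc), config$cell),
                out("product_aligned.xyz"))
      writeLines(sprintf("pre_alignment_rmsd_A\t%.12f", al$rmsd), out("rmsd.txt"))
    },
    minimize_R = ,
    minimize_P = {
      src <- if (stage == "minimize_R") "reactant_centered.xyz" else "product_centered.xyz"
      start <- read_xyz(stage_path(config, "align_pre", src))[[1L]]
      mp <- do.call(minimize_params, config$minimize)
      res <- lbfgs_minimize(config_potential(config), start, mp)
      if (!res$converged) stop(sprintf("%s did not converge in %d iterations",
                                       stage, res$iterations))
      write_xyz(res$config, out("minimized.xyz"))
      write_xyz(res$trajectory, out("trajectory.xyz"))
    },
    align_post = {
      Rm <- read_xyz(stage_path(config, "minimize_R", "minimized.xyz"))[[1L]]
      Pm <- read_xyz(stage_path(config, "minimize_P", "minimized.xyz"))[[1L]]
      al <- ira_align(mobile = Pm, reference = Rm,
                      params = config_align_params(config))
      Pa <- apply_alignment(al, Pm)
      Pa$energy <- Pm$energy
      write_xyz(list(Rm, Pa), out("endpoints.xyz"))
      writeLines(sprintf("final_rmsd_A\t%.12f", al$rmsd), out("rmsd.txt"))
    },
    pathgen = {
      ends <- read_xyz(stage_path(config, "align_post", "endpoints.xyz"))
      pp <- do.call(pathgen_params, config$path)
      band <- generate_path(ends[[1L]], ends[[2L]], pp)
      write_xyz(band, out("band_initial.xyz"))
    },
    band = {
      path <- read_xyz(stage_path(config, "pathgen", "band_initial.xyz"))
      np <- do.call(neb_params, config$neb)
      res <- optimize_band(path, config_potential(config), np)
      write_xyz(res$state$images, out("band_final.xyz"))
      hist_df <- do.call(rbind, lapply(res$history, function(h)
        data.frame(iteration = h$iteration, image = seq_along(h$energies) - 1L,
                   energy = h$energies, max_force = h$max_force, phase = h$phase)))
      utils::write.table(hist_df, out("history.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      snaps <- unlist(lapply(res$history, function(h)
        lapply(seq_along(h$positions), function(i) {
          cfg <- with_positions(path[[1L]], h$positions[[i]])
          cfg$energy <- h$energies[i]
          cfg
        })), recursive = FALSE)
      write_xyz(snaps, out("snapshots.xyz"))
      if (!res$state$converged) stop("band optimization hit the iteration cap")
    },
    visualize = {
      band <- read_xyz(stage_path(config, "band", "band_final.xyz"))
      samples <- read_xyz(stage_path(config, "band", "snapshots.xyz"))
      ap <- config_align_params(config)
      for (mode in c("index", "path_length", "rmsd_reactant")) {
        f <- switch(mode, index = "profile_index.tsv",
                    path_length = "profile_path_length.tsv",
                    rmsd_reactant = "profile_rmsd.tsv")
        write_profile_tsv(band, state = NULL, path = out(f), mode = mode,
                          align_params = ap)
      }
      ap2 <- config_align_params(config, k_max = config$visualize$k_max_2d %||% 14)
      pts <- landscape_points(samples, band[[1L]], band[[length(band)]], ap2)
      write_landscape_tsv(pts, out("landscape.tsv"))
    },
    stop(sprintf("unknown stage '%s'", stage))
  )
  invisible(NULL)
}
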