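test_that("the stage plan is topologically ordered with parallel minimizations", {
  fx <- make_fixture("surrogate_triatomic")
  wd <- withr::local_tempdir()
  write_xyz(fx$reactant, file.path(wd, "r.xyz"))
  write_xyz(fx$product, file.path(wd, "p.xyz"))
  cfg <- run_config(file.path(wd, "r.xyz"), file.path(wd, "p.xyz"),
                    potential = fx$potential, workdir = file.path(wd, "run"))
  plan <- build_dag(cfg)
  expect_equal(nrow(plan), 7)
  pos <- function(s) which(plan$stage == s)
  expect_lt(pos("align_pre"), pos("minimize_R"))
  expect_lt(pos("align_pre"), pos("minimize_P"))
  expect_lt(pos("minimize_R"), pos("align_post"))
  expect_lt(pos("minimize_P"), pos("align_post"))
  expect_lt(pos("align_post"), pos("pathgen"))
  expect_lt(pos("pathgen"), pos("band"))
  expect_lt(pos("band"), pos("visualize"))
  expect_setequal(plan$stage[plan$concurrent_group == "minimize"],
                  c("minimize_R", "minimize_P"))
  # dry run prints a plan and executes nothing
  rec <- run_pipeline(cfg, dry_run = TRUE)
  expect_true(all(rec$status == "pending"))
  expect_false(dir.exists(file.path(wd, "run")))
})

test_that("content hashes ignore timestamps and isolate parameter subtrees", {
  wd <- withr::local_tempdir()
  f <- file.path(wd, "a.txt")
  writeLines("hello", f)
  h1 <- hash_inputs(f)
  h2 <- hash_inputs(f)
  expect_identical(h1, h2)
  Sys.sleep(0.01)
  writeLines("hello", f)       # identical bytes, new mtime
  expect_identical(hash_inputs(f), h1)
  writeLines("world", f)
  expect_false(identical(hash_inputs(f), h1))
  p1 <- hash_inputs(character(0), list(neb = list(k_min = 1), minimize = list(tol = 2)))
  p2 <- hash_inputs(character(0), list(minimize = list(tol = 2), neb = list(k_min = 9)))
  p3 <- hash_inputs(character(0), list(minimize = list(tol = 2), neb = list(k_min = 1)))
  expect_false(identical(p1[["params"]], p2[["params"]]))
  expect_identical(p1[["params"]], p3[["params"]])   # key order is canonicalized
  expect_error(hash_inputs(file.path(wd, "missing.txt")), "missing input")
})

test_that("a full run succeeds and an unchanged rerun executes zero stages", {
  demo <- orchestrator_demo()
  expect_true(all(demo$first$status == "ran"))
  expect_true(all(demo$second$status == "up_to_date"))
})

test_that("editing the reactant re-runs its lineage but skips product minimization", {
  demo <- orchestrator_demo()
  third <- demo$third
  reran <- third$stage[third$status == "ran"]
  expect_setequal(reran, c("align_pre", "minimize_R", "align_post",
                           "pathgen", "band", "visualize"))
  expect_identical(third$status[third$stage == "minimize_P"], "up_to_date")
})

test_that("stage outputs carry the expected artifacts", {
  demo <- orchestrator_demo()
  res <- file.path(demo$config$workdir, "results")
  band <- read_xyz(file.path(res, "band", "band_final.xyz"))
  expect_length(band, 18)
  endpoints <- read_xyz(file.path(res, "align_post", "endpoints.xyz"))
  expect_length(endpoints, 2)
  hist <- utils::read.delim(file.path(res, "band", "history.tsv"))
  expect_true(all(c("iteration", "image", "energy", "max_force", "phase") %in% names(hist)))
  prof <- utils::read.delim(file.path(res, "visualize", "profile_path_length.tsv"),
                            comment.char = "#")
  expect_equal(nrow(prof), 18)
  land <- utils::read.delim(file.path(res, "visualize", "landscape.tsv"),
                            comment.char = "#")
  expect_true(all(land$d >= -1e-10))
  # the final profile has a single interior energy maximum
  e <- vapply(band, function(im) im$energy, numeric(1))
  expect_equal(sum(diff(sign(diff(e))) == -2), 1)
})

test_that("runs are deterministic and resumable", {
  fx <- make_fixture("surrogate_triatomic")
  wd <- withr::local_tempdir()
  write_xyz(fx$reactant, file.path(wd, "r.xyz"))
  write_xyz(fx$product, file.path(wd, "p.xyz"))
  mk <- function(run_dir) run_config(file.path(wd, "r.xyz"), file.path(wd, "p.xyz"),
                                     potential = fx$potential,
                                     workdir = file.path(wd, run_dir),
                                     overrides = list(path = list(n_images = 8L)))
  cfg1 <- mk("run1"); cfg2 <- mk("run2")
  # partial run up to align_post, then resume: exactly the rest executes
  part <- run_pipeline(cfg1, targets = "align_post")
  expect_setequal(part$stage[part$status == "ran"],
                  c("align_pre", "minimize_R", "minimize_P", "align_post"))
  rest <- run_pipeline(cfg1)
  expect_setequal(rest$stage[rest$status == "ran"],
                  c("pathgen", "band", "visualize"))
  expect_setequal(rest$stage[rest$status == "up_to_date"],
                  c("align_pre", "minimize_R", "minimize_P", "align_post"))
  # an independent full run produces byte-identical stage outputs
  run_pipeline(cfg2)
  b1 <- readLines(file.path(cfg1$workdir, "results", "band", "band_final.xyz"))
  b2 <- readLines(file.path(cfg2$workdir, "results", "band", "band_final.xyz"))
  expect_identical(b1, b2)
  # force_rerun overrides up-to-date detection
  forced <- run_pipeline(cfg2, force_rerun = TRUE)
  expect_true(all(forced$status == "ran"))
})

test_that("YAML configs round-trip through the reader with presets applied", {
  wd <- withr::local_tempdir()
  fx <- make_fixture("surrogate_triatomic")
  cfg_path <- write_fixture(fx, wd)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$path$n_images, 18L)
  expect_equal(cfg$neb$k_max, 9.72)
  # preset + override precedence
  y <- yaml::read_yaml(cfg_path)
  y$preset <- "small"
  y$path <- list(alpha = 0.25)
  yaml::write_yaml(y, cfg_path)
  cfg2 <- read_run_config(cfg_path)
  expect_equal(cfg2$path$n_images, 14L)
  expect_equal(cfg2$path$alpha, 0.25)
  expect_equal(cfg2$align$k_max, 1.8)
  cfg3 <- run_config("r.xyz", "p.xyz", preset = "complex")
  expect_equal(cfg3$path$n_images, 24L)
  expect_equal(cfg3$neb$force_tol, 0.026)
  expect_equal(cfg3$align$k_max, 4.0)
})

test_that("missing inputs and stage failures are reported, downstream halted", {
  fx <- make_fixture("surrogate_triatomic")
  wd <- withr::local_tempdir()
  cfg <- run_config(file.path(wd, "nope.xyz"), file.path(wd, "nope2.xyz"),
                    potential = fx$potential, workdir = file.path(wd, "run"))
  expect_error(run_pipeline(cfg), "missing input")
  # a failing band stage (1-iteration cap) halts visualize but keeps upstream
  write_xyz(fx$reactant, file.path(wd, "r.xyz"))
  write_xyz(fx$product, file.path(wd, "p.xyz"))
  cfg2 <- run_config(file.path(wd, "r.xyz"), file.path(wd, "p.xyz"),
                     potential = fx$potential, workdir = file.path(wd, "run2"),
                     overrides = list(neb = list(max_iterations = 1L),
                                      path = list(n_images = 6L)))
  rec <- run_pipeline(cfg2)
  expect_identical(rec$status[rec$stage == "band"], "failed")
  expect_identical(rec$status[rec$stage == "visualize"], "skipped")
  expect_identical(rec$status[rec$stage == "align_post"], "ran")
})
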