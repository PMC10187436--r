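test_that("run configurations round-trip through the YAML format", {
  cfg <- scenario_config("fig8_hetero", seed = 12)
  f <- tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  back <- read_run_config(f)
  expect_equal(back$box, cfg$box)
  expect_equal(back$temperatures, cfg$temperatures)
  expect_equal(back$total_steps, cfg$total_steps)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$move_weights, cfg$move_weights)
  expect_equal(back$model$contact_energy, cfg$model$contact_energy)
  expect_equal(vapply(back$species, function(s) s$n_chains, 0L),
               vapply(cfg$species, function(s) s$n_chains, 0L))
  # heteropolymer species survive as sequences
  cfg2 <- scenario_config("plcd_mixture")
  f2 <- tempfile(fileext = ".yaml")
  write_run_config(cfg2, f2)
  back2 <- read_run_config(f2)
  expect_equal(back2$species$A1_LCD$beads, cfg2$species$A1_LCD$beads)
})

test_that("config schema violations report their field paths", {
  cfg <- scenario_config("fig8_equal")
  f <- tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  obj <- yaml::read_yaml(f)
  obj$species[[1]]$n_chains <- NULL
  f2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(obj, f2)
  expect_error(read_run_config(f2), "species\\[1\\]\\.n_chains")
  obj2 <- yaml::read_yaml(f)
  obj2$model <- NULL
  yaml::write_yaml(obj2, f2)
  expect_error(read_run_config(f2), "'model'")
  obj3 <- yaml::read_yaml(f)
  obj3$n_replicates <- 0
  yaml::write_yaml(obj3, f2)
  expect_error(read_run_config(f2), "n_replicates")
})

test_that("the pipeline writes products, a manifest, and is deterministic", {
  cfg <- scenario_config("fig8_hetero", seed = 19, total_steps = 1e6,
                         n_replicates = 2, temperatures = 10)
  d1 <- file.path(tempdir(), "pipe1")
  d2 <- file.path(tempdir(), "pipe2")
  unlink(c(d1, d2), recursive = TRUE)
  man <- run_pipeline(cfg, d1)
  expect_s3_class(man, "latmix_manifest")
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "binodal.tsv")))
  expect_true(any(grepl("^crosslink_T", names(man$paths))))
  expect_true(any(grepl("^profile_T", names(man$paths))))
  expect_true(any(grepl("^tieline_T", names(man$paths))))
  # determinism: a fresh run in a fresh directory gives byte-identical TSVs
  run_pipeline(cfg, d2)
  for (fn in c("binodal.tsv", "profile_T10.tsv", "crosslink_T10.tsv")) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
  # resume: trajectory files are reused, analysis re-derives the same numbers
  before <- file.mtime(file.path(d1, "traj_T10_rep1.txt"))
  man3 <- run_pipeline(cfg, d1)
  expect_equal(file.mtime(file.path(d1, "traj_T10_rep1.txt")), before)
  expect_identical(readLines(file.path(d1, "binodal.tsv")),
                   readLines(file.path(d2, "binodal.tsv")))
  # the L statistic survives the round trip through trajectory files
  cl <- read.table(file.path(d1, "crosslink_T10.tsv"), header = TRUE)
  expect_gt(cl$L[cl$species_i == "A" & cl$species_j == "B"], 1)

  # reporting draws from the TSVs alone
  pdf_file <- tempfile(fileext = ".pdf")
  panels <- report(read_manifest(d1), file = pdf_file)
  expect_true(file.exists(pdf_file))
  expect_true(any(grepl("profile", panels)))
  unlink(c(d1, d2, pdf_file), recursive = TRUE)
})

test_that("incomplete or empty manifests are rejected with specifics", {
  man <- structure(list(paths = list(), temperatures = numeric(0),
                        species = character(0), outdir = tempdir()),
                   class = "latmix_manifest")
  expect_error(report(man), "empty manifest")
  man2 <- structure(list(paths = list(binodal = "/nonexistent/binodal.tsv"),
                         temperatures = 10, species = "A",
                         outdir = tempdir()),
                    class = "latmix_manifest")
  expect_error(report(man2), "binodal")
})
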