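# End-to-end pipeline, fixtures, CLI.

test_that("run_pipeline analyses mixed conditions and keeps the identity", {
  cfg <- list(seed = 5, samples = list(
    list(name = "pep", molecule = "none", abeta_mol_pct = 20),
    list(name = "pure", molecule = "none", abeta_mol_pct = 0)))
  res <- suppressWarnings(run_pipeline(cfg))
  tab <- res$table
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$d_z, tab$d_HH + tab$d_W)
  # peptide-free sample: cross-beta columns are missing markers
  expect_true(is.na(tab$L[2]) && is.na(tab$phi[2]))
  expect_false(anyNA(tab[2, c("d_z", "A_T", "lipid_tilt", "H")]))
  # peptide sample carries the aggregated fraction
  expect_equal(tab$aggregated_fraction[1], 100 * tab$phi[1] / 20)
  # gel doublet of the drug-free pure membrane is indexed
  expect_equal(round(res$details$pure$inplane$cell$a, 1), 8.4)
  expect_equal(round(res$details$pure$inplane$cell$b, 1), 8.8)
})

test_that("pipeline output is byte-identical under a fixed seed", {
  cfg <- list(seed = 9, samples = list(
    list(name = "a", molecule = "melatonin", abeta_mol_pct = 20)))
  t1 <- suppressWarnings(run_pipeline(cfg))$table
  t2 <- suppressWarnings(run_pipeline(cfg))$table
  expect_identical(t1, t2)
})

test_that("pipeline writes partial results and halts on stage failure", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 1, samples = list(
    list(name = "bad", files = list(lamellar = "does-not-exist.tsv"))))
  expect_error(suppressWarnings(run_pipeline(cfg, out_dir = dir)),
               "stage 'input'.*bad")
  log <- jsonlite::fromJSON(file.path(dir, "log.json"))
  expect_identical(log$bad$stage, "input")
})

test_that("make_fixtures emits the full synthetic condition set", {
  dir <- withr::local_tempdir()
  man <- make_fixtures(dir, seed = 2, map_q_step = 0.02)
  files <- dir(dir)
  expect_identical(sum(grepl("_map.tsv$", files)), 8L)
  expect_identical(sum(grepl("_lamellar.tsv$", files)), 8L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(dir.exists(file.path(dir, "stxm_stack")))
  expect_true(file.exists(file.path(dir, "surface.tsv")))
  expect_identical(length(man$conditions), 8L)
  # refuses to clobber
  expect_error(make_fixtures(dir, seed = 2), "not empty")
  # ground truths are seed-independent, noise realisations are not
  dir2 <- withr::local_tempdir()
  man2 <- make_fixtures(dir2, seed = 3, map_q_step = 0.02)
  expect_equal(man$conditions$none_20$d_z, man2$conditions$none_20$d_z)
  s1 <- read_line_scan(file.path(dir, "none_20_lamellar.tsv"))
  s2 <- read_line_scan(file.path(dir2, "none_20_lamellar.tsv"))
  expect_false(identical(s1$intensity, s2$intensity))
  # manifest ground truths drive a recovery run
  gt <- man$conditions$none_20
  rl <- analyze_lamellar(s1)
  expect_lt(abs(rl$d_z - gt$d_z), 0.1)
})

test_that("pipeline consumes fixture files written to disk", {
  dir <- withr::local_tempdir()
  gt <- quick_gt(seed = 13)
  write_line_scan(gen_lamellar_scan(gt), file.path(dir, "lam.tsv"))
  write_line_scan(gen_inplane_scan(gt), file.path(dir, "inp.tsv"))
  write_reciprocal_map(gen_map2d(gt), file.path(dir, "map.tsv"))
  cfg <- list(seed = 1, samples = list(list(
    name = "fx", molecule = "none", abeta_mol_pct = 20,
    files = list(lamellar = file.path(dir, "lam.tsv"),
                 inplane = file.path(dir, "inp.tsv"),
                 map = file.path(dir, "map.tsv")))))
  res <- suppressWarnings(run_pipeline(cfg))
  expect_lt(abs(res$table$d_z - gt$d_z), 0.1)
  expect_lt(abs(res$table$phi - gt$peptide_area_fraction), 0.02)
})

test_that("CLI subcommands run and report exit codes", {
  dir <- withr::local_tempdir()
  # model: rank conditions from a JSON config
  cfgp <- file.path(dir, "model.json")
  jsonlite::write_json(list(conditions = list(curcumin = 36.9,
                                              melatonin = 37.6, ASA = 41),
                            w0 = 30, g0 = 1),
                       cfgp, auto_unbox = TRUE)
  outp <- file.path(dir, "rank.tsv")
  expect_identical(lamellaR_cli(c("model", "--config", cfgp,
                                  "--out", outp)), 0L)
  rk <- read.table(outp, header = TRUE, sep = "\t")
  expect_identical(rk$condition, c("curcumin", "melatonin", "ASA"))
  expect_true(all(c("R_star", "deltaG_star") %in% names(rk)))
  # integrate: wedge-integrate a map file
  mapp <- file.path(dir, "map.tsv")
  write_reciprocal_map(gen_map2d(quick_gt(seed = 1), q_step = 0.02), mapp)
  scp <- file.path(dir, "scan.tsv")
  expect_identical(lamellaR_cli(c("integrate", "--map", mapp,
                                  "--out", scp)), 0L)
  expect_s3_class(read_line_scan(scp), "line_scan")
  # curvature
  srfp <- file.path(dir, "srf.tsv")
  write_surface(gen_surface(surface_ground_truth(seed = 1)), srfp)
  curp <- file.path(dir, "cur.json")
  expect_identical(lamellaR_cli(c("curvature", "--surface", srfp,
                                  "--out", curp)), 0L)
  cur <- jsonlite::fromJSON(curp)
  expect_lt(cur$K_max, 0)
  # input errors exit with status 2
  expect_identical(suppressMessages(suppressWarnings(
    lamellaR_cli(c("integrate", "--map", "nope.tsv", "--out", scp)))), 2L)
  invisible(capture.output(
    expect_identical(suppressMessages(lamellaR_cli(c("frobnicate"))), 2L)))
})
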