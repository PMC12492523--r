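write_fixture_images <- function(dir, n_per_group = 2, size = c(160, 160)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n_per_group)) {
    write_synthetic_image(
      generate_mesh_image(synthetic_preset("sparse", rng_seed = i,
                                           image_size = size)),
      dir, sprintf("a_sparse_%02d", i))
    write_synthetic_image(
      generate_mesh_image(synthetic_preset("dense", rng_seed = i,
                                           image_size = size)),
      dir, sprintf("b_dense_%02d", i))
  }
  # keep only the images themselves: ground-truth masks are not analyzed
  file.remove(list.files(dir, "_truth\\.png$", full.names = TRUE))
}

test_that("analysis records are self-describing and flatten to the full metric schema", {
  syn <- generate_mesh_image(synthetic_preset("dense", rng_seed = 12,
                                              image_size = c(160, 160)))
  rec <- analyze_image(syn$image, image_id = "demo",
                       metrics = metric_config(rng_seed = 99))
  expect_s3_class(rec, "analysis_record")
  expect_identical(rec$config$metrics$rng_seed, 99L)
  expect_identical(rec$config$radial$delta_r, 50)
  row <- as.data.frame(rec)
  expect_identical(nrow(row), 1L)
  expect_true(all(metric_names() %in% names(row)))
  expect_true(all(heterogeneity_names() %in% names(row)))
  expect_identical(ncol(row), 1L + 11L + 5L + 1L)

  # record JSON round-trips its configuration
  jf <- withr::local_tempfile(fileext = ".json")
  write_record_json(rec, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$config$metrics$rng_seed, 99)
  expect_equal(parsed$metrics$n_nodes, row$n_nodes)
})

test_that("batch analysis reads image files from disk in stable order and reproduces in-memory results", {
  dir <- withr::local_tempdir()
  write_fixture_images(dir, n_per_group = 1)
  csv <- file.path(dir, "metrics.csv")
  tab <- analyze_images(dir, metrics = metric_config(rng_seed = 7), csv = csv)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$image_id,
                   c("a_sparse_01.png", "b_dense_01.png"))  # filename order
  expect_true(file.exists(csv))
  expect_identical(attr(tab, "skipped"), character(0))

  # PNG round trip preserves the pipeline result exactly (8-bit grid values)
  syn <- generate_mesh_image(synthetic_preset("dense", rng_seed = 1,
                                              image_size = c(160, 160)))
  from_disk <- tab[tab$image_id == "b_dense_01.png", ]
  in_mem <- as.data.frame(analyze_image(syn$image,
                                        metrics = metric_config(rng_seed = 7)))
  expect_equal(from_disk$n_nodes, in_mem$n_nodes)
  expect_equal(from_disk$connectivity_index, in_mem$connectivity_index)
})

test_that("identical config and seed give byte-identical CSV tables", {
  dir <- withr::local_tempdir()
  write_fixture_images(dir, n_per_group = 1)
  c1 <- file.path(dir, "run1.csv"); c2 <- file.path(dir, "run2.csv")
  analyze_images(dir, metrics = metric_config(rng_seed = 3), csv = c1)
  analyze_images(dir, metrics = metric_config(rng_seed = 3), csv = c2)
  expect_identical(readBin(c1, "raw", file.size(c1)),
                   readBin(c2, "raw", file.size(c2)))
})

test_that("unreadable images are skipped with a warning, not fatal", {
  dir <- withr::local_tempdir()
  write_fixture_images(dir, n_per_group = 1)
  writeLines("not an image", file.path(dir, "corrupt.png"))
  expect_warning(tab <- analyze_images(dir), "skipping")
  expect_identical(nrow(tab), 2L)
  expect_identical(basename(attr(tab, "skipped")), "corrupt.png")
})

test_that("four-panel figures are written for records that keep images", {
  syn <- generate_mesh_image(synthetic_preset("sparse", rng_seed = 5,
                                              image_size = c(128, 128)))
  rec <- analyze_image(syn$image, keep_images = TRUE)
  fig <- withr::local_tempfile(fileext = ".png")
  plot_analysis(rec, fig)
  expect_true(file.size(fig) > 1000)
  rec2 <- analyze_image(syn$image)
  expect_error(plot_analysis(rec2, fig), "keep_images")
})

test_that("pipeline configuration files override defaults and omitted keys fall back", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preprocess:",
               "  gaussian_sigma: 2.0",
               "metrics:",
               "  rng_seed: 42",
               "radial:",
               "  delta_r: 25"), yml)
  cfg <- read_pipeline_config(yml)
  expect_equal(cfg$preprocess$gaussian_sigma, 2)
  expect_identical(cfg$preprocess$min_object_size, 64L)  # default retained
  expect_identical(cfg$metrics$rng_seed, 42L)
  expect_equal(cfg$delta_r, 25)
  expect_identical(cfg$n_zones, 6L)
  defaults <- read_pipeline_config(NULL)
  expect_equal(defaults$preprocess$gaussian_sigma, 1)
})

test_that("the command-line interface analyzes, compares and simulates", {
  skip_if(Sys.which("Rscript") == "", "Rscript not on PATH")
  # child processes must resolve the package from the same library paths
  withr::local_envvar(R_LIBS = paste(.libPaths(),
                                     collapse = .Platform$path.sep))
  cli <- system.file("cli", "angionet.R", package = "angionet")
  dir <- withr::local_tempdir()
  img_dir <- file.path(dir, "imgs"); out_dir <- file.path(dir, "out")
  write_fixture_images(img_dir, n_per_group = 1, size = c(128, 128))

  res <- system2("Rscript", c(cli, "analyze", "--images", img_dir,
                              "--out", out_dir),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res, "status"), NULL)  # exit 0
  tab <- read.csv(file.path(out_dir, "metrics.csv"))
  expect_identical(nrow(tab), 2L)
  tab$group <- c("sparse", "dense")

  cmp_csv <- file.path(dir, "formatted.csv")
  write.csv(tab, cmp_csv, row.names = FALSE)
  res2 <- system2("Rscript", c(cli, "compare", "--csv", cmp_csv,
                               "--group-col", "group", "--group-a", "sparse",
                               "--group-b", "dense", "--out", out_dir),
                  stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res2, "status"), NULL)
  cmp <- read.csv(file.path(out_dir, "comparison.csv"))
  expect_true(all(c("u", "p", "cliffs_delta", "magnitude", "auc",
                    "auc_flipped") %in% names(cmp)))

  res3 <- system2("Rscript", c(cli, "simulate", "--preset", "dense",
                               "--seed", "1", "--out", out_dir),
                  stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res3, "status"), NULL)
  expect_true(file.exists(file.path(out_dir, "dense_seed1.png")))
  meta <- jsonlite::read_json(file.path(out_dir, "dense_seed1.json"))
  expect_equal(meta$n_seeds, 40)
})
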