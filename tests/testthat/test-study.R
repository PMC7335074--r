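test_that("a small study produces the full report surface deterministically", {
  cfg <- study_config(n_subjects = 3, seed = 99, recon = TRUE)
  st1 <- run_study(cfg)
  # 6 ROIs x 2 hemispheres x 4 contrasts
  expect_equal(nrow(st1$contrasts), 6 * 2 * 4)
  expect_setequal(unique(st1$contrasts$roi),
                  c("IFG/PMv", "M1", "IPL/SMG", "MOG", "TPJ", "STS"))
  expect_setequal(unique(st1$contrasts$hemisphere), c("left", "right"))
  expect_true(all(st1$contrasts$q >= st1$contrasts$p, na.rm = TRUE))
  expect_true(all(st1$contrasts$df == st1$contrasts$n - 1))
  # reconstruction maps present for every window / chromophore / condition
  expect_equal(length(unique(st1$recon$window_start)), 6)
  expect_setequal(unique(st1$recon$chromophore), c("hbo", "hbr"))
  # bit-reproducible under the same config and seed
  st2 <- run_study(cfg)
  expect_identical(st1$contrasts, st2$contrasts)
  expect_identical(st1$recon, st2$recon)
  expect_identical(st1$hash, st2$hash)
  # different seed changes the data
  st3 <- run_study(study_config(n_subjects = 3, seed = 100, recon = FALSE))
  expect_false(identical(st1$contrasts$t, st3$contrasts$t))
  # glance/tidy methods
  expect_equal(glance(st1)$n_subjects, 3)
  expect_identical(tidy(st1), st1$contrasts)
})

test_that("results are written as tidy CSVs with provenance", {
  st <- run_study(study_config(n_subjects = 3, seed = 5, recon = FALSE))
  dir <- file.path(tempdir(), "nirsflow-results")
  write_results(st, dir)
  files <- list.files(dir)
  expect_true(all(c("contrasts.csv", "temporal_summary.csv",
                    "time_to_peak.csv", "roi_hrf_group_mean.csv",
                    "provenance.json") %in% files))
  # every CSV carries the config hash
  header <- readLines(file.path(dir, "contrasts.csv"), n = 1)
  expect_match(header, st$hash)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$hash, st$hash)
  expect_equal(prov$seed, 5)
  back <- utils::read.csv(file.path(dir, "contrasts.csv"), comment.char = "#")
  expect_equal(nrow(back), nrow(st$contrasts))
  unlink(dir, recursive = TRUE)
})

test_that("ROI maps round-trip through YAML", {
  p <- default_probe()
  rm1 <- default_roi_map(p)
  path <- file.path(tempdir(), "roi.yaml")
  write_roi_map(rm1, path)
  rm2 <- read_roi_map(path, p)
  expect_equal(dplyr::arrange(rm1, roi, hemisphere, channel),
               dplyr::arrange(rm2, roi, hemisphere, channel))
  # unknown channels are rejected
  bad <- rm1
  bad$channel[1] <- 999L
  write_roi_map(bad, path)
  expect_error(read_roi_map(path, p), class = "nirsflow_config_error")
  unlink(path)
})

test_that("stage failures abort with the subject and stage named", {
  cfg <- study_config(n_subjects = 1, seed = 1,
                      preprocess_args = list(bandpass = list(high = 99)))
  expect_error(run_study(cfg), regexp = "subject 1",
               class = "nirsflow_stage_error")
})

test_that("plot builders return ggplot objects", {
  st <- run_study(study_config(n_subjects = 3, seed = 7, recon = TRUE))
  g1 <- autoplot(st$roi_hrf, conditions = c("exec_complex", "exec_simple"))
  expect_s3_class(g1, "ggplot")
  rec1 <- structure(list(image = st$recon[st$recon$condition ==
                                            "exec_complex" &
                                          st$recon$chromophore == "hbo" &
                                          st$recon$window_start == 3, ],
                         lambda = 0.01),
                    class = "nirs_recon_map")
  expect_s3_class(autoplot(rec1), "ggplot")
  expect_s3_class(autoplot(default_probe()), "ggplot")
})
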