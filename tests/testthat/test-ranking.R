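make_rank_fixture <- function() {
  spec <- synth_spec(seed = 2, height = 64, width = 64)
  mf <- make_multifocus_pair(spec)
  list(mf = mf,
       cands = list(truth = mf$truth,
                    avg = fuse_average(mf$a, mf$b),
                    blur = gaussian_blur(mf$truth, 6)))
}

test_that("ranking sorts descending with deterministic, flagged ties", {
  fx <- make_rank_fixture()
  rep <- rank_fusions(fx$mf$a, fx$mf$b, fx$cands, metrics = "arimoto")
  rows <- rep$arimoto$rows
  expect_setequal(rows$rank, 1:3)
  expect_equal(rows$rank[order(-rows$value)], 1:3)
  expect_false(any(rows$tied))

  tied <- rank_fusions(fx$mf$a, fx$mf$b,
                       list(one = fx$cands$avg, two = fx$cands$avg),
                       metrics = "mi")
  expect_true(all(tied$mi$rows$tied))
  expect_equal(tied$mi$rows$rank, 1:2)  # input order breaks the tie
  expect_error(rank_fusions(fx$mf$a, fx$mf$b, list(x = fx$cands$avg)),
               "at least two")
})

test_that("rank agreement reaches +1 on matching and -1 on reversed orders", {
  fx <- make_rank_fixture()
  r1 <- rank_fusions(fx$mf$a, fx$mf$b, fx$cands, metrics = "arimoto")
  computed <- r1$arimoto$rows$label[order(r1$arimoto$rows$rank)]
  agree <- rank_fusions(fx$mf$a, fx$mf$b, fx$cands, metrics = "arimoto",
                        reference_rank = computed)
  expect_equal(agree$arimoto$kendall_tau, 1)
  expect_equal(agree$arimoto$spearman_rho, 1)

  # five distinct candidates, reference exactly reversed
  lad <- make_degradation_ladder(fx$mf$truth, c(0, 1, 2, 4, 6))
  r5 <- rank_fusions(fx$mf$a, fx$mf$b, lad, metrics = "arimoto")
  order5 <- r5$arimoto$rows$label[order(r5$arimoto$rows$rank)]
  rev5 <- rank_fusions(fx$mf$a, fx$mf$b, lad, metrics = "arimoto",
                       reference_rank = rev(order5))
  expect_equal(rev5$arimoto$kendall_tau, -1)
  expect_error(rank_fusions(fx$mf$a, fx$mf$b, fx$cands,
                            reference_rank = c("nope", "avg", "blur")),
               "permutation")
})

test_that("reports round-trip through JSON bit-for-bit and export CSV", {
  fx <- make_rank_fixture()
  reports <- rank_fusions(fx$mf$a, fx$mf$b, fx$cands,
                          metrics = c("arimoto", "mi"))
  jf <- withr::local_tempfile(fileext = ".json")
  write_ranking_report(reports, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_identical(back$arimoto$rows$value, reports$arimoto$rows$value)
  expect_identical(back$mi$rows$rank, reports$mi$rows$rank)

  cf <- withr::local_tempfile(fileext = ".csv")
  write_ranking_report(reports, cf)
  tab <- read.csv(cf)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$metric), c("arimoto", "mi"))
})

test_that("config files parse key = value pairs with comments", {
  cfg <- withr::local_tempfile(fileext = ".toml")
  writeLines(c("# defaults", "alpha = 1.75", 'metric = "tsallis"',
               "bins = 128  # coarse"), cfg)
  got <- read_config_file(cfg)
  expect_equal(got$alpha, 1.75)
  expect_equal(got$metric, "tsallis")
  expect_equal(got$bins, 128)
  bad <- withr::local_tempfile()
  writeLines("alpha 1.5", bad)
  expect_error(read_config_file(bad), "malformed")
})

test_that("images survive PNG and PGM round trips", {
  x <- test_card()
  for (ext in c(".png", ".pgm")) {
    f <- withr::local_tempfile(fileext = ext)
    write_gray_image(x, f)
    back <- read_gray_image(f)
    expect_identical(pixel_matrix(back), pixel_matrix(x))
  }
  expect_error(read_gray_image("does-not-exist.png"), "cannot read")
})

test_that("the command-line tool scores and simulates end to end", {
  cli <- system.file("cli", "arifuse.R", package = "arifuse")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  x <- test_card(32)
  pa <- file.path(dir, "a.png"); write_gray_image(x, pa)
  out <- file.path(dir, "score.json")
  status <- system2("Rscript", c(cli, "score", "--a", pa, "--b", pa,
                                 "--f", pa, "--json", out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  got <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(got$alpha, 1.5)  # omitted --alpha defaults to 1.5
  expect_equal(got$value, metric_arimoto(x, x, x)$value, tolerance = 1e-12)

  bad <- system2("Rscript", c(cli, "score", "--a", pa, "--b", pa,
                              "--f", file.path(dir, "missing.png")),
                 stdout = FALSE, stderr = FALSE)
  expect_equal(bad, 2L)

  small <- file.path(dir, "small.png")
  write_gray_image(test_card(16), small)
  mism <- system2("Rscript", c(cli, "score", "--a", pa, "--b", pa,
                               "--f", small),
                  stdout = FALSE, stderr = FALSE)
  expect_equal(mism, 3L)
})
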