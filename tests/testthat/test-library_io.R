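test_that("transition report rows group into precursors by peptide and charge", {
  lines <- c(
    "protein\tpeptide\tcharge\tprecursor_mz\tfragment\tproduct_mz\tapex_rt\tstart_rt\tend_rt\tarea",
    "P1\tAAAK\t2\t400.2\ty3\t300.1\t10.00\t9.90\t10.10\t1000",
    "P1\tAAAK\t2\t400.2\ty4\t400.1\t10.01\t9.90\t10.10\t800",
    "P1\tAAAK\t2\t400.2\ty5\t500.1\t9.99\t9.90\t10.10\t600",
    "P2\tCCCR\t3\t500.3\ty3\t350.1\t15.00\t14.90\t15.12\t2000",
    "P2\tCCCR\t3\t500.3\ty4\t450.1\t15.02\t14.90\t15.12\t1500",
    "P2\tCCCR\t3\t500.3\ty5\t550.1\t15.01\t14.90\t15.12\t900")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, f)
  lib <- read_transition_report(f)
  expect_length(lib, 2L)
  tab <- precursor_table(lib)
  expect_setequal(tab$n_transitions, 3L)
  # grouping conservation: rows in == transitions out
  expect_identical(sum(vapply(lib$precursors,
                              function(p) nrow(p$transitions), 0L)), 6L)
  # consensus RT is the median apex, width the median boundary span
  aaak <- lib$precursors[[which(tab$peptide == "AAAK")]]
  expect_equal(aaak$ref_rt, 10.00)
  expect_equal(aaak$peak_width, (10.10 - 9.90) * 60)
  expect_equal(aaak$total_area, 2400)
})

test_that("replicate rows of one precursor stay in one entry with areas per replicate", {
  lines <- c(
    "protein\tpeptide\tcharge\tprecursor_mz\tfragment\tproduct_mz\tapex_rt\tstart_rt\tend_rt\tarea\treplicate",
    "P1\tAAAK\t2\t400.2\ty3\t300.1\t10.00\t9.90\t10.10\t1000\trep1",
    "P1\tAAAK\t2\t400.2\ty4\t400.1\t10.00\t9.90\t10.10\t800\trep1",
    "P1\tAAAK\t2\t400.2\ty3\t300.1\t10.05\t9.95\t10.15\t1200\trep2",
    "P1\tAAAK\t2\t400.2\ty4\t400.1\t10.05\t9.95\t10.15\t900\trep2")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, f)
  lib <- read_transition_report(f)
  expect_length(lib, 1L)
  p <- lib$precursors[[1]]
  expect_identical(sort(unique(p$transitions$replicate)), c("rep1", "rep2"))
  expect_identical(nrow(p$transitions), 4L)
  # per-fragment means: y3 (1000+1200)/2, y4 (800+900)/2
  expect_equal(p$total_area, 1100 + 850)
})

test_that("empty and malformed reports are handled loudly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("protein", "peptide", "charge", "precursor_mz",
                     "fragment", "product_mz", "apex_rt", "start_rt",
                     "end_rt", "area"), collapse = "\t"), f)
  expect_warning(lib <- read_transition_report(f), "empty")
  expect_length(lib, 0L)

  lines <- c(
    "protein\tpeptide\tcharge\tprecursor_mz\tfragment\tproduct_mz\tapex_rt\tstart_rt\tend_rt\tarea",
    "P1\tAAAK\t2\t400.2\ty3\t300.1\t10.00\t9.90\t10.10\t1000",
    "P1\tAAAK\t2\t400.2\ty4\t400.1\tnot_a_number\t9.90\t10.10\t800",
    "P1\tAAAK\t2\t400.2\ty5\t500.1\t10.00\t10.20\t10.10\t600")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, f2)
  expect_warning(lib2 <- read_transition_report(f2), "malformed")
  bad <- attr(lib2, "malformed")
  expect_identical(bad$line, c(3L, 4L))  # header is line 1
  expect_identical(sum(vapply(lib2$precursors,
                              function(p) nrow(p$transitions), 0L)), 1L)

  expect_error(
    read_transition_report(f2, report_dialect(area = "MissingColumn")),
    class = "config_error")
})

test_that("target lists round-trip losslessly and clip to the gradient", {
  set.seed(42)
  lib <- make_library(sort(runif(30, 1, 29)))
  plan <- assign_windows(lib, acquisition_params())
  f <- withr::local_tempfile(fileext = ".csv")
  write_target_list(plan, f)
  back <- read_target_list(f)
  expect_identical(nrow(back), 30L)
  expect_identical(back$compound, plan$entries$peptide)
  expect_equal(back$t_start_min, plan$entries$window_start)
  expect_equal(back$t_end_min, plan$entries$window_end)
  expect_equal(back$mz, round(plan$entries$precursor_mz, 4))
  # byte-stable: writing what was read reproduces the file exactly
  plan2 <- plan
  plan2$entries$precursor_mz <- back$mz
  plan2$entries$window_start <- back$t_start_min
  plan2$entries$window_end <- back$t_end_min
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_target_list(plan2, f2)
  expect_identical(readLines(f), readLines(f2))

  plan$entries$window_end[1] <- plan$params$gradient_length + 0.3
  expect_warning(write_target_list(plan, f), "clipped")
  expect_lte(max(read_target_list(f)$t_end_min),
             plan$params$gradient_length)
})

test_that("multi-injection plans write one row per target per injection", {
  set.seed(1)
  lib <- make_library(rep(15, 30))  # force contention at one RT
  params <- acquisition_params(min_injection_time = 80,
                               expected_peak_width = 6)
  expect_lt(capacity(params), 30)
  plan <- split_injections(lib, params, max_injections = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_target_list(plan, f)
  back <- read_target_list(f)
  expect_identical(nrow(back), 30L)
  expect_identical(sort(unique(back$injection)),
                   seq_len(plan$n_injections))
})

test_that("reference maps survive the serialized container byte-stably", {
  set.seed(7)
  lib <- generate_library(generator_config("small", n_proteins = 15,
                                           seed = 7))
  run <- generate_warped_run(lib, identity, seed = 7)
  ref <- build_reference(run, bin_width = 2)
  f <- withr::local_tempfile(fileext = ".refbin")
  save_reference(ref, f)
  ref2 <- load_reference(f)
  expect_identical(ref2$rt_grid, ref$rt_grid)
  expect_identical(ref2$spectra, ref$spectra)
  expect_identical(ref2$bin_width, ref$bin_width)
  expect_equal(unname(ref2$dia_windows), unname(ref$dia_windows))
  f2 <- withr::local_tempfile(fileext = ".refbin")
  save_reference(ref2, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("corrupt or unsupported reference files fail cleanly", {
  set.seed(7)
  lib <- generate_library(generator_config("small", n_proteins = 5, seed = 7))
  run <- generate_warped_run(lib, identity, seed = 7)
  ref <- build_reference(run, bin_width = 5)
  f <- withr::local_tempfile(fileext = ".refbin")
  save_reference(ref, f)
  # truncation: clean failure, no partial object
  bytes <- readBin(f, "raw", file.size(f))
  f_tr <- withr::local_tempfile(fileext = ".refbin")
  writeBin(bytes[seq_len(length(bytes) %/% 2)], f_tr)
  expect_error(load_reference(f_tr), class = "bad_container")
  # foreign magic
  f_bad <- withr::local_tempfile(fileext = ".refbin")
  writeBin(charToRaw("NOTAREFMAP"), f_bad)
  expect_error(load_reference(f_bad), class = "bad_container")
  # version bump
  bytes2 <- bytes
  bytes2[11] <- as.raw(9L)  # version int32 starts after the 10-byte magic
  f_v <- withr::local_tempfile(fileext = ".refbin")
  writeBin(bytes2, f_v)
  expect_error(load_reference(f_v), class = "unsupported_version")
  # degenerate map rejected at save time
  ref$rt_grid <- numeric(0)
  expect_error(save_reference(ref, f), class = "invalid_reference")
})

test_that("generated libraries round-trip through the transition report", {
  lib <- generate_library(generator_config("small", n_proteins = 10,
                                           seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_transition_report(lib, f)
  lib2 <- read_transition_report(f, gradient_length = lib$gradient_length)
  t1 <- precursor_table(lib)
  t2 <- precursor_table(lib2)
  m <- match(t1$key, t2$key)
  expect_false(anyNA(m))
  expect_equal(t2$ref_rt[m], t1$ref_rt)
  expect_equal(t2$total_area[m], t1$total_area)
  expect_equal(t2$peak_width[m], t1$peak_width)
})
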