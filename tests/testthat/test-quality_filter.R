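test_that("co-elution scores separate clean from contaminated transitions", {
  clean <- make_entry(n_trans = 4L)
  sc <- coelution_scores(clean)
  expect_length(sc, 4L)
  expect_true(all(sc > 0.999))

  # one transition carries a shifted 5x contaminant; independently computed
  # Pearson correlation against the pointwise median trace must agree
  dirty <- make_entry(n_trans = 4L, contaminate = 2L)
  sc2 <- coelution_scores(dirty)
  expect_identical(names(which.min(sc2)), "y4")
  expect_lt(sc2[["y4"]], 0.9)
  grid <- dirty$traces[["y3"]]$time
  mat <- vapply(dirty$traces, function(tr)
    approx(tr$time, tr$intensity, xout = grid, rule = 2)$y,
    numeric(length(grid)))
  med <- apply(mat, 1, median)
  expect_equal(unname(sc2), unname(apply(mat, 2, cor, y = med)),
               tolerance = 1e-10)

  # flat zero trace: undefined correlation, counted as failing
  flat <- make_entry(n_trans = 4L, flat = 3L)
  sc3 <- coelution_scores(flat)
  expect_true(is.na(sc3[["y5"]]))
  expect_identical(count_clean_transitions(flat)[1], 3L)
})

test_that("clean-transition counting follows the correlation threshold", {
  expect_identical(count_clean_transitions(make_entry(n_trans = 4L))[1], 4L)
  expect_identical(
    count_clean_transitions(make_entry(n_trans = 4L, contaminate = 2L))[1],
    3L)
  # a single transition cannot establish co-elution
  one <- make_entry(n_trans = 1L)
  expect_identical(count_clean_transitions(one)[1], 0L)
  # fewer than two traces: relative-intensity fallback kicks in
  notrace <- make_entry(n_trans = 4L, traces = FALSE)
  n <- count_clean_transitions(notrace)
  expect_identical(n[1], 4L)
  expect_identical(attr(n, "fallback"), 4L)
})

test_that("filter_precursors applies disjoint area, width and cleanliness rules", {
  entries <- list()
  peps <- sprintf("PEP%03dK", 1:100)
  for (i in 1:100) {
    area <- if (i <= 20) 200 else 5000          # 20 fail min_area 500
    width <- if (i > 20 && i <= 30) 3 else 13.9 # 10 fail width 5.2-45 s
    cont <- if (i > 30 && i <= 40) 2:3 else integer(0) # 10 drop to 2 clean
    entries[[i]] <- make_entry(peps[i], 2L, n_trans = 4L,
                               apex = 1 + i * 0.28, width_s = width,
                               area = area, contaminate = cont)
  }
  lib <- chrom_library(entries, 30)
  out <- filter_precursors(lib, filter_params(min_area = 500,
                                              min_width = 5.2,
                                              max_width = 45,
                                              min_clean_transitions = 3))
  rep <- filter_report(out)
  expect_identical(rep$n_in, 100L)
  expect_identical(rep$n_pass, 60L)
  expect_identical(rep$fail_area, 20L)
  expect_identical(rep$fail_width, 10L)
  expect_identical(rep$fail_clean, 10L)
  expect_length(out, 60L)
  # matches an independent row-by-row rule evaluation
  expect_setequal(precursor_table(out)$key,
                  oracle_filter_keys(lib, filter_params(500, 5.2, 45, 3)))
  # wide-open thresholds are the identity
  all_pass <- filter_precursors(lib, filter_params(
    min_area = 0, min_width = 1e-6, max_width = Inf,
    min_clean_transitions = 1))
  expect_length(all_pass, 100L)
})

test_that("tightening thresholds never enlarges the surviving set, and filtering is idempotent", {
  lib <- generate_library(generator_config("small", n_proteins = 40,
                                           interference_fraction = 0.2,
                                           seed = 13))
  set.seed(99)
  for (rep in 1:25) {
    loose <- filter_params(min_area = runif(1, 0, 2e4),
                           min_width = runif(1, 1, 8),
                           max_width = runif(1, 20, 60),
                           min_clean_transitions = sample(1:4, 1),
                           coelution_r_min = runif(1, 0.5, 0.95))
    tight <- filter_params(min_area = loose$min_area * runif(1, 1, 3),
                           min_width = loose$min_width + runif(1, 0, 4),
                           max_width = loose$max_width - runif(1, 0, 10),
                           min_clean_transitions =
                             loose$min_clean_transitions + sample(0:2, 1),
                           coelution_r_min =
                             min(0.999, loose$coelution_r_min + runif(1, 0, 0.05)))
    k_loose <- precursor_table(filter_precursors(lib, loose))$key
    k_tight <- precursor_table(filter_precursors(lib, tight))$key
    expect_true(all(k_tight %in% k_loose))
  }
  once <- filter_precursors(lib, filter_params())
  twice <- filter_precursors(once, filter_params())
  expect_identical(precursor_table(twice)$key, precursor_table(once)$key)
})

test_that("replicate-CV refinement computes TIC-invariant sample CVs", {
  lib <- make_library(c(10, 15, 20))
  tab <- precursor_table(lib)
  # precursor 1: (100,100,100), precursor 2: (80,100,120), precursor 3 noisy
  areas <- data.frame(
    peptide = rep(tab$peptide, each = 3), charge = 2L,
    replicate = rep(c("a", "b", "c"), 3),
    area = c(100, 100, 100, 80, 100, 120, 500, 200, 900))
  kept30 <- refine_by_replicate_cv(lib, areas, cv_max = 30)
  expect_setequal(precursor_table(kept30)$peptide, tab$peptide[1:2])
  cvt <- attr(kept30, "cv_table")
  expect_equal(cvt$cv[cvt$key == tab$key[2]], 20)   # sd 20 / mean 100
  kept15 <- refine_by_replicate_cv(lib, areas, cv_max = 15)
  expect_setequal(precursor_table(kept15)$peptide, tab$peptide[1])
  # TIC normalization: scaling one replicate x2 changes nothing after TIC
  areas2 <- areas
  areas2$area[areas2$replicate == "b"] <- areas2$area[areas2$replicate == "b"] * 2
  cv_tic <- attr(refine_by_replicate_cv(lib, areas2, cv_max = 30,
                                        normalize = "tic"), "cv_table")
  cv_ref <- attr(refine_by_replicate_cv(lib, areas, cv_max = 30,
                                        normalize = "tic"), "cv_table")
  expect_equal(cv_tic$cv, cv_ref$cv, tolerance = 1e-12)
})

test_that("curve-performance refinement matches independent rule evaluation", {
  lib <- make_library(seq(2, 28, length.out = 20))
  tab <- precursor_table(lib)
  set.seed(5)
  fom <- data.frame(peptide = tab$peptide, charge = tab$charge,
                    cv = runif(20, 0, 40),
                    log2_ratio = log2(0.5) + runif(20, -1, 1),
                    log2_expected = log2(0.5))
  kept <- refine_by_curve_performance(lib, fom, cv_max = 20, ratio_tol = 0.5)
  manual <- fom$cv < 20 &
    abs(2^(fom$log2_ratio - fom$log2_expected) - 1) <= 0.5
  expect_setequal(precursor_table(kept)$key, tab$key[manual])
  # rule examples: within 50% of expected is kept, CV 25% is dropped
  ex <- data.frame(peptide = tab$peptide[1:2], charge = 2L,
                   cv = c(10, 25),
                   log2_ratio = log2(c(0.6, 0.5)),
                   log2_expected = log2(0.5))
  kept2 <- refine_by_curve_performance(subset_lib <- make_library(c(10, 15)),
                                       transform(ex,
                                         peptide = precursor_table(subset_lib)$peptide))
  expect_identical(precursor_table(kept2)$peptide,
                   precursor_table(subset_lib)$peptide[1])
})
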