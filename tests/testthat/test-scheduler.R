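test_that("cycle time is peak width over points per peak", {
  expect_equal(round(compute_cycle_time(12.9, 6), 2), 2.15)
  expect_equal(round(compute_cycle_time(13.07, 6), 2), 2.18)
  expect_equal(round(compute_cycle_time(12, 7), 2), 1.71)
  expect_equal(compute_cycle_time(8.4, 1), 8.4)
  expect_error(compute_cycle_time(12, 0), class = "invalid_params")
})

test_that("per-target time and capacity follow the duty-cycle model", {
  p0 <- acquisition_params(interscan_overhead = 0)
  expect_equal(per_target_time(p0), 1300 / 125000 + 0.015)  # 0.0254 s
  expect_equal(per_target_time(p0), 0.0254)
  # linearity in overhead
  p2 <- acquisition_params(interscan_overhead = 2)
  expect_equal(per_target_time(p2) - per_target_time(p0), 0.002)
  # zero-width scan range: injection + overhead only
  pz <- acquisition_params(scan_lo = 500, scan_hi = 500.0001,
                           interscan_overhead = 5)
  expect_equal(per_target_time(pz), 0.02, tolerance = 1e-6)

  expect_identical(capacity(p0), as.integer(floor(2.15 / 0.0254)))
  expect_identical(capacity(p0), 84L)
  # cycle an exact multiple of the per-target time: 1 s / 0.05 s = 20
  pk <- acquisition_params(scan_rate = 65000, min_injection_time = 30,
                           interscan_overhead = 0,
                           expected_peak_width = 6, points_per_peak = 6)
  expect_identical(capacity(pk), 20L)
  pbig <- acquisition_params(min_injection_time = 5000,
                             expected_peak_width = 6)
  expect_warning(expect_identical(capacity(pbig), 0L), "capacity")
})

test_that("windows cover every reference RT, respect the minimum width, and grow without contention", {
  lib <- make_library(seq(3, 27, length.out = 10))
  params <- acquisition_params()
  plan <- assign_windows(lib, params)
  e <- plan$entries
  expect_true(plan$feasible)
  expect_true(all(e$window_end - e$window_start >= params$min_window - 1e-9))
  expect_true(all(e$ref_rt >= e$window_start & e$ref_rt <= e$window_end))
  # uncontended windows grow to (near) the configured cap
  expect_true(all(e$window_end - e$window_start >=
                  params$max_window - 2 * 0.05))
})

test_that("forced contention is reported as an infeasible plan with violations", {
  lib <- make_library(rep(15, 200))
  params <- acquisition_params()
  expect_lt(capacity(params), 200)
  plan <- assign_windows(lib, params)
  expect_false(plan$feasible)
  expect_gt(nrow(plan$violations), 0)
  expect_true(any(plan$violations$count > plan$capacity))
  expect_true(all(plan$violations$time >= 14 & plan$violations$time <= 16))
})

test_that("feasible plans pass the brute-force 0.1 s duty-cycle oracle", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(50:220, 1)
    lib <- make_library(sort(runif(n, 0.5, 29.5)))
    plan <- assign_windows(lib, acquisition_params(), grow = i %% 2 == 0)
    if (plan$feasible) expect_true(oracle_duty_cycle_ok(plan))
    # max_concurrent agrees with a brute-force sweep
    grid <- seq(0, 30, by = 0.1 / 60)
    cnt <- integer(length(grid))
    for (j in seq_len(nrow(plan$entries))) {
      idx <- which(grid >= plan$entries$window_start[j] &
                   grid <= plan$entries$window_end[j])
      cnt[idx] <- cnt[idx] + 1L
    }
    expect_identical(plan$max_concurrent, max(cnt))
  }
})

test_that("plans are deterministic given identical inputs", {
  lib <- generate_library(generator_config("small", n_proteins = 30,
                                           seed = 17))
  p1 <- assign_windows(lib, acquisition_params())
  p2 <- assign_windows(lib, acquisition_params())
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
})

test_that("target selection respects capacity and the protein objective dominates on proteins", {
  # ample capacity: both objectives keep everything
  lib <- make_library(seq(2, 28, length.out = 40))
  params <- acquisition_params()
  expect_length(select_targets(lib, params, "max_precursors"), 40L)
  expect_length(select_targets(lib, params, "max_proteins"), 40L)

  # 10 proteins x 10 co-eluting precursors, capacity ~ 12
  set.seed(8)
  rts <- rep(15, 100) + runif(100, -0.1, 0.1)
  prots <- rep(sprintf("PROT%02d", 1:10), each = 10)
  lib2 <- make_library(rts, proteins = prots)
  params2 <- acquisition_params(min_injection_time = 80,
                                expected_peak_width = 7.2)
  expect_identical(capacity(params2), 12L)
  by_prec <- select_targets(lib2, params2, "max_precursors")
  by_prot <- select_targets(lib2, params2, "max_proteins",
                            per_protein_quota = 1)
  n_prot <- function(l) length(unique(precursor_table(l)$protein))
  expect_gte(n_prot(by_prot), n_prot(by_prec))
  expect_gte(length(by_prec), length(by_prot))
  expect_identical(n_prot(by_prot), 10L)
  # quota 1: the first 10 admissions cover 10 distinct proteins
  expect_true(all(table(precursor_table(by_prot)$protein) >= 1))
})

test_that("injection splitting partitions the library into feasible groups", {
  # already feasible: one injection
  lib <- make_library(seq(2, 28, length.out = 20))
  plan1 <- split_injections(lib, acquisition_params())
  expect_identical(plan1$n_injections, 1L)
  expect_true(plan1$feasible)

  # density twice the capacity everywhere: two balanced feasible groups
  params <- acquisition_params(min_injection_time = 80,
                               expected_peak_width = 6)
  cap <- capacity(params)  # 10
  rts <- rep(seq(2, 28, by = 0.2), each = 2 * cap %/% 4)
  lib2 <- make_library(rts[seq_len(min(length(rts), 600))])
  plan2 <- split_injections(lib2, params, max_injections = 4)
  expect_true(plan2$feasible)
  expect_true(oracle_duty_cycle_ok(plan2))
  sizes <- table(plan2$entries$injection)
  expect_lte(max(sizes) - min(sizes), max(sizes) * 0.5)

  # disjoint over-capacity RT clusters split along the clusters
  lib3 <- make_library(c(rep(5, 2 * cap - 2), rep(25, 2 * cap - 2)))
  plan3 <- split_injections(lib3, params, max_injections = 3)
  expect_identical(plan3$n_injections, 2L)
  expect_true(plan3$feasible)

  # impossible within the injection cap: explicit failure
  lib4 <- make_library(rep(15, 5 * cap))
  expect_error(split_injections(lib4, params, max_injections = 2),
               class = "infeasible_split")
})

test_that("wide-to-narrow rescheduling recenters on observed apexes and flags the rest", {
  lib <- make_library(seq(3, 27, length.out = 20))
  params <- acquisition_params(min_window = 2.4, max_window = 2.4)
  wide <- assign_windows(lib, params, grow = FALSE)
  tab <- precursor_table(lib)

  # apexes observed exactly at window centers: narrow plan keeps centers
  obs <- data.frame(peptide = tab$peptide, charge = tab$charge,
                    apex_rt = tab$ref_rt)
  narrow_params <- acquisition_params(min_window = 0.75)
  wide$params <- narrow_params
  narrow <- wide_to_narrow_reschedule(wide, obs)
  expect_equal((narrow$entries$window_start + narrow$entries$window_end) / 2,
               tab$ref_rt[match(narrow$entries$key, tab$key)],
               tolerance = 1e-6)
  expect_true(all(narrow$entries$window_end - narrow$entries$window_start >=
                  0.75 - 1e-9))

  # +0.5 min shift: windows follow the measured apex
  obs2 <- transform(obs, apex_rt = apex_rt + 0.5)
  narrow2 <- wide_to_narrow_reschedule(wide, obs2)
  expect_equal((narrow2$entries$window_start + narrow2$entries$window_end) / 2,
               tab$ref_rt[match(narrow2$entries$key, tab$key)] + 0.5,
               tolerance = 1e-6)

  # 10% unobserved: flagged, centered on the wide-window prediction
  obs3 <- obs[1:18, ]
  narrow3 <- wide_to_narrow_reschedule(wide, obs3)
  expect_identical(sum(!narrow3$entries$observed), 2L)
})
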