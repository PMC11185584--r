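# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk.

# A hand-built precursor entry with Gaussian traces on a shared time grid.
# `contaminate` adds a shifted 5x contaminant peak to that transition.
make_entry <- function(peptide = "ELVISLIVESK", charge = 2L,
                       n_trans = 4L, apex = 10, width_s = 13.9,
                       area = 5000, contaminate = integer(0),
                       flat = integer(0), traces = TRUE,
                       protein = "P1") {
  sigma <- width_s / 4
  half <- width_s / 2 / 60
  tgrid <- seq(apex - half, apex + half, length.out = 25)
  rel <- seq(1, 0.4, length.out = n_trans)
  rel <- rel / sum(rel)
  frag <- paste0("y", seq(3, length.out = n_trans))
  tr_list <- list()
  areas <- area * rel
  for (j in seq_len(n_trans)) {
    amp <- areas[j] / (sigma * sqrt(2 * pi))
    y <- amp * exp(-((tgrid - apex) * 60)^2 / (2 * sigma^2))
    if (j %in% contaminate)
      y <- y + 5 * amp * exp(-((tgrid - apex - width_s / 3 / 60) * 60)^2 /
                             (2 * sigma^2))
    if (j %in% flat) y <- rep(0, length(tgrid))
    tr_list[[frag[j]]] <- data.frame(time = tgrid, intensity = y)
  }
  trans <- data.frame(fragment = frag,
                      product_mz = seq(300, 900, length.out = n_trans),
                      area = areas, apex_rt = apex,
                      start_rt = apex - half, end_rt = apex + half,
                      expected_rel = rel)
  precursor_entry(peptide, charge, 550.5, protein, trans,
                  traces = if (traces) tr_list else NULL)
}

# Library of n precursors at given retention times, minimal transitions.
make_library <- function(rts, gradient = 30, width_s = 13.9, area = 5000,
                         n_trans = 4L, proteins = NULL) {
  peps <- sprintf("PEPTIDE%04dK", seq_along(rts))
  if (is.null(proteins)) proteins <- sprintf("P%03d", seq_along(rts))
  entries <- Map(function(pep, rt, prot)
    make_entry(pep, 2L, n_trans = n_trans, apex = rt, width_s = width_s,
               area = area, traces = FALSE, protein = prot),
    peps, rts, proteins)
  chrom_library(unname(entries), gradient)
}

# Independent brute-force duty-cycle oracle: counts active windows on a
# 0.1 s grid and checks concurrent x per-target time <= cycle time.
oracle_duty_cycle_ok <- function(plan, grid_step_s = 0.1) {
  ok <- TRUE
  for (inj in seq_len(plan$n_injections)) {
    e <- plan$entries[plan$entries$injection == inj, , drop = FALSE]
    if (!nrow(e)) next
    grid <- seq(0, plan$params$gradient_length, by = grid_step_s / 60)
    cnt <- integer(length(grid))
    for (i in seq_len(nrow(e))) {
      idx <- which(grid >= e$window_start[i] & grid <= e$window_end[i])
      cnt[idx] <- cnt[idx] + 1L
    }
    ok <- ok && all(cnt * plan$per_target_time <= plan$cycle_time + 1e-9)
  }
  ok
}

# Row-by-row re-evaluation of the filter rules, independent of
# filter_precursors internals.
oracle_filter_keys <- function(lib, params) {
  keep <- vapply(lib$precursors, function(p) {
    frag <- unique(p$transitions$fragment)
    n_clean <- if (length(frag) < 2) 0L else {
      sc <- coelution_scores(p)
      sum(!is.na(sc) & sc >= params$coelution_r_min)
    }
    p$total_area >= params$min_area &&
      p$peak_width >= params$min_width &&
      p$peak_width <= params$max_width &&
      n_clean >= params$min_clean_transitions
  }, TRUE)
  precursor_table(lib)$key[keep]
}
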