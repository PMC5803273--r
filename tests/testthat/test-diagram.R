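test_that("build_diagram assigns every sample of the 8 wt% series correctly", {
  series <- simulate_hydration_series(8, seed = 2)
  diagram <- build_diagram(series)
  expect_equal(nrow(diagram), 5)
  expect_false(any(diagram$unassigned))
  expect_equal(diagram$phase, series$phase_true)
  expect_true(all(abs(diagram$lattice - series$lattice_true) /
                    series$lattice_true < 0.005))
  # cubic points carry geometry
  expect_true(all(is.finite(diagram$d_w)))
})

test_that("build_diagram validates input and flags unassignable samples", {
  expect_error(build_diagram(tibble::tibble()), class = "lcp_validation_error")
  series <- simulate_hydration_series(5, seed = 3)[1, ]
  expect_error(build_diagram(series[, c("sample_id", "water_wt_pct")]),
               class = "lcp_validation_error")

  # featureless profile: retained, flagged unassigned
  flat <- series
  flat$profile <- list(saxs_profile(seq(0.01, 0.5, length.out = 100),
                                    rep(1, 100)))
  d <- build_diagram(flat)
  expect_equal(nrow(d), 1)
  expect_true(d$unassigned)
  expect_true(is.na(d$phase))
})

test_that("a coexisting sample yields two assignments in its diagram point", {
  mix <- simulate_coexistence(list(phase = "Ia3d", lattice = 500),
                              list(phase = "La", lattice = 55),
                              weight = 0.7, noise_rel_sigma = 0.005, seed = 21)
  samples <- tibble::tibble(sample_id = "coex", water_wt_pct = 80,
                            dspg_wt_pct_of_lipid = 10,
                            profile = list(mix$profile))
  d <- build_diagram(samples)
  expect_equal(d$n_assignments, 2)
  asg <- d$assignments[[1]]
  expect_setequal(asg$phase, c("Ia3d", "La"))
  # the cubic assignment carries channel geometry even when the lamellar one
  # scores higher; the lamellar row has none
  expect_true(is.finite(asg$d_w[asg$phase == "Ia3d"]))
  expect_true(is.na(asg$d_w[asg$phase == "La"]))
  expect_true(d$phase %in% c("Ia3d", "La"))
})

test_that("collapse_sequence merges runs and reports censored boundaries", {
  pts <- tibble::tibble(
    water_wt_pct = c(55, 60, 65, 70, 75, 80),
    phase = c("Pn3m", "Pn3m", "Im3m", "Im3m", "Im3m", "Pn3m"),
    dspg_wt_pct_of_lipid = 5)
  seq5 <- collapse_sequence(pts)
  expect_equal(seq5$runs$phase, c("Pn3m", "Im3m", "Pn3m"))
  expect_equal(seq5$boundaries$midpoint, c(62.5, 77.5))
  expect_equal(seq5$boundaries$water_lo, c(60, 75))
  expect_equal(seq5$boundaries$water_hi, c(65, 80))

  pts8 <- tibble::tibble(
    water_wt_pct = c(60, 65, 70, 75, 80),
    phase = c("Ia3d", "Pn3m", "Pn3m", "Ia3d", "Ia3d"),
    dspg_wt_pct_of_lipid = 8)
  expect_equal(collapse_sequence(pts8)$runs$phase, c("Ia3d", "Pn3m", "Ia3d"))

  single <- collapse_sequence(pts8[1, ])
  expect_equal(nrow(single$runs), 1)
  expect_equal(nrow(single$boundaries), 0)

  dup <- pts8
  dup$water_wt_pct[2] <- 60
  expect_error(collapse_sequence(dup), class = "lcp_validation_error")
  expect_error(collapse_sequence(dplyr::bind_rows(pts, pts8)),
               class = "lcp_validation_error")
})

test_that("re-entrance detection over the definition, exhaustively checked", {
  expect_true(detect_reentrance(c("Pn3m", "Im3m", "Pn3m"))$is_reentrant)
  expect_equal(detect_reentrance(c("Pn3m", "Im3m", "Pn3m"))$reentrant_phase,
               "Pn3m")
  expect_false(detect_reentrance(c("Ia3d", "Pn3m"))$is_reentrant)
  r <- detect_reentrance(c("Ia3d", "Pn3m", "Ia3d", "Pn3m"))
  expect_true(r$is_reentrant)
  expect_equal(r$reentrant_phase, "Ia3d")  # earliest recurring phase

  # enumeration over all length-4 sequences of 3 phases: flag iff some phase
  # recurs in non-adjacent runs of the collapsed sequence
  phases <- c("Ia3d", "Pn3m", "Im3m")
  grid <- expand.grid(p1 = phases, p2 = phases, p3 = phases, p4 = phases,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    s <- unlist(grid[i, ], use.names = FALSE)
    runs <- rle(s)$values
    expected <- any(duplicated(runs))
    expect_equal(detect_reentrance(s)$is_reentrant, expected,
                 label = paste(s, collapse = ">"))
  }

  # idempotent under collapse: raw steps and collapsed runs agree
  raw <- c("Ia3d", "Ia3d", "Pn3m", "Ia3d", "Ia3d")
  expect_equal(detect_reentrance(raw), detect_reentrance(rle(raw)$values))
})

test_that("channel_vs_hydration returns a tidy monotone table", {
  series <- simulate_hydration_series(8, seed = 6)
  diagram <- build_diagram(series)
  tab <- channel_vs_hydration(diagram)
  expect_equal(nrow(tab), 5)
  expect_equal(names(tab), c("sample_id", "water_wt_pct",
                             "dspg_wt_pct_of_lipid", "phase", "lattice", "d_w"))
  # swelling: d_w increases with hydration within each phase run
  for (ph in unique(tab$phase)) {
    sub <- tab[tab$phase == ph, ]
    expect_true(all(diff(sub$d_w) > 0), label = ph)
  }
  empty <- channel_vs_hydration(diagram[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the 80% 8 wt% point reproduces the 226 A channel diameter", {
  series <- simulate_hydration_series(8, seed = 8, noise_rel_sigma = 0)
  diagram <- build_diagram(series)
  endpoint <- diagram[diagram$water_wt_pct == 80, ]
  expect_equal(endpoint$phase, "Ia3d")
  expect_equal(round(endpoint$d_w), 226)
})

test_that("sample order does not change per-sample assignments", {
  series <- simulate_hydration_series(5, seed = 9)
  d1 <- build_diagram(series)
  d2 <- build_diagram(series[rev(seq_len(nrow(series))), ])
  d2 <- d2[match(d1$sample_id, d2$sample_id), ]
  expect_equal(d2$phase, d1$phase)
  expect_equal(d2$lattice, d1$lattice, tolerance = 1e-12)
})
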