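test_that("exact Pn3m ratios index to the exact lattice", {
  pk <- exact_peaks(2 * pi * sqrt(c(2, 3, 4)) / 100)
  fit <- index_phase(pk, "Pn3m")
  expect_true(fit$fitted)
  expect_equal(fit$lattice, 100, tolerance = 1e-10)
  expect_lt(fit$rms_rel_residual, 1e-10)
  expect_equal(fit$n_matched, 3L)
  expect_equal(tidy(fit)$multiplier, sqrt(c(2, 3, 4)))
  expect_equal(glance(fit)$phase, "Pn3m")
})

test_that("two-reflection ultra-swollen Ia3d pattern recovers a = 525", {
  pk <- exact_peaks(2 * pi * sqrt(c(6, 8)) / 525)
  fit <- index_phase(pk, "Ia3d")
  expect_true(fit$fitted)
  expect_equal(fit$lattice, 525, tolerance = 0.1)
  # sqrt(8)/sqrt(6) equals sqrt(4)/sqrt(3) exactly, so Pn3m also fits these
  # two peaks (anchored at sqrt(3), skipping sqrt(2)); the ranking must still
  # prefer Ia3d through the skipped-low-order penalty.
  ranked <- rank_phases(pk, phase_models(c("Ia3d", "Pn3m")))
  expect_equal(ranked$phase[1], "Ia3d")
  pn3m <- index_phase(pk, "Pn3m")
  expect_true(pn3m$fitted)
  expect_gt(pn3m$n_skipped, 0)
  expect_lt(ranked$score[2], ranked$score[1])
})

test_that("ranking identifies each phase from its noiseless pattern", {
  cases <- list(
    list(phase = "Im3m", lattice = 200, n = 4),
    list(phase = "Ia3d", lattice = 350, n = 4),
    list(phase = "Pn3m", lattice = 150, n = 5),
    list(phase = "La", lattice = 60, n = 3))
  for (cs in cases) {
    pk <- exact_peaks(reflection_positions(cs$phase, cs$lattice, cs$n))
    ranked <- rank_phases(pk)
    expect_equal(ranked$phase[1], cs$phase, label = cs$phase)
    expect_equal(ranked$lattice[1], cs$lattice, tolerance = 0.05,
                 label = cs$phase)
  }
})

test_that("fewer than 2 peaks gives a flagged no-fit, not an error", {
  fit <- index_phase(exact_peaks(0.1), "Pn3m")
  expect_false(fit$fitted)
  expect_equal(fit$n_matched, 0L)
  expect_equal(nrow(tidy(fit)), 0)
  expect_equal(nrow(rank_phases(exact_peaks(numeric(0)))), 0)
})

test_that("scale equivariance: scaling q scales the lattice inversely", {
  pk <- exact_peaks(reflection_positions("Ia3d", 400, 5))
  f1 <- index_phase(pk, "Ia3d")
  for (cc in c(0.5, 2, 3.7)) {
    f2 <- index_phase(exact_peaks(pk$q_center * cc), "Ia3d")
    expect_equal(f2$lattice * cc, f1$lattice, tolerance = 1e-12)
  }
})

test_that("noiseless subsets of >= 2 reflections recover 2*pi/k exactly", {
  m <- phase_models("Pn3m")$multipliers[[1]]
  a <- 237.5
  k <- 2 * pi / a
  # subsets whose ratio pattern is not a pure rescaling of a lower-order
  # assignment (e.g. {sqrt(3), sqrt(6)} scales exactly onto {sqrt(2), sqrt(4)}
  # and is inherently ambiguous; such aliases are excluded)
  subsets <- list(c(1, 2), c(2, 3), c(1, 3, 5), c(3, 4, 5, 6), seq_len(8))
  for (ss in subsets) {
    fit <- index_phase(exact_peaks(k * m[ss]), "Pn3m")
    expect_equal(fit$lattice, a, tolerance = a * 1e-9)
  }
})

test_that("indexing is invariant to peak-height rescaling", {
  q <- reflection_positions("Im3m", 280, 5)
  f1 <- index_phase(exact_peaks(q, height = 1), "Im3m")
  f2 <- index_phase(exact_peaks(q, height = 50), "Im3m")
  h <- c(5, 3, 2, 1, 0.5)
  f3 <- index_phase(tibble::tibble(q_center = q, height = h), "Im3m")
  expect_equal(f2$lattice, f1$lattice, tolerance = 1e-12)
  expect_equal(f3$lattice, f1$lattice, tolerance = 1e-12)
})

test_that("greedy anchoring matches the exhaustive oracle on <= 5 peaks", {
  set.seed(101)
  for (trial in 1:40) {
    phase <- sample(c("Ia3d", "Pn3m", "Im3m", "La"), 1)
    model <- phase_models(phase)
    m <- model$multipliers[[1]]
    a <- stats::runif(1, 80, 500)
    n <- sample(2:5, 1)
    # lowest reflection within the first three multipliers (the anchoring
    # domain); higher ones drawn freely above it
    start <- sample(1:3, 1)
    n <- min(n, length(m) - start + 1)
    pool <- seq(start + 1, length(m))
    idx <- c(start, sort(pool[sample.int(length(pool), n - 1)]))
    q <- 2 * pi * m[idx] / a
    w <- stats::runif(length(q), 0.5, 2)
    pk <- tibble::tibble(q_center = q, height = w)
    fit <- index_phase(pk, phase, rel_tol = 0.005)
    oracle <- brute_force_index(q, w, m, rel_tol = 0.005)
    expect_false(is.null(oracle))
    expect_true(fit$fitted)
    expect_equal(fit$n_matched, oracle$n)
    expect_equal(fit$rms_rel_residual, oracle$rms, tolerance = 1e-9)
  }
})

test_that("200 seeded noisy fixtures rank the generating phase first", {
  phases <- c("Ia3d", "Pn3m", "Im3m", "La")
  n_correct <- 0
  n_lattice_ok <- 0
  for (s in 1:200) {
    phase <- phases[(s %% 4) + 1]
    lattice <- if (phase == "La") 40 + (s * 13) %% 50 else 100 + (s * 17) %% 350
    sim <- simulate_saxs_profile(phase, lattice, n_reflections = 4,
                                 noise_rel_sigma = 0.01, seed = 1000 + s)
    pk <- find_peaks(sim$profile)
    ranked <- rank_phases(pk)
    if (nrow(ranked) > 0 && ranked$phase[1] == phase) {
      n_correct <- n_correct + 1
      if (abs(ranked$lattice[1] - lattice) / lattice < 0.005) {
        n_lattice_ok <- n_lattice_ok + 1
      }
    }
  }
  expect_gte(n_correct, 198)      # >= 99%
  expect_gte(n_lattice_ok, 198)   # lattice within 0.5% whenever phase correct
})

test_that("coexistence peeling recovers Ia3d + La and leaves singles alone", {
  qa <- reflection_positions("Ia3d", 500, 4)
  qb <- reflection_positions("La", 55, 3)
  pk <- exact_peaks(c(qa, qb), height = c(rep(1, 4), rep(0.6, 3)))
  res <- decompose_coexistence(pk)
  expect_equal(nrow(res), 2)
  expect_setequal(res$phase, c("Ia3d", "La"))
  expect_equal(res$lattice[res$phase == "Ia3d"], 500, tolerance = 500 * 0.005)
  expect_equal(res$lattice[res$phase == "La"], 55, tolerance = 55 * 0.005)
  expect_equal(res$phase[1], "Ia3d")  # majority phase first

  single <- decompose_coexistence(exact_peaks(
    reflection_positions("Pn3m", 200, 4)))
  expect_equal(nrow(single), 1)
  expect_equal(single$phase, "Pn3m")
})

test_that("a spurious peak stays unmatched and does not break the fit", {
  q <- reflection_positions("Ia3d", 450, 4)
  pk <- exact_peaks(sort(c(q, 0.123)), height = 1)
  res <- decompose_coexistence(pk)
  top <- res$fit[[1]]
  expect_equal(res$phase[1], "Ia3d")
  expect_equal(res$lattice[1], 450, tolerance = 450 * 0.005)
  expect_false(any(abs(top$matches$q_obs - 0.123) < 1e-9))
})
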