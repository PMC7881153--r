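# Affinity/abundance determinants: Kd groups, slope fits, key effectors.

test_that("Kd grouping separates shared values from singletons", {
  cfg <- synthesis_config(seed = 61)
  panel <- generate_panel(cfg)
  g <- group_by_kd(panel)
  g75 <- g[g$kd_um == 7.5, ]
  expect_equal(g75$n, 4L)
  expect_setequal(strsplit(g75$effectors, ";")[[1]],
                  c("PIK3CD", "ARAP1", "RADIL", "MYO9A"))
  g007 <- g[g$kd_um == 0.07, ]
  expect_equal(g007$n, 1L)
  expect_true(g007$singleton)
  expect_equal(g007$effectors, "ARAF")
  # all-distinct panel: only singletons
  pan <- ras_panel(c("X", "Y", "Z"), c(1, 2, 3), c(0.1, 0.2, 0.3))
  expect_true(all(group_by_kd(pan)$singleton))
})

test_that("fitted slopes equal the analytic equilibrium slope", {
  # every shared-Kd group lies on the line with slope
  # 100 R* / ((Kd + R*) C_tot); the OLS and through-origin fits must find it
  cfg <- synthesis_config(seed = 63)
  panel <- generate_panel(cfg)
  profs <- generate_tissues(cfg, panel)
  for (prof in profs[c(3, 11, 24)]) {
    st <- solve_tissue(prof, panel)
    fits <- fit_abundance_complex_lines(st, panel, prof$effectors)
    expect_gt(nrow(fits), 0)
    expected <- analytic_slope(st$free_ras, fits$kd_um, st$total_complexes)
    expect_equal(fits$slope, expected, tolerance = 1e-9)
    expect_true(all(fits$intercept[fits$through_origin] == 0))
    expect_true(all(abs(fits$intercept) < 1e-9))
  }
})

test_that("singleton rules: two-point line, sub-threshold skip", {
  pan <- ras_panel(c("S", "T"), c(1, 2), c(1, 2))
  st <- solve_equilibrium(50, pan, c(S = 80, T = 100))
  fits <- fit_abundance_complex_lines(st, pan, c(S = 80, T = 100))
  s_row <- fits[fits$kd_um == 1, ]
  expect_true(s_row$through_origin)
  expect_equal(s_row$slope, st$complexes_pct[["S"]] / 80, tolerance = 1e-12)
  # a singleton whose share is below 0.001 percent yields no fit
  pan2 <- ras_panel(c("BIG", "TINY"), c(1, 2), c(0.05, 30))
  ab2 <- c(BIG = 5000, TINY = 1e-4)
  st2 <- solve_equilibrium(100, pan2, ab2)
  expect_lt(st2$complexes_pct[["TINY"]], 0.001)
  fits2 <- fit_abundance_complex_lines(st2, pan2, ab2)
  expect_false(30 %in% fits2$kd_um)
})

test_that("slopes fall with Kd and the summary orders tissues by mean slope", {
  cfg <- synthesis_config(seed = 65)
  panel <- generate_panel(cfg)
  profs <- generate_tissues(cfg, panel)
  all_fits <- do.call(rbind, lapply(profs[1:6], function(p) {
    fit_abundance_complex_lines(solve_tissue(p, panel), panel, p$effectors)
  }))
  # within each tissue the analytic slope is strictly decreasing in Kd
  for (df in split(all_fits, all_fits$tissue)) {
    df <- df[order(df$kd_um), ]
    expect_true(all(diff(df$slope) < 0))
  }
  summ <- slope_summary(all_fits)
  expect_equal(summ$avg_slope, sort(summ$avg_slope))
  expect_true(all(c("kd_0.04_0.09", "kd_0.21_1", "kd_2.9_50") %in% names(summ)))
  # single tissue summarizes to itself
  one <- slope_summary(all_fits[all_fits$tissue == all_fits$tissue[1], ])
  expect_equal(nrow(one), 1L)
})

test_that("surface grid evaluates the fitted lines piecewise-linearly", {
  fits <- data.frame(tissue = "t", kd_um = c(1, 2), slope = c(0.1, 0.05),
                     intercept = c(0, 0), n_points = c(1L, 3L),
                     through_origin = c(TRUE, FALSE))
  sg <- surface_grid(fits, abundance_grid = c(0, 100, 200))
  expect_equal(nrow(sg), 6L)
  expect_equal(sg$complex_pct[sg$kd_um == 1], c(0, 10, 20))
})

test_that("key-effector extraction is inclusive at the threshold", {
  res <- data.frame(tissue = rep(c("t1", "t2"), each = 3),
                    effector = rep(c("A", "B", "C"), 2),
                    complex_pct = c(5.0, 4.999, 80, 0.5, 2, 90),
                    stringsAsFactors = FALSE)
  ke <- key_effectors(res, threshold = 5)
  expect_setequal(ke$effectors, c("A", "C"))   # 5.0 is included
  expect_equal(ke$per_tissue$n_key[ke$per_tissue$tissue == "t1"], 2L)
  expect_equal(ke$per_tissue$n_key[ke$per_tissue$tissue == "t2"], 1L)
  expect_equal(unname(ke$rankings["t1", c("A", "C")]), c(2L, 1L))
  empty <- key_effectors(res[0, ])
  expect_length(empty$effectors, 0)
})

test_that("low-affinity effectors never beat an equal-abundance high-affinity one", {
  cfg <- synthesis_config(seed = 67)
  panel <- generate_panel(cfg)
  prof <- generate_tissues(cfg, panel)[[14]]
  ab <- prof$effectors
  ab[] <- 100  # equalize abundances
  st <- solve_equilibrium(active_ras_total(prof, gtp_scenario())$total,
                          panel, ab)
  hi <- panel$effector[panel$kd_um <= 1]
  lo <- panel$effector[panel$kd_um > 1]
  expect_gt(min(st$complexes_pct[hi]), max(st$complexes_pct[lo]))
})
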