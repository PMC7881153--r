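# Core competitive equilibrium: closed forms, oracle agreement, invariants.

test_that("active Ras pool is the scenario-weighted isoform sum", {
  prof <- toy_profile()
  expect_equal(active_ras_total(prof, gtp_scenario())$total, 100)
  expect_equal(active_ras_total(prof, gtp_scenario(kras = 1.0))$total, 340)
  zero <- tissue_profile("z", c(A = 1), c(HRAS = 0, KRAS = 0, NRAS = 0))
  expect_equal(active_ras_total(zero, gtp_scenario(2, 3, 4))$total, 0)
  noh <- tissue_profile("n", c(A = 1), c(KRAS = 10))
  expect_error(active_ras_total(noh, gtp_scenario()), "HRAS")
})

test_that("single-ligand solve matches the quadratic closed form", {
  for (case in list(c(100, 100, 100), c(50, 400, 12), c(1000, 3, 7500),
                    c(0.5, 0.5, 0.04))) {
    pan <- ras_panel("E", 1, case[3] / 1000)  # kd in uM
    eq <- solve_equilibrium(case[1], pan, c(E = case[2]))
    expected <- single_ligand_complex(case[1], case[2], case[3])
    expect_equal(eq$complexes_nm[["E"]], expected, tolerance = 1e-10)
  }
  # the worked reference point: 100 nM Ras, 100 nM effector, Kd 100 nM
  pan <- ras_panel("E", 1, 0.1)
  eq <- solve_equilibrium(100, pan, c(E = 100))
  expect_equal(eq$complexes_nm[["E"]], 38.19660112501051, tolerance = 1e-10)
})

test_that("two-effector competition matches the bracketed-root solution", {
  pan <- ras_panel(c("E1", "E2"), c(1, 2), c(0.05, 5))
  eq <- solve_equilibrium(100, pan, c(E1 = 200, E2 = 200))
  # independent check: bisection on the scalar conservation equation
  f <- function(r) r + r * 200 / (50 + r) + r * 200 / (5000 + r) - 100
  lo <- 0; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(eq$free_ras, (lo + hi) / 2, tolerance = 1e-12)
  expect_equal(unname(eq$complexes_nm),
               (lo + hi) / 2 * c(200, 200) / (c(50, 5000) + (lo + hi) / 2),
               tolerance = 1e-12)
  # coarse anchors for the same system
  expect_equal(eq$free_ras, 27.7, tolerance = 0.01)
  expect_equal(eq$complexes_nm[["E1"]], 71.2, tolerance = 0.01)
  expect_equal(eq$complexes_nm[["E2"]], 1.1, tolerance = 0.01)
})

test_that("root-finding equilibrium matches ODE mass-action integration", {
  set.seed(42)
  worst <- 0
  for (i in 1:40) {
    n <- sample(1:10, 1)
    pan <- random_panel(n, seed = i)
    ab <- random_abundances(pan, seed = i)
    r_tot <- runif(1, 1, 500)
    eq <- solve_equilibrium(r_tot, pan, ab)
    od <- ode_steady_state(r_tot, pan, ab, k_on = 1)
    rel <- max(abs(eq$complexes_nm - od$complexes_nm) /
                 pmax(abs(od$complexes_nm), 1e-9))
    worst <- max(worst, rel, abs(eq$free_ras - od$free_ras) /
                   max(od$free_ras, 1e-9))
  }
  expect_lt(worst, 1e-6)
})

test_that("oracle agreement is independent of the association rate", {
  pan <- random_panel(5, seed = 99)
  ab <- random_abundances(pan, seed = 99)
  eq <- solve_equilibrium(120, pan, ab)
  for (k_on in c(0.01, 1, 50)) {
    od <- ode_steady_state(120, pan, ab, k_on = k_on)
    expect_equal(eq$complexes_nm, od$complexes_nm, tolerance = 1e-6)
  }
})

test_that("conservation holds on every solve and degenerate inputs are states", {
  for (i in 1:25) {
    pan <- random_panel(sample(1:12, 1), seed = 200 + i)
    ab <- random_abundances(pan, seed = 200 + i)
    r_tot <- runif(1, 0, 800)
    eq <- solve_equilibrium(r_tot, pan, ab)
    expect_lt(abs(eq$free_ras + eq$total_complexes - r_tot) / max(r_tot, 1),
              1e-9)
    expect_true(all(abs(eq$free_effectors + eq$complexes_nm - ab[pan$effector]) /
                      pmax(ab[pan$effector], 1) < 1e-9))
    expect_true(all(eq$complexes_nm >= 0) && eq$free_ras >= 0)
    if (eq$total_complexes > 0) {
      expect_equal(sum(eq$complexes_pct), 100, tolerance = 1e-9)
    }
  }
  # zero active Ras: all-zero state, not an error (warns on the undefined
  # percentages)
  pan <- toy_panel()
  expect_warning(eq0 <- solve_equilibrium(0, pan, toy_profile()$effectors),
                 "zero")
  expect_equal(eq0$total_complexes, 0)
  expect_equal(unname(eq0$free_effectors), unname(toy_profile()$effectors))
  # empty panel: all Ras free
  empty <- ras_panel(character(0), integer(0), numeric(0))
  eqe <- solve_equilibrium(100, empty, c(X = 1))
  expect_equal(eqe$free_ras, 100)
  expect_equal(eqe$total_complexes, 0)
  # zero-abundance effector retained with zero complex
  eq <- solve_equilibrium(100, pan, toy_profile()$effectors)
  expect_equal(eq$complexes_nm[["D"]], 0)
  expect_error(solve_equilibrium(NaN, pan, toy_profile()$effectors))
})

test_that("competition leaves a portion of every effector unbound", {
  for (i in 1:10) {
    pan <- random_panel(8, seed = 300 + i)
    ab <- random_abundances(pan, seed = 300 + i)
    r_tot <- 0.5 * sum(ab)  # sum effectors > active Ras
    eq <- solve_equilibrium(r_tot, pan, ab)
    expect_true(all(eq$free_effectors > 0))
  }
})

test_that("complexes are monotone in Kd and abundance, and saturate", {
  pan <- toy_panel()
  ab <- c(A = 200, B = 150, C = 80, D = 50)
  base <- solve_equilibrium(100, pan, ab)
  # raise Kd of A: its complex falls, every other complex rises
  harder <- panel_with_kd_test(pan, "A", 0.5)
  eq2 <- solve_equilibrium(100, harder, ab)
  expect_lt(eq2$complexes_nm[["A"]], base$complexes_nm[["A"]])
  expect_true(all(eq2$complexes_nm[c("B", "C", "D")] >
                    base$complexes_nm[c("B", "C", "D")]))
  # raise abundance of A: its complex rises
  ab2 <- ab; ab2[["A"]] <- 400
  eq3 <- solve_equilibrium(100, pan, ab2)
  expect_gt(eq3$complexes_nm[["A"]], base$complexes_nm[["A"]])
  # saturation: huge Ras binds nearly all of every effector, and the
  # dominant share falls while small shares rise
  eqs <- solve_equilibrium(1e7, pan, ab)
  expect_equal(unname(eqs$complexes_nm), unname(ab), tolerance = 1e-3)
  expect_lt(max(eqs$complexes_pct), max(base$complexes_pct))
  expect_gt(min(eqs$complexes_pct), min(base$complexes_pct))
})

test_that("percentages, class aggregation and ranking behave", {
  expect_equal(complex_percentages(c(A = 30, B = 70)), c(A = 30, B = 70))
  expect_equal(complex_percentages(c(A = 5)), c(A = 100))
  expect_warning(p0 <- complex_percentages(c(A = 0, B = 0)), "zero")
  expect_length(p0, 0)

  pan <- ras_panel(c("ARAF", "BRAF", "X"), c(1, 1, 3), c(0.07, 0.1, 1))
  expect_equal(aggregate_by_class(c(ARAF = 10, BRAF = 5), pan),
               c("1" = 15))
  expect_length(aggregate_by_class(stats::setNames(numeric(0), character(0)),
                                   pan), 0)
  expect_error(aggregate_by_class(c(ZZZ = 1), pan), "ZZZ")
  # class sums equal brute-force per-effector sums on a solved tissue
  cfg <- synthesis_config(seed = 11)
  panel <- generate_panel(cfg)
  prof <- generate_tissues(cfg, panel)[[3]]
  st <- solve_tissue(prof, panel)
  agg <- aggregate_by_class(st$complexes_pct, panel)
  brute <- vapply(sort(unique(panel$class_id)), function(cl) {
    sum(st$complexes_pct[panel$effector[panel$class_id == cl]])
  }, numeric(1))
  expect_equal(unname(agg), brute, tolerance = 1e-12)

  rk <- rank_entities(c(A = 50, B = 30, C = 20))
  expect_equal(rk$name, c("A", "B", "C"))
  expect_equal(rk$rank, 1:3)
  tie <- rank_entities(c(B = 40, A = 40))
  expect_equal(tie$name, c("A", "B"))  # ties broken by name
})

test_that("rank change agrees with exhaustive pairwise comparison", {
  set.seed(5)
  ref <- stats::setNames(runif(8), letters[1:8])
  new <- ref
  new[["c"]] <- new[["c"]]  # c unchanged, peers move
  new[["a"]] <- new[["a"]] / 10
  new[["h"]] <- new[["h"]] * 10
  rc <- rank_change(ref, new)
  brute_rank <- function(v, nm) {
    1 + sum(v > v[nm] | (v == v[nm] & names(v) < nm))
  }
  for (nm in names(ref)) {
    expect_equal(rc$change[rc$name == nm],
                 brute_rank(ref, nm) - brute_rank(new, nm))
  }
})

test_that("isoform split is proportional to active abundance", {
  prof <- toy_profile()  # H 100, K 300, N 100
  sp <- isoform_split(prof, gtp_scenario())
  expect_equal(unname(sp), c(0.2, 0.6, 0.2))
  only_k <- tissue_profile("k", c(A = 1), c(HRAS = 0, KRAS = 50, NRAS = 0))
  expect_equal(isoform_split(only_k)[["KRAS"]], 1.0)
  # pancreas-like equal thirds
  panc <- tissue_profile("pancreas", c(A = 1),
                         c(HRAS = 120, KRAS = 120, NRAS = 120))
  expect_equal(unname(isoform_split(panc)), rep(1 / 3, 3))
  zero <- tissue_profile("z", c(A = 1), c(HRAS = 0, KRAS = 0, NRAS = 0))
  expect_error(isoform_split(zero), "undefined")
})

test_that("competition check compares effector sum to the active pool", {
  prof <- toy_profile()  # sum eff 430, active 100 at 20 percent
  cc <- competition_check(prof)
  expect_true(cc$competition)
  expect_equal(cc$sum_effectors_nm, 430)
  expect_equal(cc$active_ras_nm, 100)
  cc2 <- competition_check(prof, gtp_scenario(1.5, 1.5, 1.5))
  expect_false(cc2$competition)
})
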