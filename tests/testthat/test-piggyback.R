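# Receptor-mediated recruitment: reductions, limits, ODE oracle, fold factors.

test_that("zero receptor abundance reduces to the base model", {
  pan <- toy_panel()
  ab <- c(A = 200, B = 150, C = 80, D = 50)
  stim <- stimulus_spec("S", c("EGFR", "ERBB2"), "B")
  pg <- solve_piggyback(100, pan, ab, c(EGFR = 0, ERBB2 = 0), list(stim))
  base <- solve_equilibrium(100, pan, ab)
  expect_equal(pg$complexes_nm, base$complexes_nm, tolerance = 1e-12)
  expect_equal(pg$free_ras, base$free_ras, tolerance = 1e-12)
  expect_true(all(pg$ye_complexes == 0) && all(pg$rye_complexes == 0))
})

test_that("alpha = 1 leaves total Ras-effector complexes at the base values", {
  # with no affinity enhancement the receptor shuttles effector without
  # changing its Ras binding: RE + RYE must equal the base RE exactly
  pan <- toy_panel()
  ab <- c(A = 200, B = 150, C = 80, D = 50)
  stim <- stimulus_spec("S", c("EGFR", "ERBB2"), c("B", "C"), alpha = 1)
  pg <- solve_piggyback(100, pan, ab, c(EGFR = 40, ERBB2 = 10), list(stim))
  base <- solve_equilibrium(100, pan, ab)
  expect_equal(pg$complexes_nm, base$complexes_nm, tolerance = 1e-9)
})

test_that("saturating receptor abundance approaches the kd/alpha base solve", {
  pan <- toy_panel()
  ab <- c(A = 200, B = 150, C = 80, D = 50)
  stim <- stimulus_spec("S", "EGFR", "C", receptor_effector_kd_um = 1,
                        alpha = 100)
  pg <- solve_piggyback(100, pan, ab, c(EGFR = 1e7), list(stim))
  pan_eff <- panel_with_kd_test(pan, "C", pan$kd_um[pan$effector == "C"] / 100)
  lim <- solve_equilibrium(100, pan_eff, ab)
  expect_equal(pg$complexes_nm[["C"]], lim$complexes_nm[["C"]],
               tolerance = 1e-3)
})

test_that("piggyback equilibrium matches ODE integration of the full network", {
  pan <- ras_panel(c("T1", "U1"), c(1, 2), c(2, 1))
  ab <- c(T1 = 150, U1 = 120)
  stim <- stimulus_spec("S", c("EGFR", "ERBB2"), "T1",
                        receptor_effector_kd_um = 1, alpha = 100)
  pg <- solve_piggyback(100, pan, ab, c(EGFR = 30, ERBB2 = 20), list(stim))
  od <- ode_steady_state(100, pan, ab, c(EGFR = 30, ERBB2 = 20), list(stim))
  expect_equal(pg$complexes_nm, od$complexes_nm, tolerance = 1e-6)
  expect_equal(unname(pg$free_receptors), unname(od$free_receptors),
               tolerance = 1e-6)
  expect_equal(pg$free_ras, od$free_ras, tolerance = 1e-6)
  expect_equal(unname(pg$ye_complexes["T1", ]), unname(od$ye_complexes["T1", ]),
               tolerance = 1e-6)
})

test_that("two simultaneous receptor species conserve all pools", {
  cfg <- synthesis_config(seed = 21)
  panel <- generate_panel(cfg)
  profs <- generate_tissues(cfg, panel)
  for (prof in profs[c(1, 7, 13)]) {
    st <- solve_tissue_stimulated(prof, panel,
                                  list(egf_stimulus(), pvrl3_stimulus()))
    r_tot <- active_ras_total(prof, gtp_uniform(0.9))$total
    expect_lt(abs(st$free_ras + st$total_complexes - r_tot) / r_tot, 1e-9)
    e_back <- st$free_effectors + st$complexes_nm + rowSums(st$ye_complexes)
    expect_lt(max(abs(e_back - prof$effectors[panel$effector]) /
                    pmax(prof$effectors[panel$effector], 1)), 1e-9)
    y_back <- st$free_receptors + colSums(st$ye_complexes) +
      colSums(st$rye_complexes)
    expect_lt(max(abs(y_back - st$receptor_totals) /
                    pmax(st$receptor_totals, 1)), 1e-9)
  }
})

test_that("thermodynamic cycle closes exactly at the solved state", {
  # K(Y+E)*K(R+YE) must equal K(R+E)*K(Y+RE); at equilibrium this shows as
  # RYE * E * Y * R ratios being consistent both ways round the cycle
  pan <- toy_panel()
  ab <- c(A = 200, B = 150, C = 80, D = 50)
  stim <- stimulus_spec("S", "EGFR", "B", receptor_effector_kd_um = 2,
                        alpha = 50)
  pg <- solve_piggyback(100, pan, ab, c(EGFR = 60), list(stim))
  r <- pg$free_ras
  y <- pg$free_receptors[["S"]]
  e <- pg$free_effectors[["B"]]
  kd_b <- pan$kd_um[pan$effector == "B"] * 1000
  # route 1: Y+E -> YE, R+YE -> RYE
  rye_1 <- r * (y * e / 2000) / (kd_b / 50)
  # route 2: R+E -> RE, Y+RE -> RYE
  rye_2 <- y * (r * e / kd_b) / (2000 / 50)
  expect_equal(rye_1, rye_2, tolerance = 1e-12)
  expect_equal(pg$rye_complexes["B", "S"], rye_1, tolerance = 1e-9)
})

test_that("fold factors exceed one and are largest for targeted classes", {
  cfg <- synthesis_config(seed = 31)
  panel <- generate_panel(cfg)
  profs <- generate_tissues(cfg, panel)
  for (prof in profs[c(4, 18)]) {
    unstim <- solve_tissue(prof, panel, gtp_scenario())
    stim <- solve_tissue_stimulated(prof, panel, egf_stimulus())
    ff <- fold_factor(stim, unstim, panel, by = "class")
    expect_true(all(ff$fold_factor > 1))
    targeted <- c(6, 12)  # SH2 classes hit by EGF
    expect_gt(min(ff$fold_factor[ff$class_id %in% targeted]),
              max(ff$fold_factor[!ff$class_id %in% targeted]))
  }
})

test_that("fold factor bookkeeping: identity, GTP-only monotonicity, guards", {
  pan <- toy_panel()
  ab <- c(A = 200, B = 150, C = 80, D = 50)
  st <- solve_equilibrium(100, pan, ab)
  ff_id <- fold_factor(st, st, pan, by = "effector")
  expect_true(all(ff_id$fold_factor == 1))
  # stimulation by GTP load alone (no recruitment) still raises every class
  hi <- solve_equilibrium(450, pan, ab)
  ff <- fold_factor(hi, st, pan, by = "class")
  expect_true(all(ff$fold_factor > 1))
  # unstim zero with stim positive is flagged unbounded
  st0 <- suppressWarnings(solve_equilibrium(0, pan, ab))
  ff0 <- fold_factor(hi, st0, pan, by = "effector")
  expect_true(all(ff0$unbounded))
  expect_true(all(is.infinite(ff0$fold_factor)))
})

test_that("stimulus validation catches unknown targets and receptors", {
  pan <- toy_panel()
  ab <- c(A = 1, B = 1, C = 1, D = 1)
  expect_error(solve_piggyback(10, pan, ab, c(EGFR = 1),
                               list(stimulus_spec("S", "EGFR", "ZZZ"))),
               "ZZZ")
  expect_error(solve_piggyback(10, pan, ab, c(OTHER = 1),
                               list(stimulus_spec("S", "EGFR", "A"))),
               "EGFR")
  expect_error(stimulus_spec("S", "EGFR", "A", alpha = 0.5), "alpha")
})
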