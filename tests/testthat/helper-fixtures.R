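# Shared fixtures for the suite: small random binding systems built in code.

# a random panel of n effectors with log-uniform Kd in [0.04, 39] uM
random_panel <- function(n, seed) {
  set.seed(seed)
  ras_panel(sprintf("E%02d", seq_len(n)),
            class_id = 1 + (seq_len(n) - 1) %% 12,
            kd_um = exp(runif(n, log(0.04), log(39))))
}

# random abundances (nM) for a panel, log-normal around 30 nM
random_abundances <- function(panel, seed, meanlog = log(30), sdlog = 1) {
  set.seed(seed + 1000)
  stats::setNames(rlnorm(nrow(panel), meanlog, sdlog), panel$effector)
}

# a small fixed tissue for deterministic single-tissue tests
toy_profile <- function(tissue = "toy") {
  tissue_profile(tissue,
                 effectors = c(A = 200, B = 150, C = 80, D = 0),
                 ras = c(HRAS = 100, KRAS = 300, NRAS = 100),
                 receptors = c(EGFR = 40, ERBB2 = 10, PVRL3 = 15))
}

# replace one effector's Kd (mirrors the internal perturbation helper)
panel_with_kd_test <- function(panel, eff, kd) {
  panel$kd_um[panel$effector == eff] <- kd
  panel
}

toy_panel <- function() {
  ras_panel(c("A", "B", "C", "D"), c(1, 2, 3, 4),
            c(0.05, 0.5, 7.5, 7.5), c("", "SH2", "PDZ", ""))
}
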