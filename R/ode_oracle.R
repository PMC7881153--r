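# Mass-action ODE route to the same steady state.
#
# Only the ratio k_off/k_on = Kd is observable at equilibrium, so a single
# shared association rate (k_on, per nM per time unit) is used for every
# binding edge and k_off = Kd(nM) * k_on.  Integrating the full reaction
# network to stationarity provides an independent numerical route to the
# equilibrium that never shares code with the root-finding solvers; it is
# used as a cross-check in the test-suite and is far too slow for the
# tissue-scale analyses.

#' Steady state by ODE integration of the mass-action network
#'
#' Integrates the full dynamic system of the competitive binding reactions
#' (and, when stimuli are given, the receptor recruitment reactions) until
#' all relative time derivatives fall below \code{tol}, doubling the
#' integration horizon as needed.
#'
#' @inheritParams solve_piggyback
#' @param k_on shared association rate, per nM per time unit.
#' @param horizon initial integration horizon (time units).
#' @param tol stationarity tolerance on max |dy/dt| / max(y, 1).
#' @param max_doublings horizon doublings before giving up.
#' @return list with \code{free_ras}, \code{free_effectors},
#'   \code{complexes_nm} (RE + RYE per effector), \code{total_complexes},
#'   and, with stimuli, \code{free_receptors}, \code{ye_complexes},
#'   \code{rye_complexes}.
#' @export
ode_steady_state <- function(active_ras, panel, abundances,
                             receptor_totals = numeric(0), stimuli = list(),
                             k_on = 1, horizon = 1e3, tol = 1e-10,
                             max_doublings = 20L) {
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  n <- nrow(panel)
  m <- length(stimuli)
  e_tot <- as.numeric(abundances[panel$effector])
  kd_nm <- panel$kd_um * 1000
  y_tot <- vapply(stimuli, function(s) sum(receptor_totals[s$receptors]),
                  numeric(1))
  k_ye <- vapply(stimuli, function(s) s$receptor_effector_kd_um * 1000,
                 numeric(1))
  alpha <- vapply(stimuli, `[[`, numeric(1), "alpha")
  targeted <- matrix(FALSE, n, m)
  for (s in seq_len(m)) targeted[panel$effector %in% stimuli[[s]]$targets, s] <- TRUE

  # state layout: R, E[1..n], RE[1..n], then per stimulus s: Y_s, YE[s, j
  # targeted], RYE[s, j targeted]
  tar_idx <- lapply(seq_len(m), function(s) which(targeted[, s]))
  y0 <- c(R = active_ras, E = e_tot, RE = rep(0, n))
  for (s in seq_len(m)) {
    nt <- length(tar_idx[[s]])
    y0 <- c(y0, y_tot[s], rep(0, nt), rep(0, nt))
  }

  deriv <- function(t, y, parms) {
    R <- y[1L]
    E <- y[2:(n + 1)]
    RE <- y[(n + 2):(2 * n + 1)]
    off <- 2 * n + 1
    dR <- -k_on * R * sum(E) + k_on * sum(kd_nm * RE)
    dE <- -k_on * R * E + k_on * kd_nm * RE
    dRE <- k_on * R * E - k_on * kd_nm * RE
    extra <- numeric(0)
    for (s in seq_len(m)) {
      jj <- tar_idx[[s]]
      nt <- length(jj)
      Ys <- y[off + 1L]
      YE <- y[(off + 2L):(off + 1L + nt)]
      RYE <- y[(off + 2L + nt):(off + 1L + 2L * nt)]
      off <- off + 1L + 2L * nt
      k_rye <- kd_nm[jj] / alpha[s]      # R + YE <-> RYE
      k_yre <- k_ye[s] / alpha[s]        # Y + RE <-> RYE (cycle closure)
      # Y + E <-> YE
      f1 <- k_on * Ys * E[jj] - k_on * k_ye[s] * YE
      # R + YE <-> RYE
      f2 <- k_on * R * YE - k_on * k_rye * RYE
      # Y + RE <-> RYE
      f3 <- k_on * Ys * RE[jj] - k_on * k_yre * RYE
      dYs <- -sum(f1) - sum(f3)
      dYE <- f1 - f2
      dRYE <- f2 + f3
      dE[jj] <- dE[jj] - f1
      dRE[jj] <- dRE[jj] - f3
      dR <- dR - sum(f2)
      extra <- c(extra, dYs, dYE, dRYE)
    }
    list(c(dR, dE, dRE, extra))
  }

  t_end <- horizon
  y <- y0
  for (d in seq_len(max_doublings)) {
    sol <- deSolve::lsoda(y, c(0, t_end), deriv, parms = NULL,
                          rtol = 1e-12, atol = 1e-12)
    y <- sol[nrow(sol), -1L]
    dy <- deriv(t_end, y, NULL)[[1]]
    if (max(abs(dy) / pmax(abs(y), 1)) < tol) break
    t_end <- t_end * 2
    if (d == max_doublings) {
      stop("ODE oracle did not reach steady state within the horizon cap")
    }
  }

  E <- y[2:(n + 1)]
  RE <- y[(n + 2):(2 * n + 1)]
  off <- 2 * n + 1
  ye <- rye <- matrix(0, n, m)
  free_receptors <- numeric(m)
  for (s in seq_len(m)) {
    jj <- tar_idx[[s]]
    nt <- length(jj)
    free_receptors[s] <- y[off + 1L]
    ye[jj, s] <- y[(off + 2L):(off + 1L + nt)]
    rye[jj, s] <- y[(off + 2L + nt):(off + 1L + 2L * nt)]
    off <- off + 1L + 2L * nt
  }
  complexes <- as.numeric(RE) + rowSums(rye)
  names(complexes) <- panel$effector
  out <- list(free_ras = as.numeric(y[1L]),
              free_effectors = stats::setNames(as.numeric(E), panel$effector),
              complexes_nm = complexes,
              total_complexes = sum(complexes))
  if (m) {
    dimnames(ye) <- dimnames(rye) <- list(panel$effector,
                                          vapply(stimuli, `[[`, "", "name"))
    out$free_receptors <- stats::setNames(free_receptors, colnames(ye))
    out$ye_complexes <- ye
    out$rye_complexes <- rye
  }
  out
}
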