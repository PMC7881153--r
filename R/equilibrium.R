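# Core competitive-binding equilibrium.
#
# All effectors bind active Ras through their RBD in a mutually exclusive
# way, R + E_i <-> RE_i with dissociation constant Kd_i.  At steady state
# RE_i = R * E_i / Kd_i and mass conservation for each effector gives
# RE_i = R * E_iT / (Kd_i + R).  Substituting into the Ras conservation
# equation leaves one scalar equation in the free active Ras R:
#
#   f(R) = R + sum_i R * E_iT / (Kd_i + R) - R_T = 0
#
# f is strictly increasing on [0, Inf) with f(0) = -R_T <= 0 and
# f(R_T) >= 0, so the root is unique and bracketed by [0, R_T].

# Scalar solve for free active Ras given per-effector totals and Kd (nM).
# Bracketed uniroot followed by a damped Newton polish to push the
# conservation residual to machine precision.
.solve_free_ras <- function(r_tot, kd_nm, e_tot, tol = 1e-12, maxit = 200L) {
  if (!all(is.finite(c(r_tot, kd_nm, e_tot)))) {
    stop("non-finite input to equilibrium solver")
  }
  if (r_tot < 0) stop("active Ras must be >= 0")
  if (any(kd_nm <= 0)) stop("all Kd must be > 0")
  if (any(e_tot < 0)) stop("effector totals must be >= 0")
  if (r_tot == 0 || length(e_tot) == 0L || sum(e_tot) == 0) {
    return(r_tot)
  }
  f <- function(r) r + sum(r * e_tot / (kd_nm + r)) - r_tot
  r <- stats::uniroot(f, lower = 0, upper = r_tot,
                      tol = max(tol * r_tot, .Machine$double.eps),
                      maxiter = maxit)$root
  # Newton polish: f'(r) = 1 + sum Kd_i E_iT / (Kd_i + r)^2 >= 1
  for (i in seq_len(60L)) {
    fr <- f(r)
    fp <- 1 + sum(e_tot * kd_nm / (kd_nm + r)^2)
    rn <- min(max(r - fr / fp, 0), r_tot)
    if (abs(rn - r) <= .Machine$double.eps * max(rn, 1)) {
      r <- rn
      break
    }
    r <- rn
  }
  resid <- abs(f(r)) / max(r_tot, 1)
  if (!is.finite(r) || resid > 1e-9) {
    stop(sprintf("equilibrium solver failed to converge (relative residual %.3e)",
                 resid))
  }
  r
}

#' Solve the competitive Ras-effector binding equilibrium
#'
#' Computes the unique mass-action steady state of a pool of active Ras
#' competing among a panel of effectors with mutually exclusive binding.
#' Internally everything is in nM; panel Kd values (micromolar) are
#' converted at the boundary.
#'
#' @param active_ras total active (GTP-bound) Ras, nM.
#' @param panel an effector panel (\code{\link{ras_panel}} or compatible
#'   data.frame with \code{effector} and \code{kd_um}).
#' @param abundances named numeric vector of total effector abundances (nM)
#'   covering every panel effector. Zero-abundance effectors are retained
#'   with zero complex.
#' @return list of class \code{ras_equilibrium} with elements
#'   \code{free_ras} (nM), \code{free_effectors} (named nM),
#'   \code{complexes_nm} (named nM), \code{complexes_pct} (named, share of
#'   total complexes in percent; empty when no complexes form),
#'   \code{total_complexes} (nM) and \code{active_ras}.
#' @examples
#' pan <- ras_panel(c("E1", "E2"), c(1, 2), c(0.05, 5))
#' eq <- solve_equilibrium(100, pan, c(E1 = 200, E2 = 200))
#' eq$complexes_nm
#' @export
solve_equilibrium <- function(active_ras, panel, abundances) {
  if (length(active_ras) != 1L || !is.finite(active_ras)) {
    stop("active_ras must be a single finite number (nM)")
  }
  missing_eff <- setdiff(panel$effector, names(abundances))
  if (length(missing_eff)) {
    stop("abundances missing for effector(s): ",
         paste(missing_eff, collapse = ", "))
  }
  e_tot <- as.numeric(abundances[panel$effector])
  kd_nm <- panel$kd_um * 1000
  r <- .solve_free_ras(active_ras, kd_nm, e_tot)
  complexes <- if (length(e_tot)) r * e_tot / (kd_nm + r) else numeric(0)
  names(complexes) <- panel$effector
  free_eff <- e_tot - complexes
  names(free_eff) <- panel$effector
  total <- sum(complexes)
  state <- structure(list(
    active_ras = active_ras,
    free_ras = r,
    free_effectors = free_eff,
    complexes_nm = complexes,
    complexes_pct = complex_percentages_vec(complexes),
    total_complexes = total
  ), class = "ras_equilibrium")
  check_conservation(state)
  state
}

# internal: percentages from a named nM vector
complex_percentages_vec <- function(complexes_nm) {
  total <- sum(complexes_nm)
  if (total <= 0) {
    if (length(complexes_nm)) {
      warning("total complexes is zero; percentages undefined")
    }
    return(stats::setNames(numeric(0), character(0)))
  }
  100 * complexes_nm / total
}

#' Normalize complexes to percentages of the total
#'
#' Ras-effector complex concentrations (nM) are normalized by the sum of
#' all complexes so tissues can be compared on relative pathway engagement.
#'
#' @param state a solved \code{ras_equilibrium} (or a named nM vector).
#' @return named numeric vector of percentages summing to 100 (empty, with
#'   a warning, when no complexes form).
#' @export
complex_percentages <- function(state) {
  if (inherits(state, "ras_equilibrium")) {
    return(complex_percentages_vec(state$complexes_nm))
  }
  complex_percentages_vec(state)
}

# internal: verify conservation invariants of a solved state
check_conservation <- function(state, rel_tol = 1e-9) {
  scale_r <- max(state$active_ras, 1)
  r_resid <- abs(state$free_ras + state$total_complexes - state$active_ras)
  if (r_resid / scale_r > rel_tol) {
    stop(sprintf("Ras conservation violated (relative residual %.3e)",
                 r_resid / scale_r))
  }
  if (any(state$free_ras < 0) || any(state$complexes_nm < -1e-12)) {
    stop("negative concentration in solved state")
  }
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ras_equilibrium <- function(x, ...) {
  cat("<ras_equilibrium>\n",
      sprintf(" active Ras %.4g nM | free %.4g nM | complexes %.4g nM (%d effectors)\n",
              x$active_ras, x$free_ras, x$total_complexes,
              length(x$complexes_nm)))
  if (length(x$complexes_pct)) {
    top <- sort(x$complexes_pct, decreasing = TRUE)
    top <- utils::head(top, 5)
    cat(" top shares:",
        paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Solve one tissue under a GTP scenario
#'
#' Convenience wrapper: computes the active Ras pool from the tissue profile
#' and scenario, solves the equilibrium over the panel, and attaches the
#' isoform attribution fractions.
#'
#' @inheritParams active_ras_total
#' @inheritParams solve_equilibrium
#' @return a \code{ras_equilibrium} with extra elements \code{tissue} and
#'   \code{isoform_fractions}.
#' @export
solve_tissue <- function(profile, panel, scenario = gtp_scenario()) {
  act <- active_ras_total(profile, scenario)
  state <- solve_equilibrium(act$total, panel, profile$effectors)
  state$tissue <- profile$tissue
  state$isoform_fractions <- if (act$total > 0) {
    act$by_isoform / act$total
  } else {
    stats::setNames(rep(NA_real_, 3), names(act$by_isoform))
  }
  state
}

#' Aggregate effector shares by pathway class
#'
#' @param pcts named numeric vector keyed by effector (percent or nM).
#' @param panel panel providing the effector to class map.
#' @return named numeric vector keyed by class id, summing to the same
#'   total as the input.
#' @export
aggregate_by_class <- function(pcts, panel) {
  if (!length(pcts)) return(stats::setNames(numeric(0), character(0)))
  unknown <- setdiff(names(pcts), panel$effector)
  if (length(unknown)) {
    stop("effector(s) without a class in the panel: ",
         paste(unknown, collapse = ", "))
  }
  cls <- panel$class_id[match(names(pcts), panel$effector)]
  out <- tapply(pcts, cls, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Rank entities by share
#'
#' Descending by value; ties are broken by name (ascending) so rankings are
#' reproducible.
#'
#' @param pcts named numeric vector (effector or class shares).
#' @return data.frame with columns \code{name}, \code{value}, \code{rank}.
#' @export
rank_entities <- function(pcts) {
  if (!length(pcts)) {
    return(data.frame(name = character(0), value = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  ord <- order(-pcts, names(pcts))
  data.frame(name = names(pcts)[ord], value = as.numeric(pcts)[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Rank change between a reference and a new scenario
#'
#' Positive values indicate up-ranking in the new scenario, negative values
#' down-ranking (rank change = reference rank - new rank).
#'
#' @param pcts_ref,pcts_new named share vectors over the same entities.
#' @return data.frame \code{name}, \code{rank_ref}, \code{rank_new},
#'   \code{change}.
#' @export
rank_change <- function(pcts_ref, pcts_new) {
  r1 <- rank_entities(pcts_ref)
  r2 <- rank_entities(pcts_new)
  if (!setequal(r1$name, r2$name)) {
    stop("rank_change requires the same entities in both scenarios")
  }
  m <- match(r1$name, r2$name)
  data.frame(name = r1$name, rank_ref = r1$rank, rank_new = r2$rank[m],
             change = r1$rank - r2$rank[m], stringsAsFactors = FALSE)
}

#' Single-ligand closed form
#'
#' For one effector the equilibrium complex has the familiar quadratic
#' closed form
#' \deqn{RE = ((R_T + E_T + K_d) - \sqrt{(R_T + E_T + K_d)^2 - 4 R_T E_T})/2.}
#' Used as an analytic cross-check of the numerical solver.
#'
#' @param r_tot,e_tot totals, nM.
#' @param kd_nm dissociation constant, nM.
#' @return complex concentration, nM.
#' @export
single_ligand_complex <- function(r_tot, e_tot, kd_nm) {
  s <- r_tot + e_tot + kd_nm
  (s - sqrt(s^2 - 4 * r_tot * e_tot)) / 2
}
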