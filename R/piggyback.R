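# Receptor-mediated ("piggyback") effector recruitment.
#
# A stimulated transmembrane receptor Y can bind selected effectors through
# a secondary domain (SH2, PDZ), concentrating them at the plasma membrane
# where Ras sits.  The reaction set per targeted effector j is
#
#   Y + E_j  <-> YE_j    (K_YE, the receptor-effector Kd)
#   R + YE_j <-> RYE_j   (K_RYE = Kd_j / alpha, the enhanced Ras binding)
#   Y + RE_j <-> RYE_j   (K = K_YE / alpha, implied by cycle closure)
#
# so the membrane-recruited effector binds Ras with its affinity raised by
# the enhancement factor alpha (~100).  The thermodynamic cycle
# K_YE * K_RYE = Kd_j * (K_YE / alpha) closes exactly by construction.
#
# At equilibrium, for free R and free Y fixed, each targeted effector's
# species are linear in its free concentration, so effector conservation
# gives a closed form for E_j and the Ras conservation equation keeps the
# one-scalar-unknown structure of the base model with an effective Kd:
#
#   RE_j + sum_s RYE_js = E_jT * R / (Kd_eff_j(Y) + R),
#   Kd_eff_j(Y) = (1 + sum_s Y_s/K_YE_s) /
#                 (1/Kd_j + sum_s Y_s/(K_YE_s * K_RYE_js))
#
# The solver therefore iterates: exact scalar solve of R given Y (monotone,
# bracketed), then a damped closed-form update of each free receptor from
# its own conservation equation, until the free-species vector is fixed.

#' Specify a membrane-recruitment stimulus
#'
#' @param name stimulus label (e.g. \code{"EGF"}).
#' @param receptors character vector of receptor names whose abundances are
#'   summed into one receptor species (e.g. EGFR + ErbB2 for EGF).
#' @param targets effectors recruited by this receptor (via SH2/PDZ).
#' @param receptor_effector_kd_um receptor-effector dissociation constant,
#'   micromolar (default 1).
#' @param alpha enhancement factor of the Ras-effector affinity upon
#'   membrane recruitment (default 100; must be >= 1).
#' @param gtp GTP load used in the stimulated condition (default 0.90).
#' @return list of class \code{stimulus_spec}.
#' @export
stimulus_spec <- function(name, receptors, targets,
                          receptor_effector_kd_um = 1, alpha = 100,
                          gtp = 0.9) {
  if (receptor_effector_kd_um <= 0) stop("receptor-effector Kd must be > 0")
  if (alpha < 1) stop("enhancement factor alpha must be >= 1")
  structure(list(name = name, receptors = as.character(receptors),
                 targets = as.character(targets),
                 receptor_effector_kd_um = receptor_effector_kd_um,
                 alpha = alpha, gtp = gtp),
            class = "stimulus_spec")
}

#' Built-in stimulus specifications
#'
#' \code{egf_stimulus()} models EGF acting through EGFR+ErbB2 on the SH2
#' effectors RIN1, RIN2, RIN3, GRB7, GRB10, GRB14 (classes 6 and 12).
#' \code{pvrl3_stimulus()} models nectin-3 (PVRL3) acting through its
#' receptor on the PDZ effectors MLLT4, SNX27, TIAM1, TIAM2, RAPGEF2,
#' RAPGEF6, RADIL, RGS12.
#'
#' @inheritParams stimulus_spec
#' @export
egf_stimulus <- function(receptor_effector_kd_um = 1, alpha = 100,
                         gtp = 0.9) {
  stimulus_spec("EGF", c("EGFR", "ERBB2"),
                c("RIN1", "RIN2", "RIN3", "GRB7", "GRB10", "GRB14"),
                receptor_effector_kd_um, alpha, gtp)
}

#' @rdname egf_stimulus
#' @export
pvrl3_stimulus <- function(receptor_effector_kd_um = 1, alpha = 100,
                           gtp = 0.9) {
  stimulus_spec("PVRL3", "PVRL3",
                c("MLLT4", "SNX27", "TIAM1", "TIAM2", "RAPGEF2", "RAPGEF6",
                  "RADIL", "RGS12"),
                receptor_effector_kd_um, alpha, gtp)
}

#' Solve the equilibrium with receptor-mediated recruitment
#'
#' Extends \code{\link{solve_equilibrium}} with one receptor species per
#' stimulus. Untargeted effectors behave exactly as in the base model;
#' targeted effectors additionally form receptor-effector (YE) and ternary
#' receptor-effector-Ras (RYE) complexes. RYE counts toward Ras-effector
#' complex output.
#'
#' @inheritParams solve_equilibrium
#' @param receptor_totals named numeric vector of receptor abundances (nM);
#'   every receptor named in a stimulus must be present (zero allowed).
#' @param stimuli list of \code{\link{stimulus_spec}}s.
#' @param damping damping of the receptor update (0 < damping <= 1).
#' @param tol relative convergence tolerance on the free-species vector.
#' @param maxit iteration cap.
#' @return list of class \code{ras_piggyback} (also \code{ras_equilibrium})
#'   with the base fields plus \code{free_receptors}, \code{ye_complexes}
#'   and \code{rye_complexes} (matrices effector x stimulus, nM),
#'   \code{re_complexes} (direct RBD complexes only; \code{complexes_nm} is
#'   RE + RYE).
#' @export
solve_piggyback <- function(active_ras, panel, abundances, receptor_totals,
                            stimuli, damping = 0.5, tol = 1e-12,
                            maxit = 1e5) {
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (!length(stimuli)) {
    return(solve_equilibrium(active_ras, panel, abundances))
  }
  for (s in stimuli) {
    bad <- setdiff(s$targets, panel$effector)
    if (length(bad)) {
      stop("stimulus ", s$name, " targets unknown effector(s): ",
           paste(bad, collapse = ", "))
    }
    bad <- setdiff(s$receptors, names(receptor_totals))
    if (length(bad)) {
      stop("stimulus ", s$name, " needs receptor abundance(s): ",
           paste(bad, collapse = ", "))
    }
  }
  n <- nrow(panel)
  m <- length(stimuli)
  e_tot <- as.numeric(abundances[panel$effector])
  if (any(is.na(e_tot))) {
    stop("abundances missing for effector(s): ",
         paste(panel$effector[is.na(e_tot)], collapse = ", "))
  }
  kd_nm <- panel$kd_um * 1000
  y_tot <- vapply(stimuli, function(s) sum(receptor_totals[s$receptors]),
                  numeric(1))
  k_ye <- vapply(stimuli, function(s) s$receptor_effector_kd_um * 1000,
                 numeric(1))
  # K_RYE per effector x stimulus (NA where untargeted)
  targeted <- matrix(FALSE, n, m)
  k_rye <- matrix(NA_real_, n, m)
  for (s in seq_len(m)) {
    idx <- panel$effector %in% stimuli[[s]]$targets
    targeted[idx, s] <- TRUE
    k_rye[idx, s] <- kd_nm[idx] / stimuli[[s]]$alpha
  }

  # terms per effector given free receptor vector y:
  #   q_i = sum_s targeted * y_s / K_YE_s
  #   u_i = 1/Kd_i + sum_s targeted * y_s / (K_YE_s * K_RYE_is)
  eff_terms <- function(y) {
    q <- rep(0, n)
    u <- 1 / kd_nm
    for (s in seq_len(m)) {
      if (y[s] <= 0) next
      q <- q + ifelse(targeted[, s], y[s] / k_ye[s], 0)
      u <- u + ifelse(targeted[, s], y[s] / (k_ye[s] * k_rye[, s]), 0)
    }
    list(q = q, u = u, kd_eff = (1 + q) / u)
  }

  y <- y_tot  # start from all receptor free
  r <- NA_real_
  converged <- FALSE
  for (it in seq_len(maxit)) {
    tm <- eff_terms(y)
    r <- .solve_free_ras(active_ras, tm$kd_eff, e_tot)
    # free effector from its own conservation, then receptor conservation
    e_free <- e_tot / (1 + tm$q + tm$u * r)
    y_new <- y
    for (s in seq_len(m)) {
      occ <- sum(ifelse(targeted[, s],
                        e_free / k_ye[s] * (1 + r / k_rye[, s]), 0),
                 na.rm = TRUE)
      y_new[s] <- y_tot[s] / (1 + occ)
    }
    y_next <- y + damping * (y_new - y)
    delta <- max(abs(y_next - y) / pmax(y_tot, 1e-12))
    y <- y_next
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && m > 0 && any(y_tot > 0)) {
    stop(sprintf("piggyback solver did not converge within %d iterations", maxit))
  }
  # final consistent assembly at (r, y)
  tm <- eff_terms(y)
  r <- .solve_free_ras(active_ras, tm$kd_eff, e_tot)
  e_free <- e_tot / (1 + tm$q + tm$u * r)
  re <- r * e_free / kd_nm
  ye <- rye <- matrix(0, n, m,
                      dimnames = list(panel$effector,
                                      vapply(stimuli, `[[`, "", "name")))
  for (s in seq_len(m)) {
    idx <- targeted[, s]
    ye[idx, s] <- y[s] * e_free[idx] / k_ye[s]
    rye[idx, s] <- r * y[s] * e_free[idx] / (k_ye[s] * k_rye[idx, s])
  }
  complexes <- re + rowSums(rye)
  names(complexes) <- panel$effector
  names(re) <- panel$effector
  free_eff <- e_tot - complexes - rowSums(ye)
  names(free_eff) <- panel$effector
  state <- structure(list(
    active_ras = active_ras,
    free_ras = r,
    free_effectors = free_eff,
    complexes_nm = complexes,
    complexes_pct = complex_percentages_vec(complexes),
    total_complexes = sum(complexes),
    re_complexes = re,
    ye_complexes = ye,
    rye_complexes = rye,
    free_receptors = stats::setNames(y, colnames(ye)),
    receptor_totals = stats::setNames(y_tot, colnames(ye))
  ), class = c("ras_piggyback", "ras_equilibrium"))
  check_piggyback_conservation(state, e_tot)
  state
}

# internal: Ras / receptor / effector conservation for piggyback states
check_piggyback_conservation <- function(state, e_tot, rel_tol = 1e-9) {
  r_resid <- abs(state$free_ras + state$total_complexes - state$active_ras) /
    max(state$active_ras, 1)
  if (r_resid > rel_tol) {
    stop(sprintf("Ras conservation violated (relative residual %.3e)", r_resid))
  }
  e_back <- state$free_effectors + state$complexes_nm +
    rowSums(state$ye_complexes)
  e_resid <- max(abs(e_back - e_tot) / pmax(e_tot, 1))
  if (e_resid > rel_tol) {
    stop(sprintf("effector conservation violated (relative residual %.3e)",
                 e_resid))
  }
  y_back <- state$free_receptors + colSums(state$ye_complexes) +
    colSums(state$rye_complexes)
  y_resid <- max(abs(y_back - state$receptor_totals) /
                   pmax(state$receptor_totals, 1))
  if (y_resid > rel_tol) {
    stop(sprintf("receptor conservation violated (relative residual %.3e)",
                 y_resid))
  }
  invisible(state)
}

#' Solve one tissue under stimulation
#'
#' Applies the stimulated GTP load of the stimuli (which must agree) and
#' the receptor recruitment reactions to a tissue profile.
#'
#' @inheritParams solve_tissue
#' @param stimuli list of \code{\link{stimulus_spec}}s (or one spec).
#' @param scenario optional; defaults to a uniform load at the stimuli's
#'   \code{gtp} fraction.
#' @return a \code{ras_piggyback} state with \code{tissue} attached.
#' @export
solve_tissue_stimulated <- function(profile, panel, stimuli,
                                    scenario = NULL) {
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (is.null(scenario)) {
    gtps <- unique(vapply(stimuli, `[[`, numeric(1), "gtp"))
    if (length(gtps) != 1L) {
      stop("stimuli disagree on GTP load; pass an explicit scenario")
    }
    scenario <- gtp_uniform(gtps)
  }
  act <- active_ras_total(profile, scenario)
  state <- solve_piggyback(act$total, panel, profile$effectors,
                           profile$receptors, stimuli)
  state$tissue <- profile$tissue
  state$isoform_fractions <- if (act$total > 0) act$by_isoform / act$total
                             else stats::setNames(rep(NA_real_, 3),
                                                  names(act$by_isoform))
  state
}

#' Stimulated / unstimulated fold factors
#'
#' The fold factor of an effector (or class) is the ratio of its
#' Ras-effector complex concentration (nM, including receptor-mediated RYE
#' complexes) in the stimulated system over the unstimulated reference
#' (20 percent GTP, no recruitment). Class ratios are ratios of class sums.
#'
#' @param stim_state,unstim_state solved states over the same panel.
#' @param panel the effector panel (needed for \code{by = "class"}).
#' @param by \code{"class"} or \code{"effector"}.
#' @return data.frame with the grouping column, \code{stim_nm},
#'   \code{unstim_nm}, \code{fold_factor} and \code{unbounded} (TRUE where
#'   the unstimulated complex is 0 and the stimulated one positive).
#' @export
fold_factor <- function(stim_state, unstim_state, panel,
                        by = c("class", "effector")) {
  by <- match.arg(by)
  a <- stim_state$complexes_nm
  b <- unstim_state$complexes_nm
  if (!setequal(names(a), names(b))) {
    stop("states cover different effector panels")
  }
  b <- b[names(a)]
  if (by == "class") {
    a <- aggregate_by_class(a, panel)
    b <- aggregate_by_class(b, panel)
    key <- data.frame(class_id = as.integer(names(a)))
  } else {
    key <- data.frame(effector = names(a), stringsAsFactors = FALSE)
  }
  ratio <- ifelse(b > 0, a / b, ifelse(a > 0, Inf, NA_real_))
  cbind(key, data.frame(stim_nm = as.numeric(a), unstim_nm = as.numeric(b),
                        fold_factor = as.numeric(ratio),
                        unbounded = b <= 0 & a > 0))
}
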