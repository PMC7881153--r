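#' Tissue abundance profile
#'
#' One tissue's protein abundances: effector totals, Ras isoform totals and
#' receptor totals, all in nM.
#'
#' @param tissue tissue name.
#' @param effectors named numeric vector of total effector abundances (nM).
#' @param ras named numeric vector of Ras isoform totals (nM), names among
#'   \code{HRAS}, \code{KRAS}, \code{NRAS}.
#' @param receptors named numeric vector of receptor totals (nM); may be
#'   empty.
#' @return list of class \code{tissue_profile}.
#' @export
tissue_profile <- function(tissue, effectors, ras,
                           receptors = numeric(0)) {
  for (v in list(effectors, ras, receptors)) {
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v))))) {
      stop("all abundance vectors must be fully named")
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("abundances must be finite and >= 0 (nM), in tissue ", tissue)
    }
  }
  bad <- setdiff(names(ras), c("HRAS", "KRAS", "NRAS"))
  if (length(bad)) stop("unknown Ras isoform(s): ", paste(bad, collapse = ", "))
  structure(list(tissue = as.character(tissue),
                 effectors = effectors, ras = ras, receptors = receptors),
            class = "tissue_profile")
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat("<tissue_profile>", x$tissue, "\n",
      " effectors:", length(x$effectors),
      sprintf("(sum %.1f nM)", sum(x$effectors)), "\n",
      " Ras totals (nM):",
      paste(sprintf("%s=%.1f", names(x$ras), x$ras), collapse = " "), "\n",
      " receptors:", length(x$receptors), "\n")
  invisible(x)
}

#' GTP-load scenario
#'
#' The fraction of each Ras isoform's total abundance that is in the active,
#' effector-binding GTP state. The wild-type baseline is 0.20 for all three
#' isoforms; stimulated or oncogenic scenarios raise individual isoforms
#' (mutant copy-number scenarios may exceed 1).
#'
#' @param hras,kras,nras active fractions (>= 0).
#' @return named numeric vector of class \code{gtp_scenario}.
#' @examples
#' gtp_scenario()                 # wild type, 20 percent everywhere
#' gtp_scenario(kras = 1.0)       # KRAS mutant at 100 percent
#' @export
gtp_scenario <- function(hras = 0.2, kras = 0.2, nras = 0.2) {
  x <- c(HRAS = unname(hras), KRAS = unname(kras), NRAS = unname(nras))
  if (any(!is.finite(x)) || any(x < 0)) stop("GTP fractions must be >= 0")
  structure(x, class = c("gtp_scenario", "numeric"))
}

#' Uniform GTP-load scenario
#'
#' @param fraction common active fraction for all three isoforms.
#' @export
gtp_uniform <- function(fraction) {
  gtp_scenario(fraction, fraction, fraction)
}

#' Total active (GTP-bound) Ras in a tissue
#'
#' Sums, over isoforms, the active fraction times that isoform's total
#' abundance. Also returns the per-isoform active amounts used for isoform
#' attribution of complexes.
#'
#' @param profile a \code{\link{tissue_profile}}.
#' @param scenario a \code{\link{gtp_scenario}}.
#' @return list with \code{total} (nM) and \code{by_isoform} (named nM).
#' @export
active_ras_total <- function(profile, scenario = gtp_scenario()) {
  iso <- names(scenario)
  missing_iso <- setdiff(iso, names(profile$ras))
  if (length(missing_iso)) {
    stop("tissue ", profile$tissue, " has no abundance for isoform(s): ",
         paste(missing_iso, collapse = ", "))
  }
  by_iso <- as.numeric(scenario) * profile$ras[iso]
  names(by_iso) <- iso
  list(total = sum(by_iso), by_isoform = by_iso)
}

#' Attribute complexes to Ras isoforms by active abundance
#'
#' Because the model uses one shared Kd per effector across the three
#' isoforms, the pooled active-Ras species partitions each complex among
#' HRAS/KRAS/NRAS simply in proportion to their active amounts.
#'
#' @inheritParams active_ras_total
#' @return named numeric vector of fractions summing to 1.
#' @export
isoform_split <- function(profile, scenario = gtp_scenario()) {
  act <- active_ras_total(profile, scenario)
  if (act$total <= 0) {
    stop("no active Ras in tissue ", profile$tissue,
         "; isoform split undefined")
  }
  act$by_isoform / act$total
}

#' Competition-regime check
#'
#' The competitive-binding regime holds when the summed effector abundance
#' exceeds the total active Ras, so that effectors must compete for a
#' limiting hub and a portion of every effector stays unbound.
#'
#' @inheritParams active_ras_total
#' @param panel optional panel; when given, only panel effectors are summed.
#' @return list with \code{competition} (logical), \code{sum_effectors_nm},
#'   \code{active_ras_nm} and \code{margin_nm} (sum - active).
#' @export
competition_check <- function(profile, scenario = gtp_scenario(),
                              panel = NULL) {
  eff <- profile$effectors
  if (!is.null(panel)) eff <- eff[intersect(names(eff), panel$effector)]
  se <- sum(eff)
  act <- active_ras_total(profile, scenario)$total
  list(competition = se > act, sum_effectors_nm = se,
       active_ras_nm = act, margin_nm = se - act)
}
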