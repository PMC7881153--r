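# Mutant-scenario rewiring scores and the Gaussian "sweet spot" fit.

#' Network rewiring score of a Ras mutant scenario
#'
#' The rewiring score of a tissue under an oncogenic mutation of one Ras
#' isoform is the ratio of the summed Ras-effector complexes in the mutant
#' scenario (mutated isoform active at \code{mutant_level} of its total
#' abundance, the other two isoforms at the wild-type 20 percent load) over
#' the wild-type scenario (all isoforms at 20 percent).  RS = 1 means no
#' rewiring; levels above 1 model copy-number gains. Effector abundances
#' are held at their reference values across scenarios.
#'
#' @inheritParams solve_tissue
#' @param isoform one of \code{"HRAS"}, \code{"KRAS"}, \code{"NRAS"}.
#' @param mutant_level active fraction of the mutated isoform (e.g. 1.0 for
#'   a fully GTP-loaded mutant; 0.5-1.5 for allele/copy-number scenarios).
#' @param base_gtp wild-type active fraction (default 0.2).
#' @return one-row data.frame \code{tissue}, \code{isoform},
#'   \code{mutant_level}, \code{rs}.
#' @export
rewiring_score <- function(profile, panel, isoform, mutant_level = 1.0,
                           base_gtp = 0.2) {
  isoform <- match.arg(isoform, c("HRAS", "KRAS", "NRAS"))
  if (!is.finite(mutant_level) || mutant_level <= 0) {
    stop("mutant_level must be > 0")
  }
  wt <- solve_tissue(profile, panel, gtp_uniform(base_gtp))
  if (wt$total_complexes <= 0) {
    stop("wild-type scenario forms no complexes in tissue ", profile$tissue,
         "; rewiring score undefined")
  }
  fracs <- stats::setNames(rep(base_gtp, 3), c("HRAS", "KRAS", "NRAS"))
  fracs[isoform] <- mutant_level
  mut <- solve_tissue(profile, panel,
                      gtp_scenario(fracs["HRAS"], fracs["KRAS"], fracs["NRAS"]))
  data.frame(tissue = profile$tissue, isoform = isoform,
             mutant_level = mutant_level,
             rs = mut$total_complexes / wt$total_complexes,
             stringsAsFactors = FALSE)
}

#' Rewiring scores over tissues, isoforms and mutant levels
#'
#' @param profiles list of \code{\link{tissue_profile}}s.
#' @inheritParams rewiring_score
#' @param isoforms isoforms to mutate.
#' @param levels mutant levels.
#' @return data.frame stacking \code{\link{rewiring_score}} rows.
#' @export
rewiring_scores <- function(profiles, panel,
                            isoforms = c("HRAS", "KRAS", "NRAS"),
                            levels = 1.0, base_gtp = 0.2) {
  rows <- list()
  for (p in profiles) {
    for (iso in isoforms) {
      for (lv in levels) {
        rows[[length(rows) + 1L]] <-
          rewiring_score(p, panel, iso, lv, base_gtp)
      }
    }
  }
  do.call(rbind, rows)
}

#' Tissues rarely associated with cancer
#'
#' The nine tissues excluded from the sweet-spot Gaussian fits because they
#' rarely give rise to tumors.
#'
#' @return character vector.
#' @export
rarely_cancer_tissues <- function() {
  c("appendix", "fat", "heart", "fallopian tube", "placenta",
    "smooth muscle", "small intestine", "spleen", "tonsil")
}

#' Gaussian sweet-spot fit of mutation frequency vs rewiring score
#'
#' Fits \eqn{freq = A \exp(-(rs - \mu)^2 / (2\sigma^2))} by unweighted
#' least squares (Levenberg-Marquardt), with the deterministic start
#' \eqn{\mu_0} = frequency-weighted mean of rs, \eqn{\sigma_0} = weighted
#' sd, \eqn{A_0} = max frequency. The "sweet spot" reading: intermediate
#' network rewiring carries the highest cancer mutation frequency, while
#' weak and very strong rewiring are rarely selected.
#'
#' @param rs numeric vector of rewiring scores (>= 4 points, not all equal).
#' @param freq mutation frequencies (percent), same length.
#' @param excluded_tissues optional character vector recorded on the fit
#'   (points already removed by the caller).
#' @return list of class \code{gaussian_fit}: \code{amplitude}, \code{mean},
#'   \code{sd}, \code{residual_norm}, \code{n}, \code{excluded_tissues},
#'   \code{fitted}.
#' @export
fit_sweet_spot <- function(rs, freq, excluded_tissues = character(0)) {
  if (length(rs) != length(freq)) stop("rs and freq lengths differ")
  keep <- is.finite(rs) & is.finite(freq)
  rs <- rs[keep]
  freq <- freq[keep]
  if (length(rs) < 4L) stop("need at least 4 points for a 3-parameter fit")
  if (diff(range(rs)) == 0) stop("degenerate input: all rewiring scores equal")
  w <- pmax(freq, 0)
  if (sum(w) == 0) w <- rep(1, length(rs))
  mu0 <- sum(w * rs) / sum(w)
  s0 <- sqrt(sum(w * (rs - mu0)^2) / sum(w))
  s0 <- max(s0, 0.05 * diff(range(rs)))
  a0 <- max(freq, 1e-6)
  df <- data.frame(rs = rs, freq = freq)
  fit <- minpack.lm::nlsLM(
    freq ~ A * exp(-(rs - mu)^2 / (2 * sigma^2)),
    data = df,
    start = list(A = a0, mu = mu0, sigma = s0),
    lower = c(0, -Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15, gtol = 1e-15)
  )
  cf <- stats::coef(fit)
  fitted_vals <- cf[["A"]] * exp(-(rs - cf[["mu"]])^2 / (2 * cf[["sigma"]]^2))
  structure(list(amplitude = unname(cf[["A"]]), mean = unname(cf[["mu"]]),
                 sd = abs(unname(cf[["sigma"]])),
                 residual_norm = sqrt(sum((freq - fitted_vals)^2)),
                 n = length(rs), excluded_tissues = excluded_tissues,
                 fitted = fitted_vals),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> A = %.4g, mean = %.4g, sd = %.4g (n = %d, resid = %.3g)\n",
              x$amplitude, x$mean, x$sd, x$n, x$residual_norm))
  if (length(x$excluded_tissues)) {
    cat(" excluded:", paste(x$excluded_tissues, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sweet-spot fit from score and frequency tables
#'
#' Joins per-(tissue, isoform) rewiring scores with a mutation-frequency
#' table, drops the excluded tissues, and fits either one isoform or the
#' pooled PanRas point set (all isoform-specific points together).
#'
#' @param scores data.frame \code{tissue}, \code{isoform}, \code{rs} (one
#'   mutant level).
#' @param freqs data.frame \code{tissue}, \code{isoform},
#'   \code{frequency_percent}.
#' @param isoform \code{"PanRas"} (pool all isoforms) or one isoform name.
#' @param exclude tissues to exclude (default the rarely-cancer set).
#' @return a \code{\link{fit_sweet_spot}} result.
#' @export
sweet_spot_fit <- function(scores, freqs, isoform = "PanRas",
                           exclude = rarely_cancer_tissues()) {
  merged <- merge(scores, freqs, by = c("tissue", "isoform"))
  if (isoform != "PanRas") {
    merged <- merged[merged$isoform == isoform, , drop = FALSE]
  }
  kept <- merged[!merged$tissue %in% exclude, , drop = FALSE]
  fit_sweet_spot(kept$rs, kept$frequency_percent,
                 excluded_tissues = intersect(unique(merged$tissue), exclude))
}
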