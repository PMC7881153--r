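# Affinity/abundance determinants of complex formation: shared-Kd linear
# fits, slope summaries, interpolated surfaces, and key-effector sets.
#
# At a solved equilibrium every effector with the same Kd lies exactly on a
# line through the origin in the (abundance, share) plane:
#   C%_i = 100 * R* * E_iT / ((Kd + R*) * C_tot)
# so the fitted slope must equal 100 * R* / ((Kd + R*) * C_tot) - the
# module's primary analytic oracle.

#' Group panel effectors by identical Kd
#'
#' @param panel an effector panel.
#' @return data.frame \code{kd_um}, \code{n}, \code{singleton},
#'   \code{effectors} (semicolon-joined names), ordered by Kd.
#' @export
group_by_kd <- function(panel) {
  sp <- split(panel$effector, panel$kd_um)
  kd <- as.numeric(names(sp))
  ord <- order(kd)
  data.frame(kd_um = kd[ord],
             n = lengths(sp)[ord],
             singleton = lengths(sp)[ord] == 1L,
             effectors = vapply(sp[ord], paste, "", collapse = ";"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Linear abundance-vs-share fits per Kd group
#'
#' For every set of effectors sharing a Kd, fits the line of complex share
#' (percent) against total effector abundance (nM): ordinary least squares
#' for multi-effector groups, and for singletons the line through the
#' origin and the single point (skipped when the share is below
#' \code{min_pct}, by default 0.001 percent, where a line is meaningless).
#'
#' @param state a solved \code{ras_equilibrium} for one tissue.
#' @param panel the panel the state was solved over.
#' @param abundances named abundance vector used for the solve (nM).
#' @param min_pct singleton shares below this are skipped.
#' @return data.frame of class rows: \code{tissue}, \code{kd_um},
#'   \code{slope} (percent per nM), \code{intercept}, \code{n_points},
#'   \code{through_origin}.
#' @export
fit_abundance_complex_lines <- function(state, panel, abundances,
                                        min_pct = 0.001) {
  pct <- stats::setNames(rep(0, nrow(panel)), panel$effector)
  if (length(state$complexes_pct)) {
    pct[names(state$complexes_pct)] <- state$complexes_pct
  }
  e_tot <- as.numeric(abundances[panel$effector])
  groups <- split(seq_len(nrow(panel)), panel$kd_um)
  rows <- list()
  for (kd_chr in names(groups)) {
    idx <- groups[[kd_chr]]
    kd <- as.numeric(kd_chr)
    x <- e_tot[idx]
    y <- as.numeric(pct[panel$effector[idx]])
    if (length(idx) == 1L) {
      if (y < min_pct || x <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = state$tissue %||% NA_character_, kd_um = kd,
        slope = y / x, intercept = 0, n_points = 1L, through_origin = TRUE,
        stringsAsFactors = FALSE)
    } else {
      if (length(unique(x)) < 2L) next  # no spread to fit a line on
      fit <- stats::lm(y ~ x)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = state$tissue %||% NA_character_, kd_um = kd,
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        n_points = length(idx), through_origin = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(tissue = character(0), kd_um = numeric(0),
                      slope = numeric(0), intercept = numeric(0),
                      n_points = integer(0), through_origin = logical(0)))
  }
  do.call(rbind, rows)
}

#' Analytic slope of the shared-Kd line
#'
#' @param free_ras free active Ras at the solved equilibrium, nM.
#' @param kd_um the group's dissociation constant, micromolar.
#' @param total_complexes total complexes at the equilibrium, nM.
#' @return slope in percent per nM.
#' @export
analytic_slope <- function(free_ras, kd_um, total_complexes) {
  100 * free_ras / ((kd_um * 1000 + free_ras) * total_complexes)
}

#' Per-tissue slope summary over the affinity range
#'
#' Averages each tissue's fitted slopes over Kd in [0.04, 50] micromolar
#' and sorts tissues by increasing average slope (least to most sensitive
#' to affinity variation); also reports averages within the standard
#' reporting bins [0.04, 0.09], [0.21, 1] and [2.9, 50] micromolar.
#'
#' @param fits stacked \code{\link{fit_abundance_complex_lines}} output
#'   over one or more tissues.
#' @param kd_range affinity range for the overall average, micromolar.
#' @param bins named list of c(lo, hi) reporting bins.
#' @return data.frame, one row per tissue, sorted ascending by
#'   \code{avg_slope}, with one extra column per bin.
#' @export
slope_summary <- function(fits, kd_range = c(0.04, 50),
                          bins = list(kd_0.04_0.09 = c(0.04, 0.09),
                                      kd_0.21_1 = c(0.21, 1),
                                      kd_2.9_50 = c(2.9, 50))) {
  if (!nrow(fits)) stop("no slope fits to summarize")
  in_range <- function(kd, r) kd >= r[1] & kd <= r[2]
  per_tissue <- split(fits, fits$tissue)
  rows <- lapply(per_tissue, function(df) {
    sel <- in_range(df$kd_um, kd_range)
    out <- data.frame(tissue = df$tissue[1],
                      avg_slope = mean(df$slope[sel]),
                      n_fits = sum(sel), stringsAsFactors = FALSE)
    for (b in names(bins)) {
      s <- in_range(df$kd_um, bins[[b]])
      out[[b]] <- if (any(s)) mean(df$slope[s]) else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$avg_slope), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpolated affinity x abundance x share surface
#'
#' Evaluates the per-Kd fitted lines on an abundance grid, yielding the
#' gridded (Kd, abundance, share) table from which the landscape surface
#' and its 2D projections are drawn. The surface is a piecewise-linear
#' interpolation artifact of the fits, not a model object.
#'
#' @param fits one tissue's \code{\link{fit_abundance_complex_lines}} rows.
#' @param abundance_grid abundance evaluation points, nM.
#' @return data.frame \code{kd_um}, \code{abundance_nm},
#'   \code{complex_pct} (clamped at 0).
#' @export
surface_grid <- function(fits, abundance_grid = seq(0, 500, by = 10)) {
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    data.frame(kd_um = fits$kd_um[i], abundance_nm = abundance_grid,
               complex_pct = pmax(0, fits$intercept[i] +
                                    fits$slope[i] * abundance_grid))
  })
  do.call(rbind, rows)
}

#' Key effectors of the binding landscape
#'
#' The effectors holding at least \code{threshold} percent of all
#' Ras-effector complexes in one or more tissues (inclusive threshold).
#'
#' @param results long results table with columns \code{tissue},
#'   \code{effector}, \code{complex_pct} (one scenario).
#' @param threshold share threshold, percent (default 5).
#' @return list with \code{effectors} (character, sorted), \code{per_tissue}
#'   (data.frame \code{tissue}, \code{n_key}: key effectors expressed at or
#'   above threshold there) and \code{rankings} (tissue x key-effector rank
#'   table over the key set).
#' @export
key_effectors <- function(results, threshold = 5) {
  if (!nrow(results)) {
    return(list(effectors = character(0),
                per_tissue = data.frame(tissue = character(0),
                                        n_key = integer(0)),
                rankings = NULL))
  }
  hit <- results$complex_pct >= threshold
  eff <- sort(unique(results$effector[hit]))
  per_tissue <- do.call(rbind, lapply(split(results, results$tissue),
    function(df) data.frame(tissue = df$tissue[1],
                            n_key = sum(df$effector %in% eff &
                                          df$complex_pct >= threshold),
                            stringsAsFactors = FALSE)))
  rownames(per_tissue) <- NULL
  rankings <- NULL
  if (length(eff)) {
    rk <- lapply(split(results, results$tissue), function(df) {
      sub <- df[df$effector %in% eff, , drop = FALSE]
      r <- rank_entities(stats::setNames(sub$complex_pct, sub$effector))
      stats::setNames(r$rank[match(eff, r$name)], eff)
    })
    rankings <- do.call(rbind, rk)
  }
  list(effectors = eff, per_tissue = per_tissue, rankings = rankings)
}
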