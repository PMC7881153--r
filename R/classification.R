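# Classification of effectors into three groups by binding efficiency.

#' Full landscape over tissues
#'
#' Solves every tissue at one scenario and stacks a long results table - the
#' package's central output shape.
#'
#' @param profiles list of \code{\link{tissue_profile}}s.
#' @inheritParams solve_tissue
#' @return data.frame \code{tissue}, \code{effector}, \code{class_id},
#'   \code{complex_nm}, \code{complex_pct}, \code{rank}, with a per-tissue
#'   summary in \code{attr(, "summary")} (\code{tissue},
#'   \code{free_ras_nm}, \code{total_complex_nm}).
#' @export
landscape <- function(profiles, panel, scenario = gtp_scenario()) {
  rows <- list()
  summ <- list()
  for (p in profiles) {
    st <- solve_tissue(p, panel, scenario)
    pct <- stats::setNames(rep(0, nrow(panel)), panel$effector)
    if (length(st$complexes_pct)) pct[names(st$complexes_pct)] <- st$complexes_pct
    rk <- rank_entities(pct)
    rows[[length(rows) + 1L]] <- data.frame(
      tissue = p$tissue,
      effector = panel$effector,
      class_id = panel$class_id,
      complex_nm = as.numeric(st$complexes_nm[panel$effector]),
      complex_pct = as.numeric(pct[panel$effector]),
      rank = rk$rank[match(panel$effector, rk$name)],
      stringsAsFactors = FALSE)
    summ[[length(summ) + 1L]] <- data.frame(
      tissue = p$tissue, free_ras_nm = st$free_ras,
      total_complex_nm = st$total_complexes, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- do.call(rbind, summ)
  out
}

#' Enhanced-affinity landscape
#'
#' The membrane-recruited regime used for classification: every effector's
#' Kd divided by the piggyback enhancement factor, at a stimulated GTP
#' load.
#'
#' @inheritParams landscape
#' @param enhancement affinity enhancement factor (default 100).
#' @param gtp stimulated GTP load (default 0.9).
#' @export
enhanced_landscape <- function(profiles, panel, enhancement = 100,
                               gtp = 0.9) {
  panel$kd_um <- panel$kd_um / enhancement
  landscape(profiles, panel, gtp_uniform(gtp))
}

#' Classify effectors by binding efficiency
#'
#' Group 1: at least \code{threshold} percent of all complexes in at least
#' one tissue in the unstimulated reference (efficient binding through the
#' RBD alone). Group 2: reaches the threshold only in the enhanced
#' (membrane-recruited) condition - effectors needing recruitment to the
#' plasma membrane. Group 3: never reaches it - unlikely true Ras
#' effectors. Recruitment-domain annotations are carried as evidence but do
#' not gate the printed rule.
#'
#' @param unstim long results at the 20 percent GTP reference (columns
#'   \code{tissue}, \code{effector}, \code{complex_pct}).
#' @param enhanced long results from \code{\link{enhanced_landscape}}.
#' @param panel panel supplying \code{domains}.
#' @param threshold share threshold, percent (default 5, inclusive).
#' @return data.frame \code{effector}, \code{group} (1/2/3),
#'   \code{max_pct_unstim}, \code{max_pct_enhanced},
#'   \code{has_recruitment_domain}, \code{domains}; group sizes in
#'   \code{attr(, "sizes")}.
#' @export
classify_effectors <- function(unstim, enhanced, panel, threshold = 5) {
  max_by_eff <- function(res, eff) {
    sub <- res[res$effector == eff, , drop = FALSE]
    if (!nrow(sub)) stop("effector missing from a result set: ", eff)
    max(sub$complex_pct)
  }
  eff <- panel$effector
  mu <- vapply(eff, max_by_eff, numeric(1), res = unstim)
  me <- vapply(eff, max_by_eff, numeric(1), res = enhanced)
  group <- ifelse(mu >= threshold, 1L, ifelse(me >= threshold, 2L, 3L))
  out <- data.frame(effector = eff, group = group,
                    max_pct_unstim = as.numeric(mu),
                    max_pct_enhanced = as.numeric(me),
                    has_recruitment_domain = nzchar(panel$domains),
                    domains = panel$domains, stringsAsFactors = FALSE)
  attr(out, "sizes") <- stats::setNames(
    as.integer(table(factor(group, levels = 1:3))), c("group1", "group2", "group3"))
  out
}
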