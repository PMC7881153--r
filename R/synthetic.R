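# Seeded synthetic-data generator.
#
# Emulates the statistical structure of the tissue proteome inputs the
# analyses assume - a 56-effector panel with Kd values spanning the
# observed 0.04-39 uM range (literature anchors kept fixed), 29 tissues
# with log-normally spread effector abundances in the competitive regime
# (sum of effectors exceeding the 20 percent-GTP active Ras pool), KRAS
# dominance except in a pancreas-like tissue, receptor abundances, and
# mutation frequencies drawn from a known Gaussian of rewiring score plus
# noise.  Every draw is reproducible from one integer seed.

#' Synthetic-data configuration
#'
#' @param n_tissues number of tissues (default 29).
#' @param seed integer seed; every generator output is bit-reproducible
#'   from it.
#' @param abundance_log_mean,abundance_log_sd natural-log parameters of the
#'   per-effector abundance distribution (nM scale). The default sd of 1.0
#'   spans the ~50-fold cross-tissue variation seen for individual
#'   effector complexes.
#' @param kd_range Kd sampling range, micromolar.
#' @param fraction_high_affinity share of sampled effectors with Kd at or
#'   below 1 micromolar.
#' @param receptor_range receptor abundance sampling range, nM
#'   (log-uniform).
#' @param competition_target enforce sum(effectors) > 0.2 * sum(Ras) per
#'   tissue by rescaling effector abundances when needed.
#' @param gaussian_truth c(A, mu, sigma) of the mutation-frequency curve.
#' @param noise_sd additive Gaussian noise sd on generated frequencies
#'   (default 5 percent of A).
#' @return list of class \code{synthesis_config}.
#' @export
synthesis_config <- function(n_tissues = 29L, seed = 1L,
                             abundance_log_mean = log(30),
                             abundance_log_sd = 1.0,
                             kd_range = c(0.04, 39),
                             fraction_high_affinity = 0.25,
                             receptor_range = c(5, 200),
                             competition_target = TRUE,
                             gaussian_truth = c(A = 30, mu = 2.0, sigma = 0.3),
                             noise_sd = NULL) {
  stopifnot(n_tissues >= 1, kd_range[1] > 0, kd_range[2] > kd_range[1],
            receptor_range[1] > 0, receptor_range[2] >= receptor_range[1],
            fraction_high_affinity >= 0, fraction_high_affinity <= 1)
  if (is.null(noise_sd)) noise_sd <- 0.05 * gaussian_truth[["A"]]
  structure(list(n_tissues = as.integer(n_tissues), seed = as.integer(seed),
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd, kd_range = kd_range,
                 fraction_high_affinity = fraction_high_affinity,
                 receptor_range = receptor_range,
                 competition_target = isTRUE(competition_target),
                 gaussian_truth = gaussian_truth, noise_sd = noise_sd),
            class = "synthesis_config")
}

#' The 29 modeled tissue names
#'
#' @return character vector of length 29.
#' @export
tissue_names <- function() {
  c("adrenal gland", "appendix", "brain", "colon", "duodenum",
    "endometrium", "esophagus", "fallopian tube", "fat", "gallbladder",
    "heart", "kidney", "liver", "lung", "lymph node", "ovary", "pancreas",
    "placenta", "prostate", "rectum", "salivary gland", "small intestine",
    "smooth muscle", "spleen", "stomach", "testis", "thyroid", "tonsil",
    "urinary bladder")
}

# run code under a private RNG stream derived from (seed, offset), leaving
# the caller's RNG state untouched
with_seed <- function(seed, offset, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed + offset)
  force(code)
}

#' Generate the effector panel
#'
#' Real effector names, the 12-class structure and the SH2/PDZ domain tags
#' come from the packaged skeleton; Kd values use the literature anchors
#' where printed (ARAF 0.07, MLLT4 3.03, SNX27 10,
#' PIK3CD/ARAP1/RADIL/MYO9A 7.5 uM, kept regardless of seed) and are
#' otherwise sampled log-uniformly: with probability
#' \code{fraction_high_affinity} in [min(kd_range), 1] uM, else in
#' [1, max(kd_range)] uM.
#'
#' @param config a \code{\link{synthesis_config}}.
#' @return a \code{\link{ras_panel}} of 56 effectors.
#' @export
generate_panel <- function(config = synthesis_config()) {
  skel <- panel_skeleton()
  with_seed(config$seed, 0L, {
    na_idx <- which(is.na(skel$kd_um))
    hi <- stats::runif(length(na_idx)) < config$fraction_high_affinity
    lo_range <- c(config$kd_range[1], min(1, config$kd_range[2]))
    hi_range <- c(min(1, config$kd_range[2]), config$kd_range[2])
    draw <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
    kd <- numeric(length(na_idx))
    kd[hi] <- draw(sum(hi), lo_range)
    kd[!hi] <- draw(sum(!hi), hi_range)
    skel$kd_um[na_idx] <- kd
  })
  ras_panel(skel$effector, skel$class_id, skel$kd_um, skel$domains)
}

#' Generate tissue abundance profiles
#'
#' Log-normal effector abundances per tissue; Ras isoform totals with KRAS
#' dominant everywhere except the pancreas-like tissue, where the total is
#' split into equal thirds; receptor abundances (EGFR, ERBB2, PVRL3)
#' log-uniform in \code{receptor_range}. With
#' \code{competition_target = TRUE}, tissues whose summed effector
#' abundance does not exceed the 20 percent-GTP active Ras pool are
#' rescaled into the competitive regime.
#'
#' @inheritParams generate_panel
#' @param panel the effector panel to generate abundances for.
#' @return named list of \code{\link{tissue_profile}}s.
#' @export
generate_tissues <- function(config = synthesis_config(),
                             panel = generate_panel(config)) {
  tn <- tissue_names()
  if (config$n_tissues <= length(tn)) {
    tn <- tn[seq_len(config$n_tissues)]
  } else {
    tn <- c(tn, paste0("tissue_", seq_len(config$n_tissues - length(tn))))
  }
  with_seed(config$seed, 1L, {
    profiles <- lapply(tn, function(tt) {
      eff <- stats::rlnorm(nrow(panel), config$abundance_log_mean,
                           config$abundance_log_sd)
      names(eff) <- panel$effector
      ras <- c(HRAS = stats::rlnorm(1, log(60), 0.4),
               KRAS = stats::rlnorm(1, log(250), 0.4),
               NRAS = stats::rlnorm(1, log(60), 0.4))
      if (tt == "pancreas") ras[] <- sum(ras) / 3
      rec <- exp(stats::runif(3, log(config$receptor_range[1]),
                              log(config$receptor_range[2])))
      names(rec) <- c("EGFR", "ERBB2", "PVRL3")
      if (config$competition_target) {
        active <- 0.2 * sum(ras)
        if (sum(eff) <= active) eff <- eff * (1.25 * active / sum(eff))
      }
      tissue_profile(tt, eff, ras, rec)
    })
    names(profiles) <- tn
    profiles
  })
}

#' Generate a mutation-frequency table from rewiring scores
#'
#' Frequencies follow the configured Gaussian of the rewiring score plus
#' additive Gaussian noise, truncated at zero; the generating truth is
#' recorded in \code{attr(, "truth")} for recovery assertions.
#'
#' @inheritParams generate_panel
#' @param scores data.frame \code{tissue}, \code{isoform}, \code{rs}.
#' @return data.frame \code{tissue}, \code{isoform},
#'   \code{frequency_percent}.
#' @export
generate_mutation_frequencies <- function(config, scores) {
  g <- config$gaussian_truth
  with_seed(config$seed, 3L, {
    noise <- stats::rnorm(nrow(scores), 0, config$noise_sd)
    freq <- g[["A"]] * exp(-(scores$rs - g[["mu"]])^2 / (2 * g[["sigma"]]^2)) +
      noise
    out <- data.frame(tissue = scores$tissue, isoform = scores$isoform,
                      frequency_percent = pmax(0, freq),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- g
    out
  })
}

#' Generate synthetic marker expression
#'
#' Log-normal expression for every marker in every tissue, with each
#' tissue's own dominant subtype upweighted so composition estimates have
#' structure to find.
#'
#' @inheritParams generate_panel
#' @param marker_sets named list of marker vectors.
#' @param profiles optional profiles whose tissue names to use.
#' @return numeric matrix tissues x markers.
#' @export
generate_marker_expression <- function(config = synthesis_config(),
                                       marker_sets = read_marker_sets(),
                                       profiles = NULL) {
  tn <- if (is.null(profiles)) tissue_names()[seq_len(config$n_tissues)]
        else vapply(profiles, `[[`, "", "tissue")
  markers <- unlist(marker_sets, use.names = FALSE)
  with_seed(config$seed, 2L, {
    m <- matrix(stats::rlnorm(length(tn) * length(markers), log(50), 0.8),
                nrow = length(tn), dimnames = list(tn, markers))
    # upweight one subtype per tissue, cycling through the subtypes
    for (i in seq_along(tn)) {
      st <- names(marker_sets)[1 + (i - 1) %% length(marker_sets)]
      m[i, marker_sets[[st]]] <- m[i, marker_sets[[st]]] * 5
    }
    m
  })
}
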