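#' Construct and validate an effector panel
#'
#' An effector panel is the static identity table of the modeled Ras
#' effectors: one row per effector with its pathway class (1-12), its
#' dissociation constant for active Ras (in micromolar; all effectors share
#' one Kd across the HRAS/KRAS/NRAS isoforms), and any recruitment-domain
#' tags (e.g. \code{SH2}, \code{PDZ}, \code{PH}) used by the piggyback and
#' classification analyses.
#'
#' @param effector character vector of unique effector names.
#' @param class_id integer vector of pathway class memberships in 1..12.
#' @param kd_um positive numeric vector of Ras-effector dissociation
#'   constants, micromolar.
#' @param domains character vector of semicolon-separated recruitment-domain
#'   tags ("" for none).
#' @return A \code{data.frame} of class \code{ras_panel} with columns
#'   \code{effector}, \code{class_id}, \code{kd_um}, \code{domains}.
#' @examples
#' ras_panel(c("A", "B"), c(1, 2), c(0.1, 5))
#' @export
ras_panel <- function(effector, class_id, kd_um, domains = "") {
  panel <- data.frame(
    effector = as.character(effector),
    class_id = as.integer(class_id),
    kd_um = as.numeric(kd_um),
    domains = rep_len(as.character(domains), length(effector)),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("ras_panel", "data.frame")
  panel
}

#' @rdname ras_panel
#' @param panel object to validate.
#' @export
validate_panel <- function(panel) {
  need <- c("effector", "class_id", "kd_um", "domains")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$effector)) {
    stop("duplicate effector names in panel: ",
         paste(unique(panel$effector[duplicated(panel$effector)]), collapse = ", "))
  }
  if (any(!is.finite(panel$kd_um)) || any(panel$kd_um <= 0)) {
    stop("all Kd values must be finite and > 0 (micromolar)")
  }
  if (any(!panel$class_id %in% 1:12)) {
    stop("class_id must be in 1..12")
  }
  invisible(panel)
}

#' Read / write an effector panel file
#'
#' Panel files are CSV with header \code{effector,class_id,kd_um,domains};
#' Kd is stored in micromolar (as usually reported) and converted to nM
#' internally by the solvers. Domains are semicolon-separated tags.
#'
#' @param path file path.
#' @return \code{read_panel} returns a \code{ras_panel}.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("effector", "class_id", "kd_um")
  if (!all(need %in% names(df))) {
    stop("panel file must have header effector,class_id,kd_um[,domains]")
  }
  if (!"domains" %in% names(df)) df$domains <- ""
  df$domains[is.na(df$domains)] <- ""
  ras_panel(df$effector, as.integer(df$class_id), as.numeric(df$kd_um),
            df$domains)
}

#' @rdname read_panel
#' @param panel a \code{ras_panel}.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  write_csv_lf(as.data.frame(panel), path)
  invisible(path)
}

#' The packaged 56-effector panel skeleton
#'
#' Returns the identity table of the 56 modeled effectors: names, the
#' 12-class pathway grouping, recruitment-domain tags for the SH2 targets of
#' EGFR/ErbB2 (RIN1/2/3, GRB7/10/14) and the PDZ targets of nectin receptors
#' (MLLT4, SNX27, TIAM1/2, RAPGEF2/6, RADIL, RGS12), and the literature Kd
#' anchors (ARAF 0.07, MLLT4 3.03, SNX27 10, and 7.5 uM for
#' PIK3CD/ARAP1/RADIL/MYO9A). Kd values without a printed anchor are NA in
#' the skeleton; \code{\link{generate_panel}} fills them by seeded sampling.
#'
#' @return data.frame with columns \code{effector}, \code{class_id},
#'   \code{kd_um} (NA where no anchor), \code{domains}.
#' @export
panel_skeleton <- function() {
  path <- system.file("extdata", "effector_panel.csv", package = "raswiring",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "integer", "numeric",
                                       "character"))
  df$domains[is.na(df$domains)] <- ""
  df
}

#' Effectors carrying a given recruitment-domain tag
#'
#' @param panel a panel data.frame with a \code{domains} column.
#' @param tag domain tag, e.g. \code{"SH2"} or \code{"PDZ"}.
#' @return character vector of effector names.
#' @export
effectors_with_domain <- function(panel, tag) {
  tags <- strsplit(panel$domains, ";", fixed = TRUE)
  panel$effector[vapply(tags, function(x) tag %in% x, logical(1))]
}
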