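# Marker-based estimate of basic tissue-type composition.

#' Read a marker-set file
#'
#' CSV with header \code{subtype,marker}; subtypes should be the six basic
#' tissue types (epithelial, muscle, adipose, neuronal, connective,
#' lymphoid) with 5-10 markers each (3 suffice for the lymphoid trio
#' PTPRC/CD68/CD19).
#'
#' @param path file path; default is the packaged synthetic marker file
#'   (only the lymphoid trio is literature-anchored).
#' @return named list of character vectors, one per subtype.
#' @export
read_marker_sets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_sets_synthetic.csv",
                        package = "raswiring", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subtype", "marker") %in% names(df))) {
    stop("marker file must have header subtype,marker")
  }
  split(df$marker, df$subtype)
}

#' Estimate tissue-subtype fractions from marker expression
#'
#' For each subtype, the three markers with the highest mean expression
#' across all tissues are selected (ties broken by name) and averaged per
#' tissue into a subtype score; scores are normalized per tissue into
#' percentages summing to 100.
#'
#' @param expression numeric matrix, tissues in rows (rownames), proteins
#'   in columns (colnames); any expression unit (output is scale
#'   invariant).
#' @param marker_sets named list of marker vectors per subtype (see
#'   \code{\link{read_marker_sets}}).
#' @param top_n markers retained per subtype (default 3).
#' @param rank_stat how to rank markers across tissues: \code{"mean"}
#'   (default) or \code{"max"}.
#' @return numeric matrix tissues x subtypes of percentages (rows sum to
#'   100); selected markers in \code{attr(, "selected_markers")}.
#' @export
estimate_tissue_fractions <- function(expression, marker_sets, top_n = 3L,
                                      rank_stat = c("mean", "max")) {
  rank_stat <- match.arg(rank_stat)
  if (is.data.frame(expression)) expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("expression matrix needs tissue rownames and protein colnames")
  }
  stat_fun <- if (rank_stat == "mean") colMeans else function(m) apply(m, 2, max)
  selected <- list()
  scores <- matrix(NA_real_, nrow(expression), length(marker_sets),
                   dimnames = list(rownames(expression), names(marker_sets)))
  for (st in names(marker_sets)) {
    usable <- intersect(marker_sets[[st]], colnames(expression))
    if (length(usable) < top_n) {
      stop("subtype ", st, " has fewer than ", top_n,
           " usable markers in the expression table")
    }
    overall <- stat_fun(expression[, usable, drop = FALSE])
    ord <- order(-overall, names(overall))
    top <- names(overall)[ord][seq_len(top_n)]
    selected[[st]] <- top
    scores[, st] <- rowMeans(expression[, top, drop = FALSE])
  }
  totals <- rowSums(scores)
  if (any(totals <= 0)) {
    stop("tissue(s) with zero total marker score: ",
         paste(rownames(scores)[totals <= 0], collapse = ", "))
  }
  out <- 100 * scores / totals
  attr(out, "selected_markers") <- selected
  out
}
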