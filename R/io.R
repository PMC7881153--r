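# Readers and writers for the CSV dialects used throughout.
#
# Conventions: comma-separated, mandatory header, UTF-8, LF line endings;
# concentration columns carry an _nm suffix and Kd columns _um so units are
# unambiguous; numeric values are written with 17 significant digits so
# write-then-read round trips are lossless at double precision.

# deterministic CSV writer (LF, UTF-8, %.17g numerics, no quoting - none of
# the identifiers used here contain separators)
write_csv_lf <- function(df, path) {
  fmt_col <- function(x) {
    if (is.double(x)) formatC(x, digits = 17, format = "g")
    else as.character(x)
  }
  cells <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read tissue abundance profiles
#'
#' Long-format CSV with header \code{tissue,protein,abundance_nm} covering,
#' per tissue, every panel effector, the Ras isoforms and any receptors.
#' Proteins that are neither panel effectors, Ras isoforms nor known
#' receptors are retained on the profile's receptor slot and flagged in
#' \code{attr(, "extra_proteins")}. A tissue missing a panel effector is a
#' hard error (imputation is out of scope here); negative abundances and
#' malformed rows are errors with the offending line.
#'
#' @param path file path.
#' @param panel the effector panel the file must cover.
#' @param receptors protein names treated as receptors.
#' @return named list of \code{\link{tissue_profile}}s.
#' @export
read_abundances <- function(path, panel,
                            receptors = c("EGFR", "ERBB2", "PVRL3")) {
  if (!file.exists(path)) stop("abundance file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "protein", "abundance_nm")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("abundance file must have header tissue,protein,abundance_nm")
  }
  bad <- which(!is.finite(df$abundance_nm))
  if (length(bad)) {
    stop("malformed abundance at line ", bad[1] + 1L, " of ", path)
  }
  bad <- which(df$abundance_nm < 0)
  if (length(bad)) {
    stop("negative abundance at line ", bad[1] + 1L, " of ", path,
         " (", df$protein[bad[1]], " in ", df$tissue[bad[1]], ")")
  }
  iso <- c("HRAS", "KRAS", "NRAS")
  extra <- sort(setdiff(unique(df$protein),
                        c(panel$effector, iso, receptors)))
  profiles <- lapply(split(df, df$tissue), function(sub) {
    if (anyDuplicated(sub$protein)) {
      stop("duplicate protein rows for tissue ", sub$tissue[1], ": ",
           paste(unique(sub$protein[duplicated(sub$protein)]), collapse = ", "))
    }
    v <- stats::setNames(sub$abundance_nm, sub$protein)
    missing_eff <- setdiff(panel$effector, names(v))
    if (length(missing_eff)) {
      stop("tissue ", sub$tissue[1], " is missing abundance for effector(s): ",
           paste(missing_eff, collapse = ", "))
    }
    tissue_profile(sub$tissue[1],
                   effectors = v[panel$effector],
                   ras = v[intersect(iso, names(v))],
                   receptors = v[setdiff(names(v), c(panel$effector, iso))])
  })
  attr(profiles, "extra_proteins") <- extra
  profiles
}

#' @rdname read_abundances
#' @param profiles named list of \code{\link{tissue_profile}}s.
#' @export
write_abundances <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    v <- c(p$effectors, p$ras, p$receptors)
    data.frame(tissue = p$tissue, protein = names(v),
               abundance_nm = as.numeric(v), stringsAsFactors = FALSE)
  })
  write_csv_lf(do.call(rbind, rows), path)
}

#' Write / read a long results table
#'
#' The standard per-tissue output of \code{\link{landscape}}:
#' \code{tissue,effector,class_id,complex_nm,complex_pct,rank}, plus a
#' sibling summary file \code{tissue,free_ras_nm,total_complex_nm} when the
#' table carries one. Round trips are lossless at double precision.
#'
#' @param results a \code{\link{landscape}} results data.frame.
#' @param path output CSV path; the summary (if any) goes to
#'   \code{*_summary.csv}.
#' @export
write_results <- function(results, path) {
  write_csv_lf(results, path)
  summ <- attr(results, "summary")
  if (!is.null(summ)) {
    write_csv_lf(summ, sub("\\.csv$", "_summary.csv", path))
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  summ_path <- sub("\\.csv$", "_summary.csv", path)
  if (file.exists(summ_path)) {
    attr(df, "summary") <- utils::read.csv(summ_path, stringsAsFactors = FALSE)
  }
  df
}

#' Read / write a mutation-frequency table
#'
#' CSV with header \code{tissue,isoform,frequency_percent} (one frequency
#' per tissue-isoform pair; combining multiple cancer studies per tissue is
#' the table author's concern).
#'
#' @param path file path.
#' @export
read_mutation_frequencies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "isoform", "frequency_percent")
  if (!all(need %in% names(df))) {
    stop("mutation frequency file must have header tissue,isoform,frequency_percent")
  }
  if (any(!is.finite(df$frequency_percent)) || any(df$frequency_percent < 0)) {
    stop("frequencies must be finite and >= 0")
  }
  df
}

#' @rdname read_mutation_frequencies
#' @param freqs data.frame \code{tissue,isoform,frequency_percent}.
#' @export
write_mutation_frequencies <- function(freqs, path) {
  write_csv_lf(freqs[, c("tissue", "isoform", "frequency_percent")], path)
}
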