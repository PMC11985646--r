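# Plain-text I/O: MGF spectra, CSV feature/peak tables, TSV reports.

#' Read MS2 features from an MGF file
#'
#' Minimal Mascot Generic Format reader covering the standard fields
#' (`PEPMASS`, `CHARGE`, `RTINSECONDS`, `TITLE`) and peak lines
#' (`mz intensity`). Charge sign determines polarity; a missing charge
#' defaults to negative mode.
#'
#' @param path Path to an MGF file.
#' @return A list of [ms2_feature()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L; n <- length(lines); feat_n <- 0L
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      feat_n <- feat_n + 1L
      id <- paste0("F", feat_n); pep <- NA_real_; rt <- NA_real_
      polarity <- "negative"; mzs <- numeric(0); ints <- numeric(0)
      i <- i + 1L
      while (i <= n && trimws(lines[i]) != "END IONS") {
        l <- trimws(lines[i])
        if (grepl("^TITLE=", l)) {
          id <- sub("^TITLE=", "", l)
        } else if (grepl("^PEPMASS=", l)) {
          pep <- as.numeric(strsplit(sub("^PEPMASS=", "", l), "[[:space:]]+")[[1]][1])
        } else if (grepl("^RTINSECONDS=", l)) {
          rt <- as.numeric(sub("^RTINSECONDS=", "", l)) / 60
        } else if (grepl("^CHARGE=", l)) {
          polarity <- if (grepl("-", l, fixed = TRUE)) "negative" else "positive"
        } else if (grepl("^[0-9]", l)) {
          v <- as.numeric(strsplit(l, "[[:space:]]+")[[1]])
          mzs <- c(mzs, v[1])
          ints <- c(ints, if (length(v) > 1) v[2] else NA_real_)
        }
        i <- i + 1L
      }
      out[[length(out) + 1L]] <-
        ms2_feature(id, pep, polarity, cbind(mzs, ints), rt = rt)
    }
    i <- i + 1L
  }
  out
}

#' Write MS2 features to an MGF file
#'
#' @param features List of [ms2_feature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in features) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", f$id),
                 paste0("PEPMASS=", sprintf("%.6f", f$precursor_mz)),
                 paste0("CHARGE=1", if (f$polarity == "negative") "-" else "+"),
                 if (!is.na(f$rt)) paste0("RTINSECONDS=", sprintf("%.2f", f$rt * 60))),
               con)
    if (nrow(f$peaks)) {
      ints <- ifelse(is.na(f$peaks$intensity), 100, f$peaks$intensity)
      writeLines(sprintf("%.5f %.2f", f$peaks$mz, ints), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read MS2 features from a CSV table
#'
#' Expected columns: `id`, `rt_min`, `polarity`, `precursor_mz`, `ms2`
#' (semicolon-separated fragment m/z; may be empty). Extra columns are
#' ignored.
#'
#' @param path Path to a CSV file.
#' @return A list of [ms2_feature()] objects.
#' @export
read_features_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "rt_min", "polarity", "precursor_mz", "ms2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    ms2 <- tab$ms2[i]
    peaks <- if (is.na(ms2) || !nzchar(trimws(ms2))) numeric(0) else
      as.numeric(strsplit(ms2, ";")[[1]])
    ms2_feature(tab$id[i], tab$precursor_mz[i], tab$polarity[i], peaks,
                rt = tab$rt_min[i])
  })
}

#' Bundled LC-MS/MS feature fixture
#'
#' The transcription of the published 82-feature LC-MS/MS identification
#' table (precursor m/z as printed, unit-resolution MS2 fragment lists,
#' annotated identities). Printed masses are retained verbatim, including
#' rows whose m/z is inconsistent with the assigned formula; such rows
#' document the limits of the printed data and are never treated as mass
#' ground truth.
#'
#' @return A list with `features` (list of [ms2_feature()]) and `truth`
#'   (data.frame `feature_id`, `true_name`, `note`).
#' @export
bidens_lcms_features <- function() {
  path <- system.file("extdata", "bidens_lcms_features.csv", package = "flavomics")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(features = read_features_csv(path),
       truth = data.frame(feature_id = as.character(tab$id),
                          true_name = tab$true_name, note = tab$note,
                          stringsAsFactors = FALSE))
}

#' Write an annotation report as TSV
#'
#' @param report Data.frame from [annotate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
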