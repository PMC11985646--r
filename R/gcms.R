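# GC-MS lipoidal composition: fatty-acid saturation by ring plus
# double-bond equivalents, curated sterol/other categories, and class
# area-percent aggregation.

#' Ring plus double-bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1 for a CHNOS(P) composition. A free fatty acid
#' or its methyl/ethyl ester has RDBE 1 (the carbonyl); each additional
#' unit marks a ring or double bond.
#'
#' @param f A `mol_formula` or formula string.
#' @return Half-integer RDBE value.
#' @examples
#' rdbe("C16H32O2") # 1, saturated
#' rdbe("C18H34O2") # 2, one double bond
#' @export
rdbe <- function(f) {
  f <- .as_formula(f)
  cnt <- function(e) if (e %in% names(f)) unclass(f)[[e]] else 0L
  cnt("C") - cnt("H") / 2 + cnt("N") / 2 + 1
}

#' Classify a GC peak as a saturated or unsaturated fatty acid
#'
#' A peak is a fatty acid (free acid or methyl/ethyl ester) iff its name
#' contains "acid" and its formula has exactly two oxygens; it is saturated
#' iff RDBE equals 1 (the acid/ester carbonyl baseline) and unsaturated iff
#' RDBE is 2 or more.
#'
#' @param name Compound name as reported by the GC library search.
#' @param formula A `mol_formula` or formula string.
#' @return `"saturated"`, `"unsaturated"` or `"not_fa"`.
#' @examples
#' classify_fatty_acid("Palmitic acid", "C16H32O2")        # saturated
#' classify_fatty_acid("Oleic acid, methyl ester", "C19H36O2") # unsaturated
#' @export
classify_fatty_acid <- function(name, formula) {
  f <- .as_formula(formula)
  n_ox <- if ("O" %in% names(f)) unclass(f)[["O"]] else 0L
  if (!grepl("acid", name, ignore.case = TRUE) || n_ox != 2L) return("not_fa")
  r <- rdbe(f)
  if (r == 1) "saturated" else if (r >= 2) "unsaturated" else "not_fa"
}

#' Read a GC peak table
#'
#' Expected CSV columns: `rt_min`, `name`, `formula`, `area_pct`, and
#' `curated_category` (`sterol` or `other`; may be empty for fatty-acid
#' rows, whose class is computed, not curated).
#'
#' @param path Path to a CSV file.
#' @return A data.frame of GC peaks.
#' @export
read_gc_peaks <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rt_min", "name", "formula", "area_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$curated_category)) tab$curated_category <- NA_character_
  tab$curated_category[!nzchar(trimws(ifelse(is.na(tab$curated_category), "",
                                             tab$curated_category)))] <- NA_character_
  if (any(tab$area_pct < 0)) stop("negative area_pct")
  tab
}

#' Bundled GC-MS peak fixture
#'
#' The 19-peak lipoidal-matter GC table transcribed from the published
#' compound list (retention time, identity, formula, area percent), with
#' the curated sterol/other categories used by the published class totals.
#'
#' @return A data.frame of GC peaks.
#' @export
bidens_gc_peaks <- function() {
  read_gc_peaks(system.file("extdata", "bidens_gc_peaks.csv",
                            package = "flavomics"))
}

#' Summarize GC class composition
#'
#' Splits peaks into saturated fatty acids, unsaturated fatty acids,
#' sterols and other identified compounds, and sums area percentages per
#' class. Fatty-acid membership and saturation are computed by rule
#' ([classify_fatty_acid()]); non-fatty-acid peaks must carry a curated
#' category (`sterol` or `other`), since no computable rule reproduces
#' that grouping.
#'
#' @param peaks A data.frame with columns `name`, `formula`, `area_pct`,
#'   `curated_category`.
#' @return A list of class `gc_composition` with elements `saturated_fa_pct`,
#'   `unsaturated_fa_pct`, `sterol_pct`, `other_pct`, `total_pct`, `n_peaks`
#'   and the per-peak `classes` vector.
#' @export
summarize_composition <- function(peaks) {
  if (!nrow(peaks)) {
    return(structure(list(saturated_fa_pct = 0, unsaturated_fa_pct = 0,
                          sterol_pct = 0, other_pct = 0, total_pct = 0,
                          n_peaks = 0L, classes = character(0)),
                     class = "gc_composition"))
  }
  cls <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    fa <- classify_fatty_acid(peaks$name[i], peaks$formula[i])
    if (fa == "not_fa") {
      cc <- peaks$curated_category[i]
      if (is.na(cc) || !cc %in% c("sterol", "other")) {
        stop("peak ", sQuote(peaks$name[i]),
             " is not a fatty acid and has no curated category")
      }
      cls[i] <- cc
    } else {
      cls[i] <- fa
    }
  }
  s <- function(k) sum(peaks$area_pct[cls == k])
  structure(list(saturated_fa_pct = s("saturated"),
                 unsaturated_fa_pct = s("unsaturated"),
                 sterol_pct = s("sterol"), other_pct = s("other"),
                 total_pct = sum(peaks$area_pct), n_peaks = nrow(peaks),
                 classes = cls),
            class = "gc_composition")
}

#' @export
print.gc_composition <- function(x, ...) {
  cat("GC class composition (", x$n_peaks, " peaks)\n", sep = "")
  cat(sprintf("  saturated fatty acids:   %6.2f%%\n", x$saturated_fa_pct))
  cat(sprintf("  unsaturated fatty acids: %6.2f%%\n", x$unsaturated_fa_pct))
  cat(sprintf("  sterols:                 %6.2f%%\n", x$sterol_pct))
  cat(sprintf("  other identified:        %6.2f%%\n", x$other_pct))
  cat(sprintf("  total identified:        %6.2f%%\n", x$total_pct))
  invisible(x)
}

#' Rounded class totals
#'
#' Class sums rounded to two decimals, the precision at which composition
#' tables are conventionally reported.
#'
#' @param x A `gc_composition`.
#' @return Named numeric vector of the four class sums and the total.
#' @export
composition_rounded <- function(x) {
  stopifnot(inherits(x, "gc_composition"))
  round(c(saturated_fa_pct = x$saturated_fa_pct,
          unsaturated_fa_pct = x$unsaturated_fa_pct,
          sterol_pct = x$sterol_pct, other_pct = x$other_pct,
          total_pct = x$total_pct), 2)
}
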