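# Molecular-formula arithmetic: parsing, nominal/monoisotopic mass, adduct
# m/z, ppm error, and bounded candidate-formula generation.

# package-local cache for the isotope table
.flavomics_env <- new.env(parent = emptyenv())

#' Principal-isotope mass table
#'
#' Reads the plain-text isotope table shipped with the package (element
#' symbol, mass number of the principal isotope, exact mass in Da). The
#' table is cached after the first call.
#'
#' @return A data.frame with columns `element`, `mass_number`, `exact_mass`.
#' @export
isotope_masses <- function() {
  if (is.null(.flavomics_env$isotopes)) {
    path <- system.file("extdata", "isotope_masses.tsv", package = "flavomics")
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .flavomics_env$isotopes <- tab
  }
  .flavomics_env$isotopes
}

# proton mass in Da; the charge carrier for [M+H]+ / [M-H]- under the
# proton-mass convention (electron mass absorbed)
PROTON_MASS <- 1.00727646688

.known_elements <- function() isotope_masses()$element

.exact_mass_of <- function(elements) {
  tab <- isotope_masses()
  tab$exact_mass[match(elements, tab$element)]
}

.mass_number_of <- function(elements) {
  tab <- isotope_masses()
  tab$mass_number[match(elements, tab$element)]
}

# Hill order: C first, then H, then other elements alphabetically; without
# carbon, all elements alphabetically.
.hill_order <- function(elements) {
  if ("C" %in% elements) {
    rest <- sort(setdiff(elements, c("C", "H")))
    c("C", intersect("H", elements), rest)
  } else {
    sort(elements)
  }
}

#' Parse a molecular formula
#'
#' Accepts plain Hill-style strings (`"C16H32O2"`), the underscore dialect
#' used in typed-up tables (`"C_16_H_32_O_2_"`), and Unicode-subscript
#' digits. Repeated element symbols are summed.
#'
#' @param text A single formula string.
#' @return An object of class `mol_formula`: a named integer vector of
#'   element counts in Hill order, zero counts dropped.
#' @examples
#' parse_formula("C16H32O2")
#' parse_formula("C_21_H_20_O_12_")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- text
  # normalise Unicode subscript digits U+2080..U+2089 to ASCII
  subs <- intToUtf8(0x2080 + 0:9, multiple = TRUE)
  for (i in seq_along(subs)) s <- gsub(subs[i], as.character(i - 1L), s, fixed = TRUE)
  s <- gsub("_", "", s)
  s <- gsub("[[:space:]]", "", s)
  if (s == "") {
    return(mol_formula(integer(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("malformed formula string: ", sQuote(text))
  }
  el <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  bad <- setdiff(el, .known_elements())
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (any(grepl("^0", cnt))) {
    stop("zero or zero-prefixed element count in ", sQuote(text))
  }
  n <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  counts <- tapply(n, el, sum)
  mol_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Construct a molecular formula from counts
#'
#' @param counts Named integer vector of element counts (names are element
#'   symbols). Zero counts are dropped; negative counts are an error.
#' @return A `mol_formula` object.
#' @export
mol_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (length(counts)) {
    if (is.null(names(counts)) || any(names(counts) == "")) {
      stop("counts must be a named vector of element counts")
    }
    bad <- setdiff(names(counts), .known_elements())
    if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    if (any(counts < 0L)) stop("negative element count")
    counts <- counts[.hill_order(names(counts))]
  }
  structure(as.integer(counts), names = names(counts), class = "mol_formula")
}

.as_formula <- function(f) {
  if (inherits(f, "mol_formula")) f else parse_formula(f)
}

#' @export
format.mol_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (monoisotopic ",
      sprintf("%.5f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' Formula sum
#'
#' Element-wise sum of two formulas (multiset union), used for composing an
#' aglycone with glycosyl/acyl residues.
#'
#' @param f1,f2 `mol_formula` objects or formula strings.
#' @return A `mol_formula`.
#' @export
formula_sum <- function(f1, f2) {
  f1 <- .as_formula(f1); f2 <- .as_formula(f2)
  el <- union(names(f1), names(f2))
  v <- stats::setNames(integer(length(el)), el)
  v[names(f1)] <- v[names(f1)] + unclass(f1)
  v[names(f2)] <- v[names(f2)] + unclass(f2)
  mol_formula(v)
}

#' Formula difference
#'
#' @param f1,f2 `mol_formula` objects or formula strings; every count of
#'   `f2` must be available in `f1`.
#' @return A `mol_formula`.
#' @export
formula_diff <- function(f1, f2) {
  f1 <- .as_formula(f1); f2 <- .as_formula(f2)
  el <- union(names(f1), names(f2))
  v <- stats::setNames(integer(length(el)), el)
  v[names(f1)] <- v[names(f1)] + unclass(f1)
  v[names(f2)] <- v[names(f2)] - unclass(f2)
  if (any(v < 0L)) stop("formula_diff: subtrahend not contained in minuend")
  mol_formula(v)
}

#' Nominal (integer) mass
#'
#' Sum of the integer mass numbers of each element's principal isotope
#' (C = 12, H = 1, N = 14, O = 16, S = 32), the convention under which the
#' molecular weights in GC-MS compound tables are quoted.
#'
#' @param f A `mol_formula` or formula string.
#' @return Integer mass in Da.
#' @examples
#' nominal_mass("C16H32O2") # palmitic acid, 256
#' @export
nominal_mass <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return(0L)
  as.integer(sum(unclass(f) * .mass_number_of(names(f))))
}

#' Monoisotopic (exact) mass
#'
#' Sum of principal-isotope exact masses from the shipped isotope table.
#'
#' @param f A `mol_formula` or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C15H10O7") # quercetin, 302.04265
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return(0)
  sum(unclass(f) * .exact_mass_of(names(f)))
}

#' Electrospray adduct specification
#'
#' Supported singly charged adducts are `"[M-H]-"` (negative mode) and
#' `"[M+H]+"` (positive mode). The mass shift is plus/minus one proton mass
#' (1.007276 Da); the electron mass is absorbed into the proton convention.
#'
#' @param name Adduct name, `"[M-H]-"` or `"[M+H]+"`.
#' @return A list with `name`, `polarity`, `mass_shift` (Da) and `charge`.
#' @export
adduct_spec <- function(name) {
  switch(name,
    "[M-H]-" = list(name = "[M-H]-", polarity = "negative",
                    mass_shift = -PROTON_MASS, charge = -1L),
    "[M+H]+" = list(name = "[M+H]+", polarity = "positive",
                    mass_shift = +PROTON_MASS, charge = +1L),
    stop("unsupported adduct: ", sQuote(name),
         " (only [M-H]- and [M+H]+ are supported)")
  )
}

#' Default adduct for an ionization mode
#'
#' @param polarity `"negative"` or `"positive"`.
#' @return An adduct spec (see [adduct_spec()]).
#' @export
adduct_for_polarity <- function(polarity) {
  polarity <- match.arg(polarity, c("negative", "positive"))
  adduct_spec(if (polarity == "negative") "[M-H]-" else "[M+H]+")
}

#' Theoretical adduct m/z
#'
#' @param f A `mol_formula` or formula string.
#' @param adduct An adduct name or the result of [adduct_spec()].
#' @return m/z in Da for the singly charged adduct ion.
#' @examples
#' adduct_mz("C15H10O7", "[M-H]-") # 301.03538
#' @export
adduct_mz <- function(f, adduct) {
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  monoisotopic_mass(f) + adduct$mass_shift
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da), must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Default element bounds for formula generation
#'
#' Wide enough for phenolics, flavonoid di-glycosides and acylated
#' glycosides observed in plant extracts.
#'
#' @return Named integer vector of per-element maximum counts.
#' @export
default_element_bounds <- function() {
  c(C = 60L, H = 100L, N = 6L, O = 20L, S = 3L)
}

#' Generate candidate molecular formulas for an observed m/z
#'
#' Exhaustively enumerates all formulas within per-element bounds whose
#' theoretical adduct m/z lies within `tol_ppm` of the observed m/z (ppm
#' taken relative to the theoretical value). Results are sorted by absolute
#' ppm error, ties broken by the Hill-order formula string.
#'
#' @param mz Observed m/z (Da), positive.
#' @param adduct Adduct name or spec (see [adduct_spec()]).
#' @param tol_ppm Tolerance in ppm (default 20, the usual identification
#'   cutoff for TOF data).
#' @param bounds Named integer vector of per-element maximum counts.
#' @return A data.frame with columns `formula` (Hill string),
#'   `theoretical_mz` and `error_ppm`.
#' @examples
#' generate_formulas(301.0354, "[M-H]-", 20,
#'                   bounds = c(C = 20, H = 30, N = 3, O = 10))
#' @export
generate_formulas <- function(mz, adduct, tol_ppm = 20,
                              bounds = default_element_bounds()) {
  stopifnot(is.numeric(mz), length(mz) == 1L)
  if (mz <= 0) stop("mz must be positive")
  if (tol_ppm < 0) stop("tol_ppm must be non-negative")
  if (is.null(bounds) || !length(bounds) || is.null(names(bounds))) {
    stop("bounds must be a named vector of per-element maxima")
  }
  bad <- setdiff(names(bounds), .known_elements())
  if (length(bad)) stop("unknown element symbol(s) in bounds: ",
                        paste(bad, collapse = ", "))
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  bounds <- stats::setNames(as.integer(bounds), names(bounds))

  # neutral monoisotopic mass window implied by the ppm window on the ion
  target <- mz - adduct$mass_shift
  # |obs - th| <= tol*1e-6*th  =>  th in [obs/(1+tol), obs/(1-tol)]
  t <- tol_ppm * 1e-6
  ion_lo <- mz / (1 + t)
  ion_hi <- if (t < 1) mz / (1 - t) else Inf
  m_lo <- ion_lo - adduct$mass_shift
  m_hi <- ion_hi - adduct$mass_shift

  heavy <- setdiff(names(bounds), "H")
  mH <- .exact_mass_of("H")
  grids <- lapply(heavy, function(e) 0:bounds[[e]])
  names(grids) <- heavy
  grid <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  base <- as.numeric(as.matrix(grid) %*% .exact_mass_of(heavy))

  hmax_b <- if ("H" %in% names(bounds)) bounds[["H"]] else 0L
  h_lo <- pmax(0L, ceiling((m_lo - base) / mH - 1e-9))
  h_hi <- pmin(hmax_b, floor((m_hi - base) / mH + 1e-9))
  keep <- which(h_lo <= h_hi)

  out <- list()
  for (i in keep) {
    for (h in h_lo[i]:h_hi[i]) {
      v <- c(unlist(grid[i, , drop = TRUE]), H = h)
      th <- base[i] + h * mH + adduct$mass_shift
      err <- ppm_error(mz, th)
      if (abs(err) <= tol_ppm + 1e-12) {
        f <- mol_formula(stats::setNames(as.integer(v), names(v)))
        if (length(f)) {
          out[[length(out) + 1L]] <-
            data.frame(formula = format(f), theoretical_mz = th,
                       error_ppm = err, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(formula = character(0), theoretical_mz = numeric(0),
                      error_ppm = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(abs(res$error_ppm), res$formula), , drop = FALSE]
  rownames(res) <- NULL
  res
}
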