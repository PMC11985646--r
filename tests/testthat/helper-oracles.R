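# Independent oracles: minimal re-implementations used only to cross-check
# package results. They read the shipped isotope table directly and use
# their own parsing/enumeration code paths.

oracle_isotopes <- function() {
  path <- system.file("extdata", "isotope_masses.tsv", package = "flavomics")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab$exact_mass, tab$element)
}

oracle_mass_numbers <- function() {
  path <- system.file("extdata", "isotope_masses.tsv", package = "flavomics")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab$mass_number, tab$element)
}

# token-by-token formula summation, independent of parse_formula
oracle_counts <- function(text) {
  s <- gsub("_", "", text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

oracle_mono <- function(text) {
  iso <- oracle_isotopes()
  cnt <- oracle_counts(text)
  sum(iso[names(cnt)] * cnt)
}

oracle_nominal <- function(text) {
  mn <- oracle_mass_numbers()
  cnt <- oracle_counts(text)
  sum(mn[names(cnt)] * cnt)
}

ORACLE_PROTON <- 1.00727646688

# exhaustive brute-force enumeration over the bounded CHNOS lattice,
# nested loops, no pruning beyond the bounds themselves
oracle_enumerate <- function(mz, shift, tol_ppm, bounds) {
  iso <- oracle_isotopes()
  hits <- character(0)
  bC <- bounds[["C"]]; bH <- bounds[["H"]]
  bN <- if ("N" %in% names(bounds)) bounds[["N"]] else 0
  bO <- if ("O" %in% names(bounds)) bounds[["O"]] else 0
  bS <- if ("S" %in% names(bounds)) bounds[["S"]] else 0
  for (nc in 0:bC) for (nh in 0:bH) for (nn in 0:bN)
    for (no in 0:bO) for (ns in 0:bS) {
      if (nc + nh + nn + no + ns == 0) next
      th <- nc * iso[["C"]] + nh * iso[["H"]] + nn * iso[["N"]] +
        no * iso[["O"]] + ns * iso[["S"]] + shift
      if (th <= 0) next
      if (abs((mz - th) / th * 1e6) <= tol_ppm) {
        f <- ""
        if (nc > 0) f <- paste0(f, "C", if (nc > 1) nc)
        if (nh > 0) f <- paste0(f, "H", if (nh > 1) nh)
        if (nn > 0) f <- paste0(f, "N", if (nn > 1) nn)
        if (no > 0) f <- paste0(f, "O", if (no > 1) no)
        if (ns > 0) f <- paste0(f, "S", if (ns > 1) ns)
        hits <- c(hits, f)
      }
    }
  sort(hits)
}
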