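# Fragmentation chemistry of flavonoid glycosides and phenolics:
# neutral-loss rules, O-/C-glycoside linkage classification,
# retro-Diels-Alder (RDA) diagnostic fragments, and aglycone matching.

#' Neutral-loss rule set
#'
#' Loads the shipped JSON rule set: glycosyl residues (hexosyl 162,
#' deoxyhexosyl 146, pentosyl 132, hexuronyl 176, the rutinosyl-type
#' disaccharide 308), the coumaroyl acyl residue (146), ubiquitous small
#' losses (water 18, CO2 44, CO 28, methyl 15) and the cross-ring
#' C-glycoside cleavages (120 and 90).
#'
#' @param path Optional path to an alternative JSON rule file.
#' @return A data.frame with columns `name`, `formula`, `nominal`,
#'   `exact` (monoisotopic loss mass, Da) and `category`.
#' @export
neutral_loss_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.flavomics_env$loss_rules)) return(.flavomics_env$loss_rules)
    path <- system.file("extdata", "neutral_loss_rules.json", package = "flavomics")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)$rules
  raw$exact <- vapply(raw$formula, function(f) monoisotopic_mass(parse_formula(f)),
                      numeric(1))
  stopifnot(all(raw$nominal ==
                  vapply(raw$formula, function(f) nominal_mass(parse_formula(f)),
                         integer(1))))
  if (cache) .flavomics_env$loss_rules <- raw
  raw
}

#' Curated aglycone library
#'
#' Loads the shipped aglycone records: name, formula, flavonoid subclass,
#' negative-mode diagnostic fragment m/z (nominal), and the composition of
#' the A-ring-containing 1,3-RDA product where the scaffold admits one.
#'
#' @param path Optional path to an alternative JSON library.
#' @return A list of aglycone records (lists).
#' @export
aglycone_library <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.flavomics_env$aglycones)) return(.flavomics_env$aglycones)
    path <- system.file("extdata", "aglycones.json", package = "flavomics")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)$aglycones
  names(raw) <- vapply(raw, `[[`, character(1), "name")
  if (cache) .flavomics_env$aglycones <- raw
  raw
}

#' Match a precursor-to-fragment mass difference against the loss rules
#'
#' Finds all single rules, and chains of at most two sugar/acyl residues,
#' whose summed loss matches `parent_mz - fragment_mz` within `tol`.
#' Matching is at nominal (integer) level by default, mirroring spectra in
#' which fragment m/z are reported as integers; set `level = "exact"` to
#' match against monoisotopic residue masses.
#'
#' @param parent_mz,fragment_mz m/z of the precursor and product ion (Da);
#'   `parent_mz` must not be smaller than `fragment_mz`.
#' @param tol Matching tolerance in Da (default 0.5).
#' @param level `"nominal"` or `"exact"`.
#' @param rules A rule data.frame, defaults to [neutral_loss_rules()].
#' @return A data.frame of matches sorted by `abs(delta)`: columns `rule`
#'   (single rule name or `"a+b"` chain), `loss` (matched loss mass),
#'   `delta` (observed minus matched), `category` and `matched_at`.
#' @examples
#' loss_candidates(477.0676, 301, 0.5) # hexuronyl, 176
#' @export
loss_candidates <- function(parent_mz, fragment_mz, tol = 0.5,
                            level = c("nominal", "exact"),
                            rules = neutral_loss_rules()) {
  level <- match.arg(level)
  stopifnot(tol > 0)
  if (fragment_mz > parent_mz) stop("fragment_mz exceeds parent_mz")
  if (fragment_mz < 0) stop("fragment_mz must be non-negative")
  obs <- parent_mz - fragment_mz
  mass <- if (level == "nominal") rules$nominal else rules$exact

  cand <- data.frame(rule = rules$name, loss = mass,
                     category = rules$category, stringsAsFactors = FALSE)

  chainable <- which(rules$category %in% c("sugar", "acyl"))
  if (length(chainable) > 1) {
    idx <- utils::combn(chainable, 2)
    pairs <- data.frame(
      rule = paste(rules$name[idx[1, ]], rules$name[idx[2, ]], sep = "+"),
      loss = mass[idx[1, ]] + mass[idx[2, ]],
      category = "chain", stringsAsFactors = FALSE)
    cand <- rbind(cand, pairs)
  }
  if (length(chainable)) {
    twice <- data.frame(
      rule = paste(rules$name[chainable], rules$name[chainable], sep = "+"),
      loss = if (level == "nominal") 2L * mass[chainable] else 2 * mass[chainable],
      category = "chain", stringsAsFactors = FALSE)
    cand <- rbind(cand, twice)
  }

  cand$delta <- obs - cand$loss
  hit <- cand[abs(cand$delta) <= tol, , drop = FALSE]
  hit$matched_at <- rep(level, nrow(hit))
  hit <- hit[order(abs(hit$delta), hit$rule), , drop = FALSE]
  rownames(hit) <- NULL
  hit[, c("rule", "loss", "delta", "category", "matched_at")]
}

#' Classify the glycosidic linkage from a set of loss matches
#'
#' Cross-ring losses (90/120 Da) indicate a C-linked sugar; a full glycosyl
#' loss without any cross-ring loss indicates an O-linked sugar.
#'
#' @param matches A data.frame as returned by [loss_candidates()] (rows
#'   from one feature may be concatenated).
#' @return `"C_glycoside"`, `"O_glycoside"` or `"none"`.
#' @export
classify_linkage <- function(matches) {
  if (is.null(matches) || !nrow(matches)) return("none")
  if (any(matches$category == "cross_ring")) return("C_glycoside")
  if (any(matches$category %in% c("sugar", "chain"))) return("O_glycoside")
  "none"
}

#' Predict retro-Diels-Alder fragments of an aglycone
#'
#' C-ring RDA cleavage splits a flavonoid into an A-ring-containing and a
#' B-ring-containing product. The A-part composition of the 1,3 cleavage is
#' stored on the aglycone record (C7H4O4 for the common 5,7-dihydroxy
#' A-ring); the B-part is its complement in the aglycone formula, so the
#' ion and its complementary neutral conserve the precursor mass by
#' construction. Flavonols additionally get the 1,4 cleavage whose A-side
#' neutral is the 1,3 A-part minus CH2O.
#'
#' @param aglycone An aglycone record (list) or a name resolved against
#'   [aglycone_library()].
#' @param polarity `"negative"` (default) or `"positive"`.
#' @return A data.frame with columns `label` (e.g. `"1,3A-"`), `mz`
#'   (nominal) and `complement_neutral` (nominal mass of the neutral
#'   partner). For scaffolds without a defined partition (chalcones,
#'   aurones) a zero-row data.frame with attribute `reason` is returned.
#' @examples
#' rda_fragments("quercetin")  # 1,3A- at 151, 1,4B- at 179
#' @export
rda_fragments <- function(aglycone, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (is.character(aglycone)) {
    lib <- aglycone_library()
    if (!aglycone %in% names(lib)) stop("unknown aglycone: ", sQuote(aglycone))
    aglycone <- lib[[aglycone]]
  }
  M <- nominal_mass(aglycone$formula)
  charge <- if (polarity == "negative") -1L else +1L
  ion_nominal <- M + charge

  empty <- data.frame(label = character(0), mz = integer(0),
                      complement_neutral = integer(0), stringsAsFactors = FALSE)
  if (is.null(aglycone$rda_a13)) {
    attr(empty, "reason") <-
      paste0("no RDA partition defined for subclass ", sQuote(aglycone$subclass))
    return(empty)
  }
  a13 <- parse_formula(aglycone$rda_a13)
  nomA <- nominal_mass(a13)
  suffix <- if (polarity == "negative") "-" else "+"

  out <- data.frame(
    label = paste0(c("1,3A", "1,3B"), suffix),
    mz = c(nomA + charge, (M - nomA) + charge),
    complement_neutral = c(M - nomA, nomA),
    stringsAsFactors = FALSE)

  if (identical(aglycone$subclass, "flavonol")) {
    a14 <- formula_diff(a13, "CH2O")
    nomA14 <- nominal_mass(a14)
    out <- rbind(out, data.frame(
      label = paste0("1,4B", suffix),
      mz = (M - nomA14) + charge,
      complement_neutral = nomA14, stringsAsFactors = FALSE))
  }
  stopifnot(all(out$mz + out$complement_neutral == ion_nominal))
  out
}

#' Score aglycone candidates against observed fragment m/z
#'
#' Each library aglycone is scored by the fraction of its diagnostic
#' fragments observed within `tol`; aglycones with an empty diagnostic list
#' score 0.
#'
#' @param fragment_mzs Numeric vector of observed fragment m/z.
#' @param polarity Ionization mode (diagnostic lists are negative-mode;
#'   positive-mode matching returns zero scores unless records carry
#'   positive-mode fragments).
#' @param tol Matching tolerance in Da (default 0.5).
#' @param library List of aglycone records, default [aglycone_library()].
#' @return A data.frame with columns `aglycone`, `score` (in [0,1]),
#'   `n_matched`, `n_diagnostic`, sorted by decreasing score then name.
#' @export
match_aglycone <- function(fragment_mzs, polarity = "negative", tol = 0.5,
                           library = aglycone_library()) {
  if (!length(library)) stop("empty aglycone library")
  rows <- lapply(library, function(a) {
    diag <- unlist(a$diagnostic_fragments)
    if (!length(diag) || !identical(polarity, "negative")) {
      matched <- 0L
    } else {
      matched <- sum(vapply(diag, function(d)
        any(abs(fragment_mzs - d) <= tol), logical(1)))
    }
    data.frame(aglycone = a$name,
               score = if (length(diag)) matched / length(diag) else 0,
               n_matched = as.integer(matched),
               n_diagnostic = length(diag), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$aglycone), , drop = FALSE]
  rownames(res) <- NULL
  res
}
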