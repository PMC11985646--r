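# Ground-truthed synthetic data for every pipeline stage: MS2 spectra by
# forward application of the fragmentation rules, GC peak tables, and
# microplate absorbance data. All randomness flows from the single seed in
# the noise config; each generator derives its own sub-stream by adding a
# fixed offset to that seed, so stages are reproducible independently.

#' Noise configuration for the synthetic generators
#'
#' @param precursor_ppm_sigma SD of the Gaussian relative error applied to
#'   precursor m/z, in ppm.
#' @param fragment_da_sigma SD of the Gaussian jitter applied to fragment
#'   m/z, in Da.
#' @param decoys_per_spectrum Number of uniform decoy peaks added per
#'   spectrum.
#' @param plate_sigma_pct Coefficient of variation of well absorbance, in
#'   percent (the proportional error model typical of plate readers).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(precursor_ppm_sigma = 5, fragment_da_sigma = 0.3,
                         decoys_per_spectrum = 3, plate_sigma_pct = 5,
                         seed = 1L) {
  stopifnot(precursor_ppm_sigma >= 0, fragment_da_sigma >= 0,
            decoys_per_spectrum >= 0, plate_sigma_pct >= 0)
  structure(list(precursor_ppm_sigma = precursor_ppm_sigma,
                 fragment_da_sigma = fragment_da_sigma,
                 decoys_per_spectrum = as.integer(decoys_per_spectrum),
                 plate_sigma_pct = plate_sigma_pct,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Zero-noise configuration
#'
#' @param seed Integer seed (still fixes compound sampling).
#' @return A `noise_config` with all sigmas and decoy counts at zero.
#' @export
noiseless_config <- function(seed = 1L) {
  noise_config(0, 0, 0, 0, seed)
}

# theoretical fragment peaks for a compound entry (forward rules):
# residue-loss ladder at exact masses, cross-ring cleavages for C-linked
# sugars, aglycone diagnostics and RDA products at nominal m/z
.true_peaks <- function(entry, polarity, rules = neutral_loss_rules(),
                        agly = aglycone_library()) {
  adduct <- adduct_for_polarity(polarity)
  prec <- adduct_mz(entry$formula, adduct)
  mz <- numeric(0); int <- numeric(0)
  dec <- entry$decorations
  if (length(dec)) {
    cum <- cumsum(rules$exact[match(dec, rules$name)])
    mz <- c(mz, prec - cum); int <- c(int, rep(100, length(cum)))
  }
  if (identical(entry$linkage, "C")) {
    outer <- if (length(dec) > 1)
      sum(rules$exact[match(dec[-length(dec)], rules$name)]) else 0
    cr <- rules$exact[match(c("cross-ring-90", "cross-ring-120"), rules$name)]
    mz <- c(mz, prec - outer - cr); int <- c(int, c(90, 90))
  }
  if (!is.null(entry$aglycone)) {
    a <- agly[[entry$aglycone]]
    if (identical(polarity, "negative")) {
      d <- unlist(a$diagnostic_fragments)
      if (length(d)) { mz <- c(mz, d); int <- c(int, rep(80, length(d))) }
    }
    rda <- rda_fragments(a, polarity)
    if (nrow(rda)) { mz <- c(mz, rda$mz); int <- c(int, rep(80, nrow(rda))) }
  }
  keep <- !duplicated(round(mz, 6)) & mz > 0
  list(precursor = prec, mz = mz[keep], intensity = int[keep])
}

#' Generate synthetic MS2 features with known identities
#'
#' Samples compounds from the library and builds each spectrum by forward
#' application of the fragmentation rules: the residue-loss ladder down to
#' the aglycone ion, cross-ring products for C-glycosides, and the
#' aglycone's diagnostic and RDA fragments. Gaussian ppm noise perturbs the
#' precursor, Gaussian Da jitter the fragments; decoy peaks are drawn
#' uniformly over [50, precursor - 5] Da at lower intensity, redrawn until
#' at least 1 Da away from every true fragment so they never collide with a
#' rule mass.
#'
#' @param lib Compound library; defaults to the shipped library restricted
#'   to entries with an aglycone record (the flavonoid surface the
#'   annotator is scored on).
#' @param n Number of features to generate.
#' @param noise A [noise_config()].
#' @param polarity Ionization mode of the generated spectra.
#' @return A list with `features` (list of [ms2_feature()]) and `truth`
#'   (data.frame `feature_id`, `true_name`).
#' @export
gen_ms2 <- function(lib = NULL, n = 100, noise = noise_config(),
                    polarity = "negative") {
  if (is.null(lib)) {
    lib <- Filter(function(e) !is.null(e$aglycone), compound_library())
  }
  stopifnot(length(lib) > 0, n >= 1)
  set.seed(noise$seed + 101L)
  rules <- neutral_loss_rules()
  agly <- aglycone_library()
  pick <- sample.int(length(lib), n, replace = TRUE)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    e <- lib[[pick[i]]]
    tp <- .true_peaks(e, polarity, rules, agly)
    prec <- tp$precursor *
      (1 + stats::rnorm(1, 0, noise$precursor_ppm_sigma * 1e-6))
    mz <- tp$mz + stats::rnorm(length(tp$mz), 0, noise$fragment_da_sigma)
    int <- tp$intensity
    if (noise$decoys_per_spectrum > 0) {
      for (k in seq_len(noise$decoys_per_spectrum)) {
        repeat {
          d <- stats::runif(1, 50, max(51, tp$precursor - 5))
          if (!length(tp$mz) || min(abs(tp$mz - d)) >= 1) break
        }
        mz <- c(mz, d)
        int <- c(int, stats::runif(1, 10, 40))
      }
    }
    feats[[i]] <- ms2_feature(paste0("S", i), prec, polarity,
                              cbind(mz, int), rt = i / 10)
  }
  list(features = feats,
       truth = data.frame(feature_id = paste0("S", seq_len(n)),
                          true_name = vapply(lib[pick], `[[`, character(1), "name"),
                          stringsAsFactors = FALSE))
}

# built-in GC peak templates; fatty-acid classes are later recovered by
# rule, sterol/other carry the curated category
.gc_templates <- function() {
  rbind(
    data.frame(name = c("Palmitic acid", "Stearic acid",
                        "Palmitic acid, methyl ester", "Stearic acid, methyl ester"),
               formula = c("C16H32O2", "C18H36O2", "C17H34O2", "C19H38O2"),
               class = "saturated", curated_category = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(name = c("Oleic acid", "Linoleic acid, methyl ester",
                        "Oleic acid, methyl ester", "Linoleic acid ethyl ester"),
               formula = c("C18H34O2", "C19H34O2", "C19H36O2", "C20H36O2"),
               class = "unsaturated", curated_category = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(name = c("Stigmasterol", "Stigmastanol", "Sitostenone",
                        "Lupene-3,28-diol/betulin"),
               formula = c("C29H48O", "C29H52O", "C29H48O", "C30H50O2"),
               class = "sterol", curated_category = "sterol",
               stringsAsFactors = FALSE),
    data.frame(name = c("Tocopherol", "Heptatriacotanol", "Tetramethyl-hexadecenol"),
               formula = c("C29H50O2", "C37H76O", "C20H40O"),
               class = "other", curated_category = "other",
               stringsAsFactors = FALSE))
}

#' Generate a synthetic GC peak table with known class composition
#'
#' Draws peaks from fatty-acid, sterol and long-chain alcohol/tocopherol
#' templates and assigns Dirichlet-distributed area percentages scaled to a
#' configured total, emulating the structure of a lipoidal-matter GC
#' report.
#'
#' @param n Number of peaks, at least 1.
#' @param noise A [noise_config()] (only the seed is used).
#' @param total_pct Total identified area percentage the peaks sum to.
#' @param classes Template classes to draw from (subset of `"saturated"`,
#'   `"unsaturated"`, `"sterol"`, `"other"`).
#' @return A list with `peaks` (data.frame compatible with
#'   [summarize_composition()]) and `truth` (data.frame `name`, `class`).
#' @export
gen_gc_table <- function(n = 19, noise = noise_config(), total_pct = 66.59,
                         classes = c("saturated", "unsaturated", "sterol", "other")) {
  stopifnot(n >= 1, total_pct > 0)
  set.seed(noise$seed + 202L)
  tmpl <- .gc_templates()
  tmpl <- tmpl[tmpl$class %in% classes, , drop = FALSE]
  if (!nrow(tmpl)) stop("no templates for the requested classes")
  pick <- sample.int(nrow(tmpl), n, replace = TRUE)
  # symmetric Dirichlet(1) via normalized gammas
  w <- stats::rgamma(n, shape = 1)
  area <- w / sum(w) * total_pct
  peaks <- data.frame(rt_min = sort(stats::runif(n, 25, 45)),
                      name = tmpl$name[pick], formula = tmpl$formula[pick],
                      area_pct = area,
                      curated_category = tmpl$curated_category[pick],
                      stringsAsFactors = FALSE)
  list(peaks = peaks,
       truth = data.frame(name = tmpl$name[pick], class = tmpl$class[pick],
                          area_pct = area, stringsAsFactors = FALSE))
}

#' Generate synthetic plate absorbances from a 4PL dose-response curve
#'
#' Well absorbances are `control_abs * v(c) / 100` under the true curve,
#' perturbed by proportional Gaussian noise with CV `plate_sigma_pct`
#' (the error model typical of optical-density measurements). Control
#' wells at zero concentration are included and carry the same noise.
#'
#' @param top,bottom,ic50,hill True 4PL parameters (viability scale).
#' @param concentrations Dosed concentrations; default the two-fold series
#'   100 down to 1.5625.
#' @param replicates Wells per concentration (default 3, triplicates).
#' @param noise A [noise_config()].
#' @param control_abs Mean absorbance of untreated wells (AU).
#' @return A data.frame with columns `concentration`, `replicate`,
#'   `absorbance`, `is_control`.
#' @export
gen_plate <- function(top = 100, bottom = 0, ic50 = 1.66, hill = 1,
                      concentrations = serial_dilution(100, 2, 7),
                      replicates = 3, noise = noise_config(),
                      control_abs = 1) {
  stopifnot(ic50 > 0, replicates >= 1, all(concentrations > 0))
  set.seed(noise$seed + 303L)
  cv <- noise$plate_sigma_pct / 100
  conc <- rep(concentrations, each = replicates)
  mu <- control_abs * .fourpl(conc, top, bottom, log10(ic50), hill) / 100
  test <- data.frame(concentration = conc,
                     replicate = rep(seq_len(replicates),
                                     times = length(concentrations)),
                     absorbance = pmax(0, mu * (1 + stats::rnorm(length(mu), 0, cv))),
                     is_control = FALSE)
  ctrl <- data.frame(concentration = 0,
                     replicate = seq_len(replicates),
                     absorbance = pmax(0, control_abs *
                                         (1 + stats::rnorm(replicates, 0, cv))),
                     is_control = TRUE)
  rbind(ctrl, test)
}
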