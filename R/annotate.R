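# MS2 feature annotation: candidate retrieval by formula mass at a ppm
# tolerance, fragment explanation via neutral-loss chains and aglycone
# diagnostics, linkage classification, and ranked reporting.

#' Construct an MS2 feature
#'
#' @param id Feature identifier.
#' @param precursor_mz Precursor m/z (Da), positive.
#' @param polarity `"negative"` or `"positive"`.
#' @param peaks Numeric vector of fragment m/z, or a two-column
#'   matrix/data.frame `(mz, intensity)`. May be empty (MS1-only feature).
#' @param rt Retention time in minutes (carried through, not scored).
#' @return A list of class `ms2_feature` with peaks sorted by m/z.
#' @export
ms2_feature <- function(id, precursor_mz, polarity = c("negative", "positive"),
                        peaks = numeric(0), rt = NA_real_) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0)
  if (is.null(peaks)) peaks <- numeric(0)
  if (is.matrix(peaks)) peaks <- as.data.frame(peaks)
  if (is.data.frame(peaks)) {
    pk <- data.frame(mz = as.numeric(peaks[[1]]), intensity = as.numeric(peaks[[2]]))
  } else {
    pk <- data.frame(mz = as.numeric(peaks),
                     intensity = rep(NA_real_, length(peaks)))
  }
  pk <- pk[order(pk$mz), , drop = FALSE]
  rownames(pk) <- NULL
  if (!is.na(rt) && rt < 0) stop("rt must be non-negative")
  structure(list(id = as.character(id), rt = rt, precursor_mz = precursor_mz,
                 polarity = polarity, peaks = pk),
            class = "ms2_feature")
}

#' @export
print.ms2_feature <- function(x, ...) {
  cat("<ms2_feature> ", x$id, "  m/z ", sprintf("%.4f", x$precursor_mz),
      " (", x$polarity, "), ", nrow(x$peaks), " fragment(s)",
      if (!is.na(x$rt)) sprintf(", Rt %.2f min", x$rt), "\n", sep = "")
  invisible(x)
}

#' Annotation configuration
#'
#' @param ppm_tol Precursor formula tolerance in ppm (default 20).
#' @param frag_tol Fragment matching tolerance in Da (default 0.5,
#'   appropriate for unit-resolution fragment lists).
#' @param max_chain Maximum explanation chain depth (default 3: up to two
#'   sugar/acyl residues plus one small loss).
#' @param w_frag,w_diag Score weights for the explained-peak fraction and
#'   the aglycone diagnostic fraction (defaults 0.7 / 0.3).
#' @param top_k Candidates reported per feature in [annotate_table()].
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(ppm_tol = 20, frag_tol = 0.5, max_chain = 3,
                              w_frag = 0.7, w_diag = 0.3, top_k = 3) {
  stopifnot(ppm_tol >= 0, frag_tol > 0, max_chain >= 1, w_frag >= 0, w_diag >= 0)
  structure(list(ppm_tol = ppm_tol, frag_tol = frag_tol, max_chain = max_chain,
                 w_frag = w_frag, w_diag = w_diag, top_k = top_k),
            class = "annotation_config")
}

#' Compound library for annotation
#'
#' Loads the shipped compound library (flavonoid aglycones and glycosides,
#' phenolic, organic and amino acids, sugars) and resolves aglycone
#' references and decoration residues. The composition invariant --
#' compound formula equals aglycone formula plus decoration residues -- is
#' checked for every entry that declares both.
#'
#' @param path Optional path to an alternative JSON library.
#' @return A list of compound entries.
#' @export
compound_library <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.flavomics_env$compounds)) return(.flavomics_env$compounds)
    path <- system.file("extdata", "compound_library.json", package = "flavomics")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)$compounds
  rules <- neutral_loss_rules()
  agly <- aglycone_library()
  out <- lapply(raw, function(e) {
    e$decorations <- as.character(unlist(e$decorations))
    bad <- setdiff(e$decorations, rules$name)
    if (length(bad)) stop("entry ", e$name, ": unknown residue(s) ",
                          paste(bad, collapse = ", "))
    if (!is.null(e$aglycone)) {
      if (!e$aglycone %in% names(agly)) {
        stop("entry ", e$name, ": unknown aglycone ", sQuote(e$aglycone))
      }
      expect <- parse_formula(agly[[e$aglycone]]$formula)
      for (d in e$decorations) {
        expect <- formula_sum(expect, rules$formula[match(d, rules$name)])
      }
      if (format(expect) != format(parse_formula(e$formula))) {
        stop("entry ", e$name, ": formula does not equal aglycone + residues")
      }
    }
    e
  })
  names(out) <- NULL
  if (cache) .flavomics_env$compounds <- out
  out
}

# expected fragments for one candidate entry: data.frame(mz, explanation).
# Residue losses are computed at exact masses; diagnostic and RDA fragments
# are nominal. Both land within a 0.5 Da window of unit-resolution peaks.
.expected_fragments <- function(entry, polarity, cfg,
                                rules = neutral_loss_rules(),
                                agly = aglycone_library()) {
  adduct <- adduct_for_polarity(polarity)
  prec <- adduct_mz(entry$formula, adduct)
  small <- rules[rules$category == "small", , drop = FALSE]
  exp_mz <- numeric(0); exp_lab <- character(0)
  add <- function(mz, lab) {
    exp_mz <<- c(exp_mz, mz); exp_lab <<- c(exp_lab, lab)
  }

  dec <- entry$decorations
  n_dec <- length(dec)
  cum <- 0
  prefix_ions <- prec     # ions reachable by residue prefixes (incl. precursor)
  prefix_labs <- ""
  if (n_dec) {
    for (k in seq_len(min(n_dec, cfg$max_chain - 1L))) {
      cum <- cum + rules$exact[match(dec[k], rules$name)]
      lab <- paste0("-", paste(dec[seq_len(k)], collapse = "+"))
      add(prec - cum, if (k == n_dec) paste0(lab, " (aglycone ion)") else lab)
      prefix_ions <- c(prefix_ions, prec - cum)
      prefix_labs <- c(prefix_labs, lab)
    }
  }
  # cross-ring cleavages of a C-linked innermost residue, after shedding
  # any outer residues
  if (identical(entry$linkage, "C")) {
    outer <- if (n_dec > 1) sum(rules$exact[match(dec[-n_dec], rules$name)]) else 0
    for (cr in c("cross-ring-90", "cross-ring-120")) {
      add(prec - outer - rules$exact[match(cr, rules$name)],
          paste0("-", if (outer > 0) paste0(paste(dec[-n_dec], collapse = "+"), "+"),
                 cr))
    }
  }
  # one or two small losses appended to the precursor or any prefix ion
  for (i in seq_along(prefix_ions)) {
    for (s1 in seq_len(nrow(small))) {
      add(prefix_ions[i] - small$exact[s1],
          paste0(prefix_labs[i], "-", small$name[s1]))
      for (s2 in s1:nrow(small)) {
        add(prefix_ions[i] - small$exact[s1] - small$exact[s2],
            paste0(prefix_labs[i], "-", small$name[s1], "-", small$name[s2]))
      }
    }
  }
  # aglycone diagnostics and RDA products (nominal)
  if (!is.null(entry$aglycone)) {
    a <- agly[[entry$aglycone]]
    for (d in unlist(a$diagnostic_fragments)) {
      if (identical(polarity, "negative")) {
        add(d, paste0("diagnostic ", d, " (", a$name, ")"))
      }
    }
    rda <- rda_fragments(a, polarity)
    if (nrow(rda)) {
      for (i in seq_len(nrow(rda))) {
        add(rda$mz[i], paste0("RDA ", rda$label[i], " (", a$name, ")"))
      }
    }
  }
  data.frame(mz = exp_mz, explanation = exp_lab, stringsAsFactors = FALSE)
}

#' Annotate one MS2 feature against a compound library
#'
#' Implements the identification procedure: (1) library entries whose
#' theoretical adduct m/z (under the mode's adduct hypothesis) lies within
#' `cfg$ppm_tol` of the precursor are retained; (2) each observed fragment
#' is explained, where possible, by residue-loss chains (up to two
#' sugar/acyl residues plus one or two small losses), cross-ring cleavages
#' for C-glycosides, or aglycone diagnostic/RDA fragments; (3) the
#' glycosidic linkage is classified from the observed losses; (4)
#' candidates are scored as `w_frag * explained-peak fraction + w_diag *
#' aglycone diagnostic fraction` and ranked. Candidates with identical
#' (score, |ppm|) share a rank; retention time is carried through but never
#' scored, so positional isomers tie.
#'
#' @param feature An [ms2_feature()].
#' @param lib Compound library, default [compound_library()].
#' @param cfg Configuration, default [annotation_config()].
#' @return A data.frame of ranked candidates (possibly zero rows) with
#'   columns `feature_id`, `rt`, `candidate`, `formula`, `class`, `adduct`,
#'   `observed_mz`, `theoretical_mz`, `error_ppm`, `linkage`, `score`,
#'   `rank`, `n_peaks`, `n_explained`, `explained_peaks`, `ms1_only`.
#' @examples
#' f <- ms2_feature("x", 463.0918, "negative", c(301, 283, 255, 151))
#' annotate_feature(f)[1, c("candidate", "score")]
#' @export
annotate_feature <- function(feature, lib = compound_library(),
                             cfg = annotation_config()) {
  stopifnot(inherits(feature, "ms2_feature"), length(lib) > 0)
  adduct <- adduct_for_polarity(feature$polarity)
  rules <- neutral_loss_rules()
  agly <- aglycone_library()
  obs <- feature$peaks$mz
  ms1_only <- !length(obs)

  # feature-level linkage from observed precursor->fragment losses
  lmatches <- do.call(rbind, lapply(obs, function(p)
    loss_candidates(feature$precursor_mz, p, tol = cfg$frag_tol, rules = rules)))
  linkage <- switch(classify_linkage(lmatches),
                    C_glycoside = "C", O_glycoside = "O", none = "none")

  rows <- list()
  for (e in lib) {
    th <- adduct_mz(e$formula, adduct)
    err <- ppm_error(feature$precursor_mz, th)
    if (abs(err) > cfg$ppm_tol) next
    expf <- .expected_fragments(e, feature$polarity, cfg, rules, agly)
    if (length(obs) && nrow(expf)) {
      hit <- vapply(obs, function(p) {
        i <- which(abs(expf$mz - p) <= cfg$frag_tol)
        if (length(i)) i[which.min(abs(expf$mz[i] - p))] else NA_integer_
      }, integer(1))
    } else {
      hit <- rep(NA_integer_, length(obs))
    }
    n_exp <- sum(!is.na(hit))
    frag_frac <- if (length(obs)) n_exp / length(obs) else 0
    diag_frac <- 0
    if (!is.null(e$aglycone)) {
      a <- agly[[e$aglycone]]
      d <- unlist(a$diagnostic_fragments)
      if (length(d) && identical(feature$polarity, "negative") && length(obs)) {
        diag_frac <- sum(vapply(d, function(x)
          any(abs(obs - x) <= cfg$frag_tol), logical(1))) / length(d)
      }
    }
    expl <- if (n_exp) {
      paste(sprintf("%s=%s", format(obs[!is.na(hit)], trim = TRUE),
                    expf$explanation[hit[!is.na(hit)]]), collapse = "; ")
    } else ""
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = feature$id, rt = feature$rt, candidate = e$name,
      formula = e$formula, class = e$class, adduct = adduct$name,
      observed_mz = feature$precursor_mz, theoretical_mz = th,
      error_ppm = err, linkage = linkage,
      score = cfg$w_frag * frag_frac + cfg$w_diag * diag_frac,
      n_peaks = length(obs), n_explained = n_exp,
      explained_peaks = expl, ms1_only = ms1_only, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(feature_id = character(0), rt = numeric(0),
                      candidate = character(0), formula = character(0),
                      class = character(0), adduct = character(0),
                      observed_mz = numeric(0), theoretical_mz = numeric(0),
                      error_ppm = numeric(0), linkage = character(0),
                      score = numeric(0), rank = integer(0),
                      n_peaks = integer(0), n_explained = integer(0),
                      explained_peaks = character(0), ms1_only = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, abs(res$error_ppm), res$candidate), , drop = FALSE]
  key <- paste(signif(res$score, 12), signif(abs(res$error_ppm), 12))
  res$rank <- match(key, unique(key))
  rownames(res) <- NULL
  res[, c("feature_id", "rt", "candidate", "formula", "class", "adduct",
          "observed_mz", "theoretical_mz", "error_ppm", "linkage", "score",
          "rank", "n_peaks", "n_explained", "explained_peaks", "ms1_only")]
}

#' Annotate a table of MS2 features
#'
#' Runs [annotate_feature()] on each feature and stacks the top-k
#' candidates per feature. Features with no candidate within tolerance
#' appear as a single row with empty candidate fields, so the report always
#' has one block per input feature.
#'
#' @param features A list of [ms2_feature()] objects.
#' @param lib Compound library, default [compound_library()].
#' @param cfg Configuration, default [annotation_config()].
#' @return A data.frame report.
#' @export
annotate_table <- function(features, lib = compound_library(),
                           cfg = annotation_config()) {
  stopifnot(is.list(features))
  if (!length(features)) {
    empty <- annotate_feature(ms2_feature("none", 1e6, "negative"), lib, cfg)
    return(empty[0, , drop = FALSE])
  }
  blocks <- lapply(features, function(f) {
    res <- annotate_feature(f, lib, cfg)
    if (!nrow(res)) {
      data.frame(feature_id = f$id, rt = f$rt, candidate = NA_character_,
                 formula = NA_character_, class = NA_character_,
                 adduct = adduct_for_polarity(f$polarity)$name,
                 observed_mz = f$precursor_mz, theoretical_mz = NA_real_,
                 error_ppm = NA_real_, linkage = NA_character_,
                 score = NA_real_, rank = NA_integer_,
                 n_peaks = nrow(f$peaks), n_explained = NA_integer_,
                 explained_peaks = "", ms1_only = !nrow(f$peaks),
                 stringsAsFactors = FALSE)
    } else {
      res[res$rank <= cfg$top_k, , drop = FALSE]
    }
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Top-1 recovery of true identities
#'
#' Fraction of features whose true compound appears in the top rank tier of
#' the annotation report (rank 1 is shared by exact score ties, which the
#' annotator reports rather than breaking arbitrarily).
#'
#' @param report A report from [annotate_table()].
#' @param truth Named character vector or data.frame (`feature_id`,
#'   `true_name`) of true identities.
#' @return Proportion in [0, 1].
#' @export
top1_recovery <- function(report, truth) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$true_name, truth$feature_id)
  }
  ids <- unique(report$feature_id)
  hit <- vapply(ids, function(i) {
    top <- report[report$feature_id == i & !is.na(report$rank) &
                    report$rank == 1L, "candidate"]
    isTRUE(truth[[i]] %in% top)
  }, logical(1))
  mean(hit)
}
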