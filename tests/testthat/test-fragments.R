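# Neutral-loss rules, linkage classification, RDA prediction, aglycone match

test_that("the rule set carries the canonical residue losses", {
  r <- neutral_loss_rules()
  want <- c(hexosyl = 162L, deoxyhexosyl = 146L, pentosyl = 132L,
            hexuronyl = 176L, `deoxyhexosyl-hexosyl` = 308L, coumaroyl = 146L,
            water = 18L, CO2 = 44L, CO = 28L, methyl = 15L,
            `cross-ring-120` = 120L, `cross-ring-90` = 90L)
  expect_identical(setNames(r$nominal[match(names(want), r$name)], names(want)),
                   want)
  # nominal losses are consistent with the residue formulas
  for (i in seq_len(nrow(r))) {
    expect_identical(r$nominal[i], nominal_mass(r$formula[i]))
  }
})

test_that("loss_candidates matches single residues and chains", {
  m1 <- loss_candidates(477.0676, 301, 0.5)
  expect_identical(m1$rule[1], "hexuronyl")
  expect_identical(m1$loss[1], 176L)

  m2 <- loss_candidates(609.1324, 301, 0.5)
  expect_true("deoxyhexosyl-hexosyl" %in% m2$rule)
  expect_true("hexosyl+deoxyhexosyl" %in% m2$rule)
  expect_true(all(m2$loss == 308))

  expect_identical(nrow(loss_candidates(301, 301, 0.5)), 0L)
  expect_error(loss_candidates(301, 400, 0.5), "exceeds")
})

test_that("two-residue chains equal the sum of their single rules", {
  r <- neutral_loss_rules()
  m <- loss_candidates(1000, 100, tol = 500) # wide net: collect many chains
  chains <- m[m$category == "chain", , drop = FALSE]
  expect_gt(nrow(chains), 0)
  for (i in seq_len(nrow(chains))) {
    parts <- strsplit(chains$rule[i], "+", fixed = TRUE)[[1]]
    expect_identical(chains$loss[i], sum(r$nominal[match(parts, r$name)]))
  }
})

test_that("exact-level matching uses monoisotopic residue masses", {
  th <- adduct_mz("C21H20O12", "[M-H]-")
  frag <- th - monoisotopic_mass("C6H10O5")
  m <- loss_candidates(th, frag, tol = 0.005, level = "exact")
  expect_identical(m$rule[1], "hexosyl")
  expect_lt(abs(m$delta[1]), 1e-9)
})

test_that("linkage classification follows cross-ring precedence and is order-invariant", {
  cross <- loss_candidates(447.0947, 327, 0.5)   # -120
  sugar <- loss_candidates(447.0947, 285, 0.5)   # -162
  expect_identical(classify_linkage(rbind(cross, sugar)), "C_glycoside")
  expect_identical(classify_linkage(rbind(sugar, cross)), "C_glycoside")
  expect_identical(classify_linkage(sugar), "O_glycoside")
  expect_identical(classify_linkage(NULL), "none")
  expect_identical(classify_linkage(loss_candidates(301, 301, 0.5)), "none")
})

test_that("RDA prediction reproduces the diagnostic masses", {
  q <- rda_fragments("quercetin")
  expect_identical(q$mz[q$label == "1,3A-"], 151L)
  expect_identical(q$mz[q$label == "1,4B-"], 179L)
  n <- rda_fragments("naringenin")
  expect_identical(n$mz[n$label == "1,3B-"], 119L)
  expect_identical(n$mz[n$label == "1,3A-"], 151L)
  a <- rda_fragments("acacetin")
  expect_identical(a$mz[a$label == "1,3B-"], 131L)
  ap <- rda_fragments("apigenin")
  expect_identical(ap$mz[ap$label == "1,3B-"], 117L)
  lu <- rda_fragments("luteolin")
  expect_identical(lu$mz[lu$label == "1,3B-"], 133L)
})

test_that("RDA mass conservation holds across the whole library, both modes", {
  for (a in aglycone_library()) {
    for (pol in c("negative", "positive")) {
      rda <- rda_fragments(a, pol)
      if (!nrow(rda)) {
        expect_match(attr(rda, "reason"), "no RDA partition")
        next
      }
      ion <- nominal_mass(a$formula) + if (pol == "negative") -1L else 1L
      expect_true(all(rda$mz + rda$complement_neutral == ion),
                  info = paste(a$name, pol))
    }
  }
})

test_that("scaffolds without a partition yield an explicit no-prediction result", {
  r <- rda_fragments("okanin")
  expect_identical(nrow(r), 0L)
  expect_match(attr(r, "reason"), "chalcone")
  expect_error(rda_fragments("not-a-compound"), "unknown aglycone")
})

test_that("aglycone matching scores the observed diagnostic fraction", {
  m <- match_aglycone(c(301, 179, 151), "negative")
  expect_true("quercetin" %in% m$aglycone[seq_len(3)])
  expect_true(all(m$score >= 0 & m$score <= 1))

  m0 <- match_aglycone(numeric(0), "negative")
  expect_true(all(m0$score == 0))

  full <- match_aglycone(c(257, 177, 151, 133, 107), "negative")
  expect_identical(full$score[full$aglycone == "luteolin"], 1)
})
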