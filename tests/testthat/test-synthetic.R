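test_that("generation is cell-for-cell deterministic given the seed", {
  cfg <- pairSimConfig(nEast = 12, nWest = 10, seed = 5)
  a <- generatePair(cfg)
  b <- generatePair(cfg)
  expect_identical(featureValues(a$east), featureValues(b$east))
  expect_identical(featureValues(a$west), featureValues(b$west))
  expect_identical(sampleData(a$east), sampleData(b$east))
  c <- generatePair(pairSimConfig(nEast = 12, nWest = 10, seed = 6))
  expect_false(identical(featureValues(a$east), featureValues(c$east)))
})

test_that("generated tables respect the schema and mirror the study structure", {
  cfg <- pairSimConfig(nEast = 30, nWest = 25, seed = 2)
  p <- generatePair(cfg)
  expect_s4_class(p$east, "SongFeatureTable")
  expect_equal(dim(p$east), c(30L, 20L))   # default 20-feature plan
  expect_equal(dim(p$west), c(25L, 20L))
  expect_equal(featureCodes(p$east), featureCodes(p$west))
  # schema validity: validation report runs clean on every generated table
  for (tab in p) {
    rep <- validateFeatureTable(tab)
    expect_false(any(rep$all_missing))
    expect_true(validObject(tab))
  }
  # localities are present and fall in the two range regions
  expect_true(all(!is.na(sampleData(p$east)$latitude)))
  expect_lt(mean(sampleData(p$west)$longitude),
            mean(sampleData(p$east)$longitude))
})

test_that("missingness is structural: an absent syllable blanks all its codes", {
  cfg <- pairSimConfig(nEast = 40, nWest = 40,
                       syllablePresence = c(a = 1, b = 1, c = 0.5, d = 0.5),
                       seed = 9)
  p <- generatePair(cfg)
  v <- featureValues(p$east)
  cCodes <- grep("c$", featureCodes(p$east), value = TRUE)
  missC <- is.na(v[, cCodes])
  # each individual is either complete or fully blank on syllable c
  expect_true(all(rowSums(missC) %in% c(0L, length(cCodes))))
  # the song-level syllable count tracks the number of present syllables
  present <- 2 + (!is.na(v[["1c"]])) + (!is.na(v[["1d"]]))
  expect_equal(v[["7"]], as.numeric(present))
})

test_that("requested effect sizes separate the taxa in the requested direction", {
  cfg <- pairSimConfig(nEast = 60, nWest = 60, effectShift = 2, seed = 3,
                       syllablePresence = c(a = 1, b = 1, c = 1, d = 1))
  p <- generatePair(cfg)
  for (code in c("2a", "4b", "1c")) {
    e <- featureValues(p$east)[[code]]
    w <- featureValues(p$west)[[code]]
    g <- hedgesG(w, e)
    expect_gt(g, 1)   # 2-sd shift, so g well above 1
  }
  # unshifted song-scoped feature stays put
  expect_lt(abs(hedgesG(featureValues(p$west)[["1"]],
                        featureValues(p$east)[["1"]])), 0.6)
})

test_that("injectLocalVariant shifts only the selected rows and flags them", {
  cfg <- pairSimConfig(nEast = 20, nWest = 4, seed = 7,
                       syllablePresence = c(a = 1, b = 1, c = 1, d = 1))
  tab <- generatePair(cfg)$east
  shifted <- injectLocalVariant(tab, fraction = 0.25, featureCode = "4b",
                                shiftSd = 3, seed = 10)
  flag <- sampleData(shifted)$variant
  expect_equal(sum(flag), 5L)
  v0 <- featureValues(tab); v1 <- featureValues(shifted)
  expect_equal(v1[["4b"]][!flag], v0[["4b"]][!flag])
  expect_true(all(v1[["4b"]][flag] > v0[["4b"]][flag]))
  expect_equal(v1[["2a"]], v0[["2a"]])
  # zero shift changes nothing but the flags
  null <- injectLocalVariant(tab, fraction = 0.25, featureCode = "4b",
                             shiftSd = 0, seed = 10)
  expect_equal(featureValues(null), featureValues(tab))
  expect_equal(sampleData(null)$variant, flag)
  expect_error(injectLocalVariant(tab, featureCode = "8a"), "numeric")
  # region-box selection uses the locality metadata
  s <- sampleData(tab)
  box <- c(min(s$latitude), median(s$latitude), -180, 0)
  byBox <- injectLocalVariant(tab, featureCode = "4b", shiftSd = 1,
                              regionBox = box)
  expect_equal(sampleData(byBox)$variant, s$latitude <= median(s$latitude))
})

test_that("divergence tables honour their span and correlation modes", {
  mono <- generateDivergenceTable(9, "monotone", seed = 1)
  expect_equal(correlateDivergence(mono)$rho, 1)
  expect_true(all(mono$mtdna_relative_time >= 0.005 &
                    mono$mtdna_relative_time <= 0.021))
  expect_true(all(mono$delta_p >= 70 & mono$delta_p <= 190))
  # independent mode: |rho| behaves like the null sampling distribution
  rhos <- vapply(1:200, function(s)
    correlateDivergence(generateDivergenceTable(9, "independent",
                                                seed = s))$rho, 0)
  expect_lt(abs(mean(rhos)), 0.1)
  expect_gt(mean(abs(rhos)), 0.1)   # not degenerate at zero
  expect_lt(mean(abs(rhos)), 0.5)
  expect_error(generateDivergenceTable(2), "at least 3")
})

test_that("the variant screening scenario produces its documented structure", {
  sc <- variantScreenScenario(seed = 3)
  expect_equal(nrow(featureValues(sc$table)), 32L)
  expect_equal(sum(sampleData(sc$table)$variant), 8L)
  expect_false("8a" %in% featureCodes(sc$table))
  expect_setequal(sc$injectedCodes, c("1c", "2c", "3c", "4c"))
  expect_equal(sc$regions,
               ifelse(sampleData(sc$table)$variant, "variant", "dominant"))
  # the null control draws flags but shifts nothing
  null <- variantScreenScenario(seed = 3, shiftSd = 0)
  v <- featureValues(null$table)
  expect_false(identical(v, featureValues(sc$table)))
  expect_equal(v[["1a"]], featureValues(sc$table)[["1a"]])
})
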