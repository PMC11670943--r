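## Synthetic song-feature generator.  Emulates the structure of manual
## spectrogram measurements of oscine song: per-recording tables of
## durations (s), frequencies (Hz), counts and one categorical slur
## variable, keyed by measurement codes; an east and a west taxon drawn
## from a shared plan with configurable per-feature location shifts; and
## structural block missingness, where an individual whose song lacks a
## syllable lacks every measurement of that syllable.

#' Configuration for simulating an east/west taxon pair
#'
#' Defaults follow mid-range study conditions: 50 individuals per taxon
#' and a 20-feature plan over four syllables (whole-song duration and
#' syllable count, slur of syllable a, repeat count of syllable a, and
#' duration/peak/min/max frequency of syllables a-d).  Syllables c and d
#' are present in only part of each population, producing the uneven,
#' block-missing tables the downstream methods must tolerate.
#'
#' @param nEast,nWest individuals per taxon (study range roughly 25-75).
#' @param syllables syllable letters in the plan.
#' @param syllablePresence named per-syllable presence probability; an
#'   absent syllable blanks all of its measurements for that individual.
#' @param effectShift named numeric vector of east-to-west location
#'   shifts in within-population standard-deviation units, names being
#'   measurement codes (unnamed scalar: applied to every numeric
#'   syllable-scoped feature).
#' @param cellMissingRate additional cell-wise missing-completely-at-
#'   random rate on syllable-scoped cells (default 0; structural
#'   missingness only).
#' @param eastCentroid,westCentroid lat/lon centroids of the two
#'   breeding ranges; localities are drawn around them with
#'   \code{localitySd} degrees of spread.
#' @param localitySd standard deviation (degrees) of locality draws.
#' @param seed integer seed; one seed fans out into per-feature
#'   substreams so adding features does not shift other draws.
#' @return A validated config list of class \code{pairSimConfig}.
#' @export
pairSimConfig <- function(nEast = 50L, nWest = 50L,
                          syllables = c("a", "b", "c", "d"),
                          syllablePresence = c(a = 1, b = 1, c = 0.85,
                                               d = 0.7),
                          effectShift = 0,
                          cellMissingRate = 0,
                          eastCentroid = c(lat = 44, lon = -75),
                          westCentroid = c(lat = 46, lon = -120),
                          localitySd = 2.5,
                          seed = 1L) {
  stopifnot(nEast >= 2L, nWest >= 2L, length(syllables) >= 1L,
            all(syllables %in% letters[1:8]),
            all(syllablePresence >= 0 & syllablePresence <= 1),
            cellMissingRate >= 0 && cellMissingRate < 1,
            localitySd > 0)
  if (is.null(names(syllablePresence)))
    names(syllablePresence) <- syllables
  miss <- setdiff(syllables, names(syllablePresence))
  syllablePresence[miss] <- 1
  plan <- .defaultFeaturePlan(syllables)
  if (nrow(plan) == 0L) stop("infeasible config: empty feature plan")
  structure(list(nEast = as.integer(nEast), nWest = as.integer(nWest),
                 syllables = syllables,
                 syllablePresence = syllablePresence,
                 plan = plan,
                 effectShift = effectShift,
                 cellMissingRate = cellMissingRate,
                 eastCentroid = eastCentroid, westCentroid = westCentroid,
                 localitySd = localitySd, seed = as.integer(seed)),
            class = "pairSimConfig")
}

## Feature plan: code + base-distribution parameters per feature.
## Durations are log-normal (syllable median ~0.25 s, song ~2 s),
## frequencies normal in the passerine band (2-9 kHz), counts Poisson,
## slur Bernoulli over {U, D}.
.defaultFeaturePlan <- function(syllables) {
  rows <- list(
    data.frame(code = "1", dist = "lnorm", p1 = log(2), p2 = 0.30),
    data.frame(code = "7", dist = "n_syllables", p1 = NA, p2 = NA),
    data.frame(code = paste0("8", syllables[1L]), dist = "slur",
               p1 = 0.5, p2 = NA),
    data.frame(code = paste0("5", syllables[1L]), dist = "pois",
               p1 = 4, p2 = NA))
  freqMeans <- c(3000, 5200, 4100, 6800, 2600, 7500, 3500, 5900)
  for (i in seq_along(syllables)) {
    s <- syllables[i]
    fm <- freqMeans[(i - 1L) %% length(freqMeans) + 1L]
    rows <- c(rows, list(
      data.frame(code = paste0("1", s), dist = "lnorm",
                 p1 = log(0.25), p2 = 0.35),
      data.frame(code = paste0("2", s), dist = "norm", p1 = fm, p2 = 450),
      data.frame(code = paste0("3", s), dist = "norm", p1 = fm - 900,
                 p2 = 350),
      data.frame(code = paste0("4", s), dist = "norm", p1 = fm + 1100,
                 p2 = 500)))
  }
  do.call(rbind, rows)
}

.planSd <- function(dist, p1, p2) {
  switch(dist,
         lnorm = sqrt((exp(p2^2) - 1) * exp(2 * p1 + p2^2)),
         norm = p2,
         pois = sqrt(p1),
         NA_real_)
}

.drawFeature <- function(dist, p1, p2, n) {
  switch(dist,
         lnorm = stats::rlnorm(n, p1, p2),
         norm = stats::rnorm(n, p1, p2),
         pois = as.numeric(stats::rpois(n, p1)),
         slur = sample(slurLevels(), n, replace = TRUE,
                       prob = c(p1, 1 - p1)),
         stop("unknown distribution ", dist))
}

#' Generate an east/west pair of song feature tables
#'
#' Draws both taxa from the config's shared feature plan.  The effect
#' model is a location shift applied to the west taxon, expressed in
#' within-population standard deviations of each feature, so both taxa
#' share one random stream per feature and a larger shift moves the west
#' values monotonically.  Structural missingness blanks every
#' measurement of a syllable an individual's song lacks, and the
#' whole-song syllable count (code 7) equals the number of syllables
#' actually present.
#'
#' @param config a \code{\link{pairSimConfig}}.
#' @return List with \code{east} and \code{west}
#'   \code{SongFeatureTable}s.
#' @export
generatePair <- function(config) {
  stopifnot(inherits(config, "pairSimConfig"))
  plan <- config$plan
  nE <- config$nEast; nW <- config$nWest; n <- nE + nW
  streams <- .substreams(config$seed,
                         c(paste0("feature_", plan$code),
                           "presence", "mcar", "locality"))
  ## per-individual syllable presence (block missingness pattern)
  pres <- .withSeed(streams[["presence"]], {
    sapply(config$syllables, function(s)
      stats::runif(n) < config$syllablePresence[[s]])
  })
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = n)
  colnames(pres) <- config$syllables
  ## guarantee analysable tables: every song keeps its first syllable
  pres[, 1L] <- TRUE

  shift <- config$effectShift
  if (is.null(names(shift)) && length(shift) == 1L) {
    sylCodes <- plan$code[grepl("[a-h]", plan$code) & plan$dist != "slur"]
    shift <- stats::setNames(rep(shift, length(sylCodes)), sylCodes)
  }

  vals <- list()
  for (f in seq_len(nrow(plan))) {
    code <- plan$code[f]; dist <- plan$dist[f]
    if (dist == "n_syllables") {
      vals[[code]] <- as.numeric(rowSums(pres))
      next
    }
    x <- .withSeed(streams[[paste0("feature_", code)]],
                   .drawFeature(dist, plan$p1[f], plan$p2[f], n))
    sh <- if (code %in% names(shift)) shift[[code]] else 0
    if (sh != 0 && dist != "slur") {
      delta <- sh * .planSd(dist, plan$p1[f], plan$p2[f])
      idxW <- (nE + 1L):n
      if (dist == "pois") {
        x[idxW] <- pmax(x[idxW] + round(delta), 0)
      } else {
        x[idxW] <- x[idxW] + delta
        if (dist == "lnorm") x <- pmax(x, 1e-3)   # durations stay positive
      }
    }
    ## structural missingness: blank codes of absent syllables
    syl <- sub("^[1-9]([a-h]?).*$", "\\1", code)
    if (nzchar(syl)) x[!pres[, syl]] <- NA
    vals[[code]] <- x
  }

  if (config$cellMissingRate > 0) {
    vals <- .withSeed(streams[["mcar"]], {
      for (f in seq_len(nrow(plan))) {
        code <- plan$code[f]
        if (grepl("[a-h]", code)) {
          drop <- stats::runif(n) < config$cellMissingRate
          vals[[code]][drop] <- NA
        }
      }
      vals
    })
  }

  loc <- .withSeed(streams[["locality"]], {
    cen <- rbind(matrix(config$eastCentroid, nE, 2, byrow = TRUE),
                 matrix(config$westCentroid, nW, 2, byrow = TRUE))
    cen + matrix(stats::rnorm(2 * n, 0, config$localitySd), n, 2)
  })

  df <- as.data.frame(vals, check.names = FALSE)
  taxon <- rep(c("east", "west"), c(nE, nW))
  ids <- c(sprintf("E%03d", seq_len(nE)), sprintf("W%03d", seq_len(nW)))
  pooled <- SongFeatureTable(df, taxon = taxon,
                             latitude = loc[, 1L], longitude = loc[, 2L],
                             ids = ids)
  list(east = pooled[seq_len(nE), ], west = pooled[nE + seq_len(nW), ])
}

#' Inject a localised within-taxon variant
#'
#' Emulates a local song variant: a subset of individuals (those inside
#' \code{regionBox}, or a random fraction when no localities are
#' available) get a location shift on one or more numeric features,
#' expressed in standard deviations of each feature's observed values.
#' The affected rows are flagged in \code{sampleData(x)$variant} so
#' recovery can be scored.
#'
#' @param x a \code{SongFeatureTable}.
#' @param fraction fraction of individuals to shift when selecting at
#'   random (0 < fraction < 1).
#' @param featureCode numeric measurement code(s) to shift.
#' @param shiftSd shift size(s) in feature-sd units, recycled over
#'   \code{featureCode}.
#' @param regionBox optional \code{c(latMin, latMax, lonMin, lonMax)}
#'   selecting individuals by locality instead of at random.
#' @param seed seed for the random selection.
#' @return The modified \code{SongFeatureTable} with a logical
#'   \code{variant} metadata column.
#' @export
injectLocalVariant <- function(x, fraction = 0.25, featureCode,
                               shiftSd = 4, regionBox = NULL, seed = 1L) {
  d <- descriptors(x)
  featureCode <- as.character(featureCode)
  bad <- setdiff(featureCode, d$code)
  if (length(bad)) stop("unknown feature code(s): ",
                        paste(bad, collapse = ", "))
  if (any(d$dtype[match(featureCode, d$code)] != "numeric"))
    stop("can only shift numeric features")
  shiftSd <- rep_len(shiftSd, length(featureCode))
  n <- nrow(featureValues(x))
  s <- sampleData(x)
  if (!is.null(regionBox)) {
    if (all(is.na(s$latitude)) || all(is.na(s$longitude)))
      stop("regionBox selection requires latitude/longitude metadata")
    sel <- !is.na(s$latitude) & !is.na(s$longitude) &
      s$latitude >= regionBox[1L] & s$latitude <= regionBox[2L] &
      s$longitude >= regionBox[3L] & s$longitude <= regionBox[4L]
  } else {
    if (fraction <= 0 || fraction >= 1)
      stop("fraction must lie strictly between 0 and 1")
    k <- max(1L, round(fraction * n))
    sel <- logical(n)
    sel[.withSeed(seed, sample.int(n, k))] <- TRUE
  }
  v <- x@values
  for (i in seq_along(featureCode)) {
    code <- featureCode[i]
    col <- v[[code]]
    sdObs <- stats::sd(col, na.rm = TRUE)
    col[sel] <- col[sel] + shiftSd[i] * sdObs
    v[[code]] <- col
  }
  out <- x
  out@values <- v
  out@sampleData$variant <- sel
  out
}

#' Generate a synthetic divergence table
#'
#' Draws per-pair Delta-p scores in the empirically observed span of
#' divergence scores (about 70-190) and relative mtDNA divergence times
#' in [0.005, 0.021].  \code{"monotone"} mode makes Delta-p a strictly
#' increasing function of time (Spearman rho = 1); \code{"independent"}
#' draws the two columns independently.
#'
#' @param nPairs number of pairs (>= 3).
#' @param correlationMode \code{"independent"} or \code{"monotone"}.
#' @param seed integer seed.
#' @return data.frame with \code{pair_id}, \code{delta_p},
#'   \code{mtdna_relative_time}.
#' @export
generateDivergenceTable <- function(nPairs,
                                    correlationMode = c("independent",
                                                        "monotone"),
                                    seed = 1L) {
  correlationMode <- match.arg(correlationMode)
  if (nPairs < 3L) stop("need at least 3 pairs")
  .withSeed(seed, {
    times <- stats::runif(nPairs, 0.005, 0.021)
    dp <- if (correlationMode == "monotone")
      70 + 120 * (rank(times) - 1) / (nPairs - 1)
    else stats::runif(nPairs, 70, 190)
    data.frame(pair_id = sprintf("pair%02d", seq_len(nPairs)),
               delta_p = dp, mtdna_relative_time = times)
  })
}

#' Localised-variant screening scenario
#'
#' A ready-made within-taxon screening scenario emulating a localised
#' song variant: a taxon of 32 individuals singing a two-syllable song
#' (9 numeric features once the constant syllable count is set aside;
#' both syllables present in every song, as in a single song type), in
#' which a quarter of the individuals sing a variant whose syllable c
#' differs in all four of its measurements (duration and the three
#' frequencies) by \code{shiftSd} within-population standard deviations
#' each; the focal contrast is the maximum frequency of syllable c
#' (code \code{"4c"}).  With \code{shiftSd = 0} the taxon is a
#' homogeneous control (flags drawn, nothing shifted).
#'
#' @param seed integer seed.
#' @param shiftSd shift applied to each syllable-c measurement, in
#'   feature-sd units (default 4; 0 gives the null control).
#' @param n number of individuals (default 32).
#' @param fraction fraction of individuals singing the variant.
#' @return List with the injected \code{table}, the \code{regions}
#'   labels (\code{"variant"}/\code{"dominant"}, the scenario's
#'   geographic surrogate), and \code{injectedCodes}.
#' @export
variantScreenScenario <- function(seed, shiftSd = 4, n = 32L,
                                  fraction = 0.25) {
  cfg <- pairSimConfig(nEast = n, nWest = 2L, syllables = c("a", "c"),
                       syllablePresence = c(a = 1, c = 1), seed = seed)
  tab <- suppressMessages(generatePair(cfg))$east
  tab <- tab[, setdiff(featureCodes(tab), "8a")]   # song type has no slur
  codes <- c("4c", "1c", "2c", "3c")
  tab <- injectLocalVariant(tab, fraction = fraction, featureCode = codes,
                            shiftSd = rep(shiftSd, length(codes)),
                            seed = seed + 10000L)
  list(table = tab,
       regions = ifelse(sampleData(tab)$variant, "variant", "dominant"),
       injectedCodes = codes)
}
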