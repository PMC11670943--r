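# Independent oracles and fixture builders shared across the suite.
# Every oracle is a literal, brute-force evaluation of the defining
# formula, kept free of the package's own computational paths.

# Random mixed-type feature table with optional cell-wise missingness.
# Codes follow the measurement grammar: numeric quantities 1-4 over
# syllables, a count code, and optionally one categorical slur code.
randomMixedTable <- function(n, nNumeric = 4, withSlur = TRUE,
                             missFrac = 0, seed = 1) {
  set.seed(seed)
  syl <- rep(letters[1:8], each = 4)
  qty <- rep(1:4, times = 8)
  codes <- paste0(qty, syl)[seq_len(nNumeric)]
  vals <- lapply(seq_len(nNumeric), function(j)
    round(runif(n, 0, 10^runif(1, 0, 3)), 3))
  names(vals) <- codes
  if (withSlur)
    vals[["8a"]] <- sample(c("U", "D"), n, replace = TRUE)
  df <- as.data.frame(vals, check.names = FALSE)
  if (missFrac > 0) {
    for (j in seq_len(ncol(df))) {
      drop <- runif(n) < missFrac
      if (sum(!drop) < 2) drop[seq_len(2)] <- FALSE  # keep columns usable
      df[[j]][drop] <- NA
    }
  }
  SongFeatureTable(df, taxon = rep(c("east", "west"), length.out = n))
}

# Literal double-loop Gower evaluation over a SongFeatureTable.
gowerOracle <- function(tab) {
  v <- featureValues(tab)
  d <- descriptors(tab)
  n <- nrow(v)
  ranges <- vapply(seq_len(ncol(v)), function(j) {
    if (d$dtype[j] != "numeric") return(NA_real_)
    obs <- v[[j]][!is.na(v[[j]])]
    if (!length(obs)) NA_real_ else max(obs) - min(obs)
  }, 0)
  m <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    num <- 0; den <- 0
    for (j in seq_len(ncol(v))) {
      xi <- v[i, j]; xk <- v[k, j]
      if (is.na(xi) || is.na(xk)) next
      if (d$dtype[j] == "numeric") {
        if (!is.na(ranges[j]) && ranges[j] > 0) {
          num <- num + abs(xi - xk) / ranges[j]; den <- den + 1
        }
      } else { num <- num + (xi != xk); den <- den + 1 }
    }
    m[i, k] <- if (den == 0) NA_real_ else num / den
  }
  m
}

# Exhaustive k-medoids optimum: minimal total cost over all medoid sets.
pamBruteCost <- function(m, k) {
  n <- nrow(m)
  best <- Inf
  sets <- utils::combn(n, k)
  for (c in seq_len(ncol(sets))) {
    cost <- sum(apply(m[, sets[, c], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# Literal silhouette formula.
silhouetteOracle <- function(m, cl) {
  n <- nrow(m)
  ks <- sort(unique(cl))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl[i]
    same <- which(cl == own & seq_len(n) != i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(m[i, same])
    b <- min(vapply(setdiff(ks, own),
                    function(g) mean(m[i, cl == g]), 0))
    s[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# Well-separated numeric blobs as a feature table (frequency-like codes).
blobTable <- function(nPerBlob, nBlobs, sep = 5, spread = 1, seed = 1) {
  set.seed(seed)
  n <- nPerBlob * nBlobs
  centers <- seq_len(nBlobs) * sep * spread * 10
  vals <- lapply(1:4, function(j) {
    ctr <- rep(centers, each = nPerBlob) * j
    1000 + abs(ctr + rnorm(n, 0, spread * 10))
  })
  names(vals) <- paste0(1:4, "a")
  SongFeatureTable(as.data.frame(vals, check.names = FALSE),
                   taxon = rep("east", n))
}
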