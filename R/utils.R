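## Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Reflect out-of-range indices back into [1, n] (symmetric padding: the edge
# sample is duplicated, i.e. index 0 -> 1, -1 -> 2, n+1 -> n). Valid as long
# as the overhang does not exceed n, which callers assert.
reflectIndex <- function(i, n) {
  j <- as.integer(i)
  below <- j < 1L
  j[below] <- 1L - j[below]
  above <- j > n
  j[above] <- 2L * n + 1L - j[above]
  j
}

# Median with a deterministic even-count rule: the lower of the two middle
# order statistics. Coincides with the usual sample median for odd counts.
lowerMedian <- function(x) {
  n <- length(x)
  sort.int(x, method = "quick")[ceiling(n / 2)]
}

# Canonical modality ordering used whenever modalities are stacked as channels.
MODALITY_ORDER <- c("T1", "T1CE", "T2", "FLAIR", "UNKNOWN")

orderModalities <- function(names) {
  names[order(match(names, MODALITY_ORDER))]
}

isWholeNumber <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# Linear (column-major) index of coordinate rows into a grid of dims `dm`.
coordsToLinear <- function(coords, dm) {
  lin <- coords[, 1L]
  mult <- 1
  for (ax in seq_along(dm)[-1L]) {
    mult <- mult * dm[ax - 1L]
    lin <- lin + (coords[, ax] - 1L) * mult
  }
  as.integer(lin)
}
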