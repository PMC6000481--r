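# Independent oracles used to cross-check the package implementations.
# They deliberately share no code with the functions they verify.

# Stack-based flood fill; counts connected components of a logical mask.
oracleClusterCount <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  count <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    count <- count + 1L
    stack <- matrix(c(r, c), 1L, 2L)
    lab[r, c] <- count
    while (nrow(stack)) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_along(dr)) {
        rr <- p[1L] + dr[k]; cc <- p[2L] + dc[k]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- count
          stack <- rbind(stack, c(rr, cc))
        }
      }
    }
  }
  count
}

# Brute-force two-way ANOVA ICC(3,1) via lm/anova.
oracleICC31 <- function(m, alpha = 0.05) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  sess = factor(rep(seq_len(k), each = n)))
  a <- anova(lm(y ~ subj + sess, data = d))
  msr <- a["subj", "Mean Sq"]; mse <- a["Residuals", "Mean Sq"]
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  f <- msr / mse
  fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  list(icc = icc, msr = msr, mse = mse,
       ciLow = (fl - 1) / (fl + k - 1), ciHigh = (fu - 1) / (fu + k - 1))
}

# Pixel-by-pixel set statistics by explicit enumeration.
oracleOverlap <- function(a, b) {
  i <- 0L; u <- 0L
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a))) {
    if (a[r, c] && b[r, c]) i <- i + 1L
    if (a[r, c] || b[r, c]) u <- u + 1L
  }
  list(intersection = i, union = u,
       jaccard = if (u > 0) i / u else NA_real_)
}

randomMask <- function(nr, nc, p = 0.2) matrix(runif(nr * nc) < p, nr, nc)

randomVasMatrix <- function(nr, nc, p = 0.2)
  matrix(as.integer(ifelse(runif(nr * nc) < p, sample(1:10, nr * nc,
                                                      replace = TRUE), 0L)),
         nr, nc)

# An outline set whose interior is the full canvas (metrics unrestricted).
fullOutlines <- function(dims = c(24, 16)) {
  masks <- lapply(bodyViews(), function(v) matrix(TRUE, dims[1], dims[2]))
  names(masks) <- bodyViews()
  outlineSet(masks)
}

# One-symptom drawing from per-view intensity matrices (missing views blank).
drawingFromMats <- function(mats, outlines, patientId = "P1",
                            session = "test") {
  d <- makeBlankDrawing(outlines, patientId, session)
  dims <- outlineDims(outlines)
  maps <- lapply(bodyViews(), function(v)
    if (!is.null(mats[[v]])) symptomMap(v, mats[[v]]) else blankMap(v, dims))
  names(maps) <- bodyViews()
  addSymptom(d, symptomSpec("burning"), maps)
}

smallSimParams <- function(...) {
  defaults <- list(nPatients = 5, dims = c(64, 64),
                   clustersMean = 3, clustersSD = 3,
                   blobRadiusMeanlog = log(5), blobRadiusSdlog = 0.3,
                   seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(simParams, args)
}
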