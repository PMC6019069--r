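# independent brute-force oracles and small fixture builders

# class-grouped matrix by explicit double loop over class pairs
oracleGroupMatrix <- function(m, classes) {
  lev <- unique(classes)
  g <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (a in lev) for (b in lev)
    g[a, b] <- sum(m[classes == a, classes == b, drop = FALSE])
  g
}

# exhaustive <=2-hop path enumeration from src-set to tgt-set cells
oraclePaths <- function(m, classes, srcClasses, tgtClasses, minSyn = 1) {
  ids <- rownames(m)
  src <- which(classes %in% srcClasses)
  tgt <- which(classes %in% tgtClasses)
  mid <- setdiff(seq_along(ids), union(src, tgt))
  out <- character(0)
  for (i in src) for (j in tgt)
    if (m[i, j] >= minSyn) out <- c(out, paste(ids[i], ids[j], sep = ">"))
  for (i in src) for (k in mid) for (j in tgt)
    if (m[i, k] >= minSyn && m[k, j] >= minSyn)
      out <- c(out, paste(ids[i], ids[k], ids[j], sep = ">"))
  sort(out)
}

pathKeys <- function(paths) {
  if (!nrow(paths)) return(character(0))
  sort(ifelse(is.na(paths$via), paste(paths$from, paths$to, sep = ">"),
              paste(paths$from, paths$via, paths$to, sep = ">")))
}

# textbook per-pixel Pearson correlation loop
oracleCorrelationMap <- function(arr, seed) {
  d <- dim(arr)
  out <- matrix(0, d[2], d[3])
  ms <- mean(seed)
  for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    v <- arr[, r, c]
    sv <- sum((v - mean(v))^2)
    ss <- sum((seed - ms)^2)
    if (sv == 0 || ss == 0) { out[r, c] <- 0; next }
    out[r, c] <- sum((v - mean(v)) * (seed - ms)) / sqrt(sv * ss)
  }
  out
}

# random annotated synapse matrix over the controlled vocabulary
randomSynapseMatrix <- function(n, classes = NULL, maxCount = 5) {
  ids <- sprintf("cell_%02d", seq_len(n))
  if (is.null(classes))
    classes <- sample(cellClassVocabulary(), n, replace = TRUE)
  m <- matrix(sample(0:maxCount, n * n, replace = TRUE), n, n,
              dimnames = list(ids, ids))
  diag(m) <- 0L
  SynapseMatrix(m, data.frame(cell_id = ids, name = ids,
                              cell_class = classes, side = "unknown",
                              stringsAsFactors = FALSE))
}

# straight-line larvae in separate x lanes (non-crossing, trackable)
laneTrajectories <- function(nLarvae = 20, duration = 30, spacing_mm = 8,
                             arenaHeight = 160, seed = 9) {
  withr::with_seed(seed, {
    times <- seq(0, duration, 1)
    s <- do.call(rbind, lapply(seq_len(nLarvae), function(i) {
      z0 <- runif(1, 30, arenaHeight - 30)
      v <- runif(1, -0.5, 0.5)
      data.frame(larva_id = sprintf("gt_%02d", i), t_s = times,
                 x_mm = spacing_mm * i,
                 z_mm = pmin(pmax(z0 + v * times, 0), arenaHeight),
                 stringsAsFactors = FALSE)
    }))
    TrajectorySet(s, arenaHeight)
  })
}

# long-format 405/488 trace table from a pair of simulated movies
movieTraceTable <- function(sim405, sim488, baselineFrames = 1:24) {
  do.call(rbind, lapply(list(sim405, sim488), function(s) {
    mv <- s$movie
    w <- stimulusTable(mv)$wavelength_nm
    do.call(rbind, lapply(seq_len(nrow(s$truth)), function(i) {
      ci <- s$truth[i, ]
      roi <- circleROI(ci$row, ci$col, 2 * ci$radius_px,
                       dim(movieFrames(mv))[2:3])
      d <- computeDff(extractTrace(mv, roi), baselineFrames = baselineFrames,
                      frameInterval_s = frameInterval(mv), label = ci$cell)
      data.frame(cell = ci$cell, wavelength_nm = w, time_s = d$time_s,
                 dff = d$dff, stringsAsFactors = FALSE)
    }))
  }))
}
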