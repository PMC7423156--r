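# Independent brute-force streamline oracle: a plain scalar reimplementation
# of the documented propagation and RNG protocol (one substream per
# streamline drawn from a master generator; three uniforms for the start
# offset, then three per step).  Used to check the vectorized tracker's
# retention decisions by replaying the identical random stream.

oracleCanonical <- function(v) {
  s <- if (abs(v[1]) > 1e-12) sign(v[1]) else if (abs(v[2]) > 1e-12) sign(v[2]) else sign(v[3])
  if (s == 0) s <- 1
  v * s
}

oraclePerp <- function(d) {
  a <- if (abs(d[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3], d[1] * a[2] - d[2] * a[1])
  e1 <- e1 / sqrt(sum(e1 * e1))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3], d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

oracleTractography <- function(protocol, field) {
  params <- protocol@params
  dimg <- field@dim
  stepVox <- params@stepLength / field@voxelSize
  disp <- field@dispersionDeg * pi / 180
  lin <- function(v) v[1] + (v[2] - 1) * dimg[1] + (v[3] - 1) * dimg[1] * dimg[2]
  wp <- lapply(protocol@waypointMasks, as.vector)
  ex <- lapply(protocol@exclusionMasks, as.vector)
  tm <- as.vector(protocol@terminationMask)
  seedIdx <- sort(which(as.vector(protocol@seedMask)))
  nPer <- params@nSamples
  N <- length(seedIdx) * nPer
  set.seed(params@seed)
  streamSeeds <- sample.int(2147483646L, N)

  status <- character(N)
  wayHit <- matrix(FALSE, N, max(1L, length(wp)))
  visits <- vector("list", N)

  j <- 0L
  for (sv in seedIdx) {
    corner <- c((sv - 1) %% dimg[1], ((sv - 1) %/% dimg[1]) %% dimg[2],
                (sv - 1) %/% (dimg[1] * dimg[2]))
    for (s in seq_len(nPer)) {
      j <- j + 1L
      sgn <- if (s %% 2L == 1L) 1 else -1
      set.seed(streamSeeds[j])
      pos <- corner + runif(3)
      dir <- NULL
      vis <- integer(0)
      vox <- floor(pos) + 1
      li <- lin(vox)
      vis <- c(vis, li)
      st <- ""
      excluded <- FALSE
      for (e in ex) if (e[li]) { st <- "excluded"; excluded <- TRUE }
      for (w in seq_along(wp)) if (wp[[w]][li]) wayHit[j, w] <- TRUE
      if (!excluded && length(tm) && tm[li]) st <- "terminated"
      if (st == "") {
        for (step in seq_len(params@maxSteps)) {
          u <- runif(3)
          vox <- floor(pos) + 1
          li <- lin(vox)
          if (field@isotropic[li]) {
            ct <- 2 * u[2] - 1
            stq <- sqrt(max(0, 1 - ct^2))
            phi <- 2 * pi * u[3]
            cand <- oracleCanonical(c(stq * cos(phi), stq * sin(phi), ct))
          } else {
            o <- field@orientations[li, 1L, ]
            if (disp > 0) {
              uu <- min(max(u[2], 1e-12), 1 - 1e-12)
              theta <- abs(qnorm(uu)) * disp
              phi <- 2 * pi * u[3]
              pb <- oraclePerp(o)
              o <- cos(theta) * o + sin(theta) * (cos(phi) * pb$e1 + sin(phi) * pb$e2)
              o <- oracleCanonical(o)
            }
            cand <- o
          }
          if (is.null(dir)) {
            cand <- cand * sgn
          } else {
            if (sum(cand * dir) < 0) cand <- -cand
            if (sum(cand * dir) < params@curvatureThreshold) { st <- "curvature"; break }
          }
          pos2 <- pos + stepVox * cand
          vox2 <- floor(pos2) + 1
          if (any(vox2 < 1) || any(vox2 > dimg)) { st <- "exit"; break }
          li2 <- lin(vox2)
          vis <- c(vis, li2)
          pos <- pos2; dir <- cand
          hitEx <- FALSE
          for (e in ex) if (e[li2]) { st <- "excluded"; hitEx <- TRUE }
          for (w in seq_along(wp)) if (wp[[w]][li2]) wayHit[j, w] <- TRUE
          if (hitEx) break
          if (length(tm) && tm[li2]) { st <- "terminated"; break }
        }
        if (st == "") st <- "max_steps"
      }
      status[j] <- st
      visits[[j]] <- unique(vis)
    }
  }
  retained <- status != "excluded"
  if (length(wp)) retained <- retained & rowSums(wayHit[, seq_along(wp), drop = FALSE]) > 0
  counts <- numeric(prod(dimg))
  for (jj in which(retained)) counts[visits[[jj]]] <- counts[visits[[jj]]] + 1
  list(status = status, wayHit = wayHit, retained = retained,
       counts = array(counts, dimg), visits = visits)
}
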