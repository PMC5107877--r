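# Independent brute-force oracles used across the suite. These deliberately
# re-implement the contracts in the most literal way possible (explicit
# loops and queues) so they share no code with the package internals.

# Erosion: a voxel survives iff the translated kernel (anchor floor(d/2))
# fits entirely inside the mask; out of bounds counts as background.
bruteErode <- function(m, kern) {
  d <- dim(m)
  offs <- expand.grid(dz = seq_len(kern[1]) - 1 - kern[1] %/% 2,
                      dy = seq_len(kern[2]) - 1 - kern[2] %/% 2,
                      dx = seq_len(kern[3]) - 1 - kern[3] %/% 2)
  out <- array(FALSE, d)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
    kk <- k + offs$dz; jj <- j + offs$dy; ii <- i + offs$dx
    inb <- kk >= 1 & kk <= d[1] & jj >= 1 & jj <= d[2] & ii >= 1 & ii <= d[3]
    out[k, j, i] <- all(inb) && all(m[cbind(kk, jj, ii)])
  }
  out
}

# Statistical region growing: literal BFS with explicit queues, phase 1
# (per-seed neighbourhood statistics, absorption rule) and phase 2
# (region-statistics refinement passes, each expanded to closure).
bruteGrow <- function(volArr, maskArr, seedMat, v, nIter = 5L, minStd = 1) {
  d <- dim(volArr)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbStats <- function(s) {
    vals <- c()
    for (r in seq_len(nrow(offs) + 1)) {
      p <- if (r == 1) s else s + offs[r - 1, ]
      if (all(p >= 1) && all(p <= d))
        vals <- c(vals, volArr[p[1], p[2], p[3]])
    }
    mu <- mean(vals)
    list(m = mu, s = max(sqrt(mean((vals - mu)^2)), minStd))
  }
  bfs <- function(startList, admissible) {
    vis <- array(FALSE, d)
    q <- list()
    for (s in startList)
      if (admissible[s[1], s[2], s[3]] && !vis[s[1], s[2], s[3]]) {
        vis[s[1], s[2], s[3]] <- TRUE
        q[[length(q) + 1]] <- s
      }
    while (length(q) > 0) {
      cur <- q[[1]]; q <- q[-1]
      for (r in seq_len(nrow(offs))) {
        p <- cur + offs[r, ]
        if (all(p >= 1) && all(p <= d) && !vis[p[1], p[2], p[3]] &&
            admissible[p[1], p[2], p[3]]) {
          vis[p[1], p[2], p[3]] <- TRUE
          q[[length(q) + 1]] <- p
        }
      }
    }
    vis
  }
  region <- array(FALSE, d)
  for (si in seq_len(nrow(seedMat))) {
    s <- seedMat[si, ]
    if (region[s[1], s[2], s[3]]) next
    st <- nbStats(s)
    adm <- maskArr & volArr >= st$m - v * st$s & volArr <= st$m + v * st$s
    region <- region | bfs(list(s), adm)
  }
  for (it in seq_len(nIter)) {
    if (!any(region)) break
    vals <- volArr[region]
    mu <- mean(vals)
    sd_ <- max(sqrt(mean((vals - mu)^2)), minStd)
    adm <- region | (maskArr & volArr >= mu - v * sd_ & volArr <= mu + v * sd_)
    starts <- which(region, arr.ind = TRUE)
    grown <- bfs(lapply(seq_len(nrow(starts)), function(r) starts[r, ]), adm)
    if (sum(grown) == sum(region)) break
    region <- grown
  }
  region
}

# Surface distances: exhaustive O(n^2) pairwise nearest distances between
# surface voxel centres (surface = 6-neighbour definition), pooled both
# directions.
bruteSurfaceDistances <- function(maskA, maskB, spacing) {
  surf <- function(m) {
    d <- dim(m)
    keep <- matrix(0, 0, 3)
    for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3])) {
      if (!m[k, j, i]) next
      nb <- rbind(c(k - 1, j, i), c(k + 1, j, i), c(k, j - 1, i),
                  c(k, j + 1, i), c(k, j, i - 1), c(k, j, i + 1))
      onSurf <- FALSE
      for (r in 1:6) {
        p <- nb[r, ]
        if (any(p < 1) || any(p > d) || !m[p[1], p[2], p[3]]) onSurf <- TRUE
      }
      if (onSurf) keep <- rbind(keep, c(k, j, i))
    }
    keep
  }
  world <- function(co)
    cbind((co[, 3] - 1) * spacing[3], (co[, 2] - 1) * spacing[2],
          (co[, 1] - 1) * spacing[1])
  wa <- world(surf(maskA))
  wb <- world(surf(maskB))
  nn <- function(a, b)
    apply(a, 1, function(p) sqrt(min(colSums((t(b) - p)^2))))
  pooled <- c(nn(wa, wb), nn(wb, wa))
  c(msd = mean(pooled), maxsd = max(pooled))
}

# Central finite differences of a smoothed array along world-mm axes;
# oracle for the analytic Gaussian-derivative Hessian components. `stride`
# sets the step (in voxels) so Richardson extrapolation can cancel the
# leading truncation term.
fdSecondDeriv <- function(a, spacing, ax1, ax2, stride = 1L) {
  sh <- function(arr, s) {
    d <- dim(arr)
    out <- array(NA_real_, d)
    dst <- src <- vector("list", 3)
    for (x in 1:3) {
      if (s[x] >= 0) {
        dst[[x]] <- seq_len(d[x] - s[x])
        src[[x]] <- seq.int(1 + s[x], d[x])
      } else {
        dst[[x]] <- seq.int(1 - s[x], d[x])
        src[[x]] <- seq_len(d[x] + s[x])
      }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  e <- function(ax) { s <- c(0, 0, 0); s[ax] <- stride; s }
  h1 <- spacing[ax1] * stride; h2 <- spacing[ax2] * stride
  if (ax1 == ax2) {
    (sh(a, e(ax1)) - 2 * a + sh(a, -e(ax1))) / h1^2
  } else {
    (sh(a, e(ax1) + e(ax2)) - sh(a, e(ax1) - e(ax2)) -
       sh(a, -e(ax1) + e(ax2)) + sh(a, -e(ax1) - e(ax2))) / (4 * h1 * h2)
  }
}

# Small deterministic test mask helper.
randomMask <- function(d, p = 0.6, seed = 1) {
  set.seed(seed)
  array(runif(prod(d)) < p, d)
}
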