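# Independent oracles, deliberately naive: exhaustive least-squares
# change-point search, quadratic overlap scans, BFS connected components,
# a hand-rolled UPGMA, and a choose()-based Fisher enumeration. None of
# these share code with the implementation paths they check.

# Best k-breakpoint segmentation of x by exhaustive least-squares search
# (k <= 2), minimum segment length m. Returns breakpoint indices (last
# probe of each left segment).
oracle_changepoints <- function(x, k, m) {
  n <- length(x)
  sse <- function(i, j) {
    v <- x[i:j]
    sum((v - mean(v))^2)
  }
  if (k == 0L) return(integer())
  if (k == 1L) {
    best <- integer(); bv <- Inf
    for (b in m:(n - m)) {
      v <- sse(1, b) + sse(b + 1, n)
      if (v < bv - 1e-12) { bv <- v; best <- b }
    }
    return(best)
  }
  best <- integer(); bv <- Inf
  for (b1 in m:(n - 2 * m)) {
    for (b2 in (b1 + m):(n - m)) {
      v <- sse(1, b1) + sse(b1 + 1, b2) + sse(b2 + 1, n)
      if (v < bv - 1e-12) { bv <- v; best <- c(b1, b2) }
    }
  }
  best
}

# Quadratic all-pairs subtraction oracle: progressive call i is removed iff
# any non-progressive call of the same direction overlaps it reciprocally
# at >= min_ro.
oracle_subtract_removed <- function(prog, nonprog, min_ro) {
  removed <- logical(nrow(prog))
  for (i in seq_len(nrow(prog))) {
    for (j in seq_len(nrow(nonprog))) {
      if (prog$direction[i] != nonprog$direction[j]) next
      if (prog$chrom[i] != nonprog$chrom[j]) next
      ov <- max(0, min(prog$end[i], nonprog$end[j]) -
                  max(prog$start[i], nonprog$start[j]))
      ro <- min(ov / (prog$end[i] - prog$start[i]),
                ov / (nonprog$end[j] - nonprog$start[j]))
      if (ro >= min_ro) { removed[i] <- TRUE; break }
    }
  }
  removed
}

# Brute-force single-linkage components over the all-pairs reciprocal-overlap
# matrix (same direction, same chromosome), via BFS.
oracle_components <- function(calls, min_ro) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (calls$direction[i] != calls$direction[j]) next
      if (calls$chrom[i] != calls$chrom[j]) next
      ov <- max(0, min(calls$end[i], calls$end[j]) -
                  max(calls$start[i], calls$start[j]))
      ro <- min(ov / (calls$end[i] - calls$start[i]),
                ov / (calls$end[j] - calls$start[j]))
      if (ro >= min_ro) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Hand-rolled UPGMA returning the cophenetic distance matrix.
oracle_upgma_cophenetic <- function(m) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- c(NA, NA); bv <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        if (d[a, b] < bv - 1e-12) { bv <- d[a, b]; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    for (x in members[[a]]) for (y in members[[b]]) {
      coph[x, y] <- coph[y, x] <- bv
    }
    for (k in setdiff(active, c(a, b))) {
      d[a, k] <- d[k, a] <-
        (sizes[a] * d[a, k] + sizes[b] * d[b, k]) / (sizes[a] + sizes[b])
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  coph
}

# Fisher enumeration from binomial coefficients (point-probability rule).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  po <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(pr[pr <= po * (1 + 1e-9)]))
}
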