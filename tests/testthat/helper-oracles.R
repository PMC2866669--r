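# Brute-force reference implementations used as independent oracles on
# small grids. All arrays use dimension order (z, y, x).

refl <- function(i, n) {
  if (n == 1L) return(1L)
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# per-slice 2D median with reflected edges
oracle_median2d <- function(arr, radius) {
  d <- dim(arr)
  out <- arr
  for (z in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (x in seq_len(d[3])) {
        w <- numeric(0)
        for (dy in -radius:radius)
          for (dx in -radius:radius)
            w <- c(w, arr[z, refl(y + dy, d[2]), refl(x + dx, d[3])])
        out[z, y, x] <- median(w)
      }
  out
}

# per-slice hole filling: background not 4-connected to the border
oracle_fill2d <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[1])) {
    sl <- mask[z, , , drop = TRUE]
    reach <- matrix(FALSE, d[2], d[3])
    stack <- list()
    for (y in seq_len(d[2]))
      for (x in seq_len(d[3]))
        if ((y %in% c(1L, d[2]) || x %in% c(1L, d[3])) && !sl[y, x] && !reach[y, x]) {
          reach[y, x] <- TRUE
          stack[[length(stack) + 1L]] <- c(y, x)
        }
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= d[2] && q[2] >= 1 && q[2] <= d[3] &&
            !sl[q[1], q[2]] && !reach[q[1], q[2]]) {
          reach[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    out[z, , ] <- sl | !reach
  }
  out
}

# all-pairs exact Euclidean distance to the nearest background voxel
oracle_edt <- function(mask, w = c(1, 1, 1)) {
  d <- dim(mask)
  out <- array(0, dim = d)
  fg <- which(mask)
  bg <- which(!mask)
  if (!length(fg)) return(out)
  stopifnot(length(bg) > 0)
  fco <- arrayInd(fg, d)
  bco <- arrayInd(bg, d)
  for (i in seq_along(fg)) {
    dd <- (w[1] * (bco[, 1] - fco[i, 1]))^2 +
          (w[2] * (bco[, 2] - fco[i, 2]))^2 +
          (w[3] * (bco[, 3] - fco[i, 3]))^2
    out[fg[i]] <- sqrt(min(dd))
  }
  out
}

# offsets for a connectivity as a matrix of (dz, dy, dx) rows
conn_offsets <- function(connectivity) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  s <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  maxsum <- c(`6` = 1, `18` = 2, `26` = 3)[[as.character(connectivity)]]
  as.matrix(g[s > 0 & s <= maxsum, ])
}

# grayscale reconstruction by naive iterated geodesic dilation (Jacobi)
oracle_reconstruct <- function(marker, mask) {
  d <- dim(mask)
  off <- conn_offsets(26)
  J <- marker
  idx <- arrayInd(seq_along(J), d)
  repeat {
    dil <- J
    for (k in seq_len(nrow(off))) {
      src <- idx[, 1] - off[k, 1]
      srcy <- idx[, 2] - off[k, 2]
      srcx <- idx[, 3] - off[k, 3]
      ok <- src >= 1 & src <= d[1] & srcy >= 1 & srcy <= d[2] &
            srcx >= 1 & srcx <= d[3]
      v <- rep(-Inf, length(J))
      v[ok] <- J[cbind(src[ok], srcy[ok], srcx[ok])]
      dil <- pmax(dil, v)
    }
    Jn <- pmin(mask, array(dil, dim = d))
    if (all(Jn == J)) break
    J <- Jn
  }
  J
}

# connected labelling by BFS in raster order
oracle_label <- function(vals, connectivity, same_value_only = FALSE) {
  d <- dim(vals)
  off <- conn_offsets(connectivity)
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (x in seq_len(d[3]))
    for (y in seq_len(d[2]))
      for (z in seq_len(d[1])) {
        if (vals[z, y, x] <= 0 || lab[z, y, x] != 0L) next
        nxt <- nxt + 1L
        v0 <- vals[z, y, x]
        queue <- list(c(z, y, x))
        lab[z, y, x] <- nxt
        while (length(queue)) {
          p <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (k in seq_len(nrow(off))) {
            q <- p + off[k, ]
            if (any(q < 1) || any(q > d)) next
            if (lab[q[1], q[2], q[3]] != 0L || vals[q[1], q[2], q[3]] <= 0) next
            if (same_value_only && vals[q[1], q[2], q[3]] != v0) next
            lab[q[1], q[2], q[3]] <- nxt
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
  lab
}

# optimal bottleneck path cost from each seed label to every mask voxel:
# cost = max over the path of (dmax - dist), 6-connected, including both ends
oracle_ws_costs <- function(dist, seeds, mask) {
  d <- dim(mask)
  dmax <- if (any(mask)) max(dist[mask]) else 0
  elev <- dmax - dist
  labels <- sort(setdiff(unique(as.vector(seeds)), 0L))
  off <- conn_offsets(6)
  lapply(labels, function(L) {
    cost <- array(Inf, dim = d)
    cost[seeds == L] <- elev[seeds == L]
    repeat {
      changed <- FALSE
      for (x in seq_len(d[3]))
        for (y in seq_len(d[2]))
          for (z in seq_len(d[1])) {
            if (!mask[z, y, x]) next
            best <- cost[z, y, x]
            for (k in seq_len(nrow(off))) {
              q <- c(z, y, x) + off[k, ]
              if (any(q < 1) || any(q > d)) next
              if (!mask[q[1], q[2], q[3]]) next
              cand <- max(cost[q[1], q[2], q[3]], elev[z, y, x])
              if (cand < best) best <- cand
            }
            if (best < cost[z, y, x]) {
              cost[z, y, x] <- best
              changed <- TRUE
            }
          }
      if (!changed) break
    }
    cost
  })
}

# random binary mask as a binary_grid
rand_mask <- function(dim, p = 0.5) {
  binary_grid(array(runif(prod(dim)) < p, dim = dim))
}

# assert that a watershed labelling is an optimum-path forest w.r.t. the
# oracle costs: every voxel's label attains the minimal cost; unique argmin
# voxels must match exactly; seed voxels keep their own label
expect_watershed_matches_oracle <- function(out, dist, seeds, mask) {
  costs <- oracle_ws_costs(dist, seeds, mask)
  labels <- sort(setdiff(unique(as.vector(seeds)), 0L))
  for (i in which(mask)) {
    cs <- vapply(costs, function(cm) cm[i], numeric(1))
    if (seeds[i] > 0L) {
      expect_identical(out[i], seeds[i])
      next
    }
    if (all(is.infinite(cs))) {
      expect_identical(out[i], 0L)
      next
    }
    argmin <- labels[cs == min(cs)]
    expect_true(out[i] %in% argmin)
    if (length(argmin) == 1L) expect_identical(out[i], argmin)
  }
}
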