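# Independent brute-force oracles. Deliberately written as literal
# enumerations (triple loops, explicit neighbor walks) so they share no code
# path with the implementation they check.

oracle_glcm <- function(levels, G, off) {
  d <- dim(levels)
  M <- matrix(0, G, G)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    a <- levels[x, y, z]
    if (a <= 0) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
      next
    b <- levels[x2, y2, z2]
    if (b <= 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

oracle_glrlm <- function(levels, G, off) {
  d <- dim(levels)
  runs <- list()
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    a <- levels[x, y, z]
    if (a <= 0) next
    xp <- x - off[1]; yp <- y - off[2]; zp <- z - off[3]
    if (xp >= 1 && xp <= d[1] && yp >= 1 && yp <= d[2] && zp >= 1 &&
        zp <= d[3] && levels[xp, yp, zp] == a) next
    r <- 0; xc <- x; yc <- y; zc <- z
    while (xc >= 1 && xc <= d[1] && yc >= 1 && yc <= d[2] && zc >= 1 &&
           zc <= d[3] && levels[xc, yc, zc] == a) {
      r <- r + 1; xc <- xc + off[1]; yc <- yc + off[2]; zc <- zc + off[3]
    }
    runs[[length(runs) + 1]] <- c(a, r)
  }
  rmax <- max(vapply(runs, `[`, numeric(1), 2))
  M <- matrix(0, G, rmax)
  for (rn in runs) M[rn[1], rn[2]] <- M[rn[1], rn[2]] + 1
  M
}

neighbors26 <- function(v, d) {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    p <- v + c(dx, dy, dz)
    if (all(p >= 1) && all(p <= d)) out <- rbind(out, p)
  }
  out
}

oracle_zones <- function(levels) {
  d <- dim(levels)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(levels > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    if (lab[v[1], v[2], v[3]] != 0) next
    nxt <- nxt + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- nxt
    lev <- levels[v[1], v[2], v[3]]
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- neighbors26(cur, d)
      for (r in seq_len(nrow(nb))) {
        p <- nb[r, ]
        if (levels[p[1], p[2], p[3]] == lev && lab[p[1], p[2], p[3]] == 0) {
          lab[p[1], p[2], p[3]] <- nxt
          queue[[length(queue) + 1]] <- p
        }
      }
    }
  }
  lab
}

oracle_size_zone_matrix <- function(levels, G) {
  lab <- oracle_zones(levels)
  if (max(lab) == 0) return(matrix(0, G, 1))
  zl <- integer(max(lab)); zs <- integer(max(lab))
  for (z in seq_len(max(lab))) {
    sel <- lab == z
    zs[z] <- sum(sel)
    zl[z] <- levels[which(sel)[1]]
  }
  M <- matrix(0, G, max(zs))
  for (z in seq_len(max(lab))) M[zl[z], zs[z]] <- M[zl[z], zs[z]] + 1
  M
}

oracle_ngtdm <- function(levels, G) {
  d <- dim(levels)
  n_g <- numeric(G); s_g <- numeric(G)
  idx <- which(levels > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    nb <- neighbors26(v, d)
    vals <- c()
    for (r in seq_len(nrow(nb))) {
      p <- nb[r, ]
      if (levels[p[1], p[2], p[3]] > 0)
        vals <- c(vals, levels[p[1], p[2], p[3]])
    }
    if (length(vals) == 0) next
    a <- levels[v[1], v[2], v[3]]
    n_g[a] <- n_g[a] + 1
    s_g[a] <- s_g[a] + abs(a - mean(vals))
  }
  cbind(n = n_g, s = s_g)
}

oracle_auroc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# literal ReliefF transcription: range-normalized diff, manhattan distance
oracle_relieff <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) max(v) - min(v))
  rng[rng == 0] <- 1
  W <- numeric(p)
  for (i in seq_len(n)) {
    d_i <- numeric(n)
    for (j in seq_len(n))
      d_i[j] <- sum(abs(X[i, ] - X[j, ]) / rng)
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    hits <- hits[order(d_i[hits])][seq_len(min(k, length(hits)))]
    misses <- misses[order(d_i[misses])][seq_len(min(k, length(misses)))]
    for (f in seq_len(p)) {
      dh <- 0
      for (h in hits) dh <- dh + abs(X[i, f] - X[h, f]) / rng[f]
      dm <- 0
      for (m in misses) dm <- dm + abs(X[i, f] - X[m, f]) / rng[f]
      W[f] <- W[f] + dm / length(misses) - dh / length(hits)
    }
  }
  W / n
}

# gliding-box lacunarity by explicit box sweep
oracle_lacunarity <- function(fg, r) {
  w <- which(fg, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  crop <- fg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(crop)
  masses <- c()
  for (z in 1:(d[3] - r + 1)) for (y in 1:(d[2] - r + 1))
    for (x in 1:(d[1] - r + 1))
      masses <- c(masses, sum(crop[x:(x + r - 1), y:(y + r - 1),
                                   z:(z + r - 1)]))
  mean(masses^2) / mean(masses)^2
}

feature_table_from_matrix <- function(X, ids = sprintf("s%03d", seq_len(nrow(X)))) {
  rownames(X) <- ids
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  feature_table(X)
}
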