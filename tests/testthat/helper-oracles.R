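# Definition-level oracles, kept deliberately naive and independent of the
# package's compiled kernels.

# shift a 2D/3D logical array by an offset, padding with FALSE
shift_mask <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", length(d))
  for (a in seq_along(d)) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(d[a] - o); dst[[a]] <- seq_len(d[a] - o) + o }
    else { src[[a]] <- seq_len(d[a] + o) - o; dst[[a]] <- seq_len(d[a] + o) }
    if (length(src[[a]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- if (length(d) == 2)
    m[src[[1]], src[[2]]] else m[src[[1]], src[[2]], src[[3]]]
  out
}

diamond_offsets <- function(n, d) {
  g <- expand.grid(dx = -n:n, dy = -n:n, dz = if (d == 3) -n:n else 0)
  g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) <= n, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) c(g$dx[i], g$dy[i], g$dz[i]))
}

as3d <- function(m) if (length(dim(m)) == 2) array(m, dim = c(dim(m), 1L)) else m

oracle_erode <- function(m, n = 1L) {
  d <- length(dim(m))
  m3 <- as3d(m)
  res <- Reduce(`&`, lapply(diamond_offsets(n, d), function(o) shift_mask(m3, -o)))
  if (d == 2) array(res, dim = dim(m)) else res
}

oracle_dilate <- function(m, n = 1L) {
  d <- length(dim(m))
  m3 <- as3d(m)
  res <- Reduce(`|`, lapply(diamond_offsets(n, d), function(o) shift_mask(m3, o)))
  if (d == 2) array(res, dim = dim(m)) else res
}

oracle_open <- function(m, n) oracle_dilate(oracle_erode(m, n), n)

oracle_pattern_spectrum <- function(m) {
  ps <- numeric(0)
  prev <- sum(m)
  n <- 0L
  while (prev > 0) {
    n <- n + 1L
    op <- oracle_open(m, n)
    ps[as.character(n)] <- prev - sum(op)
    prev <- sum(op)
  }
  ps
}

oracle_mad <- function(gt, seg) {
  x <- xor(gt, seg)
  dim(x) <- dim(gt)
  ps <- oracle_pattern_spectrum(x)
  if (length(ps) == 0 || sum(ps) == 0) return(0)
  sum(as.numeric(names(ps)) * ps) / sum(ps)
}

# area under the polyline {(0,0), (fpr,tpr), (1,1)} by trapezoids
oracle_auc_trapezoid <- function(fpr, tpr) {
  xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

# exhaustive Kapur criterion
oracle_kapur <- function(h) {
  ints <- if (!is.null(names(h))) as.numeric(names(h)) else seq_along(h) - 1
  p <- h / sum(h)
  best <- -Inf; best_t <- NA
  for (t in seq_len(length(h) - 1L)) {
    P1 <- sum(p[1:t]); P2 <- 1 - P1
    if (P1 <= 0 || P2 <= 0) next
    Hb <- 0; Hf <- 0
    for (i in 1:t) if (p[i] > 0) Hb <- Hb - (p[i] / P1) * log(p[i] / P1)
    for (i in (t + 1):length(h)) if (p[i] > 0) Hf <- Hf - (p[i] / P2) * log(p[i] / P2)
    if (Hb + Hf > best + 1e-12) { best <- Hb + Hf; best_t <- ints[t] }
  }
  best_t
}

# naive ordered flooding with the same (relief, insertion order) rule and
# neighbour scan order as the package watershed, implemented with a plain
# vector queue and linear scans
oracle_watershed <- function(relief, markers) {
  d <- dim(relief)
  nx <- d[1]; ny <- d[2]; nz <- if (length(d) == 3) d[3] else 1L
  N <- nx * ny * nz
  lab <- as.integer(markers)
  done <- logical(N)
  cap <- 8L * N
  qv <- numeric(cap); qc <- numeric(cap); qi <- integer(cap); ql <- integer(cap)
  qa <- logical(cap)
  cnt <- 0L
  push <- function(i, l) {
    cnt <<- cnt + 1L
    qv[cnt] <<- relief[i]; qc[cnt] <<- cnt; qi[cnt] <<- i; ql[cnt] <<- l
    qa[cnt] <<- TRUE
  }
  nbrs <- function(i) {
    i0 <- i - 1L
    x <- i0 %% nx; y <- (i0 %/% nx) %% ny; z <- i0 %/% (nx * ny)
    out <- integer(0)
    for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1))) {
      X <- x + o[1]; Y <- y + o[2]; Z <- z + o[3]
      if (X >= 0 && X < nx && Y >= 0 && Y < ny && Z >= 0 && Z < nz)
        out <- c(out, 1L + X + nx * (Y + ny * Z))
    }
    out
  }
  for (i in seq_len(N)) if (lab[i] > 0L) push(i, lab[i])
  while (TRUE) {
    act <- which(qa[seq_len(cnt)])
    if (length(act) == 0) break
    mv <- min(qv[act])
    cand <- act[qv[act] == mv]
    j <- cand[which.min(qc[cand])]
    qa[j] <- FALSE
    i <- qi[j]
    if (done[i]) next
    done[i] <- TRUE
    mylab <- if (lab[i] != 0L) lab[i] else ql[j]
    lab[i] <- mylab
    for (nb in nbrs(i)) if (!done[nb] && lab[nb] == 0L) push(nb, mylab)
  }
  array(lab, dim = d)
}

# naive best-first growth mirroring the documented rule
oracle_grow <- function(vol, seed_xyz, depth, dir) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  lin0 <- (seed_xyz[1] - 1L) + nx * ((seed_xyz[2] - 1L) + ny * (seed_xyz[3] - 1L)) + 1L
  zseed <- seed_xyz[3]
  queued <- logical(length(vol)); done <- logical(length(vol))
  pred <- integer(length(vol)); pred[] <- NA_integer_
  qv <- numeric(0); qc <- numeric(0); qi <- integer(0); qa <- logical(0)
  cnt <- 0L
  push <- function(i) {
    cnt <<- cnt + 1L
    qv[cnt] <<- vol[i]; qc[cnt] <<- cnt; qi[cnt] <<- i; qa[cnt] <<- TRUE
    queued[i] <<- TRUE
  }
  push(lin0)
  stopv <- NA_integer_
  while (any(qa[seq_len(cnt)])) {
    act <- which(qa[seq_len(cnt)])
    mv <- max(qv[act])
    cand <- act[qv[act] == mv]
    j <- cand[which.min(qc[cand])]
    qa[j] <- FALSE
    i <- qi[j]
    if (done[i]) next
    done[i] <- TRUE
    z <- (i - 1L) %/% (nx * ny) + 1L
    if (abs(z - zseed) >= depth) { stopv <- i; break }
    i0 <- i - 1L
    x <- i0 %% nx; y <- (i0 %/% nx) %% ny; zz <- i0 %/% (nx * ny)
    for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1))) {
      X <- x + o[1]; Y <- y + o[2]; Z <- zz + o[3]
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) next
      if (dir > 0 && Z + 1L < zseed) next
      if (dir < 0 && Z + 1L > zseed) next
      nb <- 1L + X + nx * (Y + ny * Z)
      if (!queued[nb]) { pred[nb] <- i; push(nb) }
    }
  }
  path <- integer(0)
  v <- stopv
  while (!is.na(v)) { path <- c(path, v); v <- pred[v] }
  path
}

tiny_phantom <- function(seed = 1L, shape = c(96L, 96L, 72L), ...) {
  generate_phantom(phantom_spec(shape = shape, seed = seed, ...))
}
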