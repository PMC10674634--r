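# Plain-R brute-force reference for the semi-global matching pipeline.
# Written directly from the stage definitions (nested loops, no shared code
# with the package's compiled path) so the fast implementation can be
# checked pixel-for-pixel on small instances.

oracle_cost_volume <- function(left, right, dmin, dmax, block) {
  H <- nrow(left); W <- ncol(left); D <- dmax - dmin + 1
  lo <- -((block - 1) %/% 2); hi <- block %/% 2
  sentinel <- block^2 * 255 + 1
  C <- array(0, dim = c(H, W, D))
  for (di in seq_len(D)) {
    d <- dmin + di - 1
    for (x0 in 0:(W - 1)) {
      if (x0 - d < 0) {
        C[, x0 + 1, di] <- sentinel
        next
      }
      xs <- max(0, x0 + lo):min(W - 1, x0 + hi)
      xs <- xs[xs - d >= 0]
      for (y0 in 0:(H - 1)) {
        ys <- max(0, y0 + lo):min(H - 1, y0 + hi)
        C[y0 + 1, x0 + 1, di] <-
          sum(abs(left[ys + 1, xs + 1, drop = FALSE] -
                  right[ys + 1, xs - d + 1, drop = FALSE]))
      }
    }
  }
  C
}

oracle_texture <- function(left, block) {
  H <- nrow(left); W <- ncol(left)
  lo <- -((block - 1) %/% 2); hi <- block %/% 2
  out <- matrix(0, H, W)
  for (y0 in 0:(H - 1)) {
    ys <- max(0, y0 + lo):min(H - 1, y0 + hi)
    for (x0 in 0:(W - 1)) {
      xs <- max(0, x0 + lo):min(W - 1, x0 + hi)
      v <- as.numeric(left[ys + 1, xs + 1])
      n <- length(v)
      va <- sum(v * v) / n - (sum(v) / n) * (sum(v) / n)
      out[y0 + 1, x0 + 1] <- sqrt(max(va, 0))
    }
  }
  out
}

# directions (dy, dx); the predecessor of p along a path is p - (dy, dx)
oracle_dirs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                     c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))

oracle_path <- function(C, P1, P2, dy, dx) {
  H <- dim(C)[1]; W <- dim(C)[2]; D <- dim(C)[3]
  L <- array(0, dim = dim(C))
  ys <- if (dy >= 0) 0:(H - 1) else (H - 1):0
  xs <- if (dx >= 0) 0:(W - 1) else (W - 1):0
  for (y in ys) for (x in xs) {
    py <- y - dy; px <- x - dx
    if (py < 0 || py >= H || px < 0 || px >= W) {
      L[y + 1, x + 1, ] <- C[y + 1, x + 1, ]
    } else {
      Lp <- L[py + 1, px + 1, ]
      minprev <- min(Lp)
      down <- c(Inf, Lp[-D]) + P1   # from d - 1
      up <- c(Lp[-1], Inf) + P1     # from d + 1
      best <- pmin(Lp, pmin(down, pmin(up, minprev + P2)))
      L[y + 1, x + 1, ] <- C[y + 1, x + 1, ] + best - minprev
    }
  }
  L
}

oracle_aggregate <- function(C, P1, P2, n_paths) {
  A <- array(0, dim = dim(C))
  for (r in seq_len(n_paths)) {
    A <- A + oracle_path(C, P1, P2, oracle_dirs[r, 1], oracle_dirs[r, 2])
  }
  A
}

oracle_wta <- function(A, dmin, uniqueness, subpixel, lr_check) {
  H <- dim(A)[1]; W <- dim(A)[2]; D <- dim(A)[3]
  values <- matrix(NA_real_, H, W)
  valid <- matrix(FALSE, H, W)
  rbest <- NULL
  if (lr_check) {
    rbest <- matrix(NA_integer_, H, W)
    for (y in 1:H) {
      Am <- matrix(A[y, , ], nrow = W, ncol = D)
      for (xr in 0:(W - 1)) {
        dis <- which((xr + dmin + (1:D) - 1) <= W - 1)
        if (!length(dis)) next
        vv <- Am[cbind(xr + dmin + dis, dis)]
        rbest[y, xr + 1] <- dis[which.min(vv)]
      }
    }
  }
  for (y in 1:H) for (x0 in 0:(W - 1)) {
    nfeas <- min(x0 - dmin + 1, D)
    if (nfeas < 1) next
    v <- A[y, x0 + 1, seq_len(nfeas)]
    bd <- which.min(v)
    bc <- v[bd]
    if (uniqueness > 0) {
      others <- setdiff(seq_len(nfeas), (bd - 1):(bd + 1))
      if (any(v[others] * 100 <= bc * (100 + uniqueness))) next
      if (nfeas <= 1) next
    }
    if (lr_check) {
      xr <- x0 - (dmin + bd - 1)
      rb <- rbest[y, xr + 1]
      if (is.na(rb) || abs(rb - bd) > 1) next
    }
    off <- 0
    if (subpixel && bd > 1 && bd < nfeas) {
      cm <- v[bd - 1]; cp <- v[bd + 1]
      denom <- cm + cp - 2 * bc
      if (denom > 0) off <- (cm - cp) / (2 * denom)
    }
    values[y, x0 + 1] <- dmin + (bd - 1) + off
    valid[y, x0 + 1] <- TRUE
  }
  list(values = values, valid = valid)
}

oracle_sgm <- function(left, right, params) {
  dr <- params$disparity_range
  C <- oracle_cost_volume(left, right, dr[1], dr[2], params$block_size)
  A <- oracle_aggregate(C, params$penalty_small, params$penalty_large,
                        params$n_paths)
  sel <- oracle_wta(A, dr[1], params$uniqueness_ratio, params$subpixel,
                    params$do_left_right_check)
  if (params$texture_threshold > 0) {
    weak <- oracle_texture(left, params$block_size) < params$texture_threshold
    sel$values[weak] <- NA_real_
    sel$valid[weak] <- FALSE
  }
  sel
}

# exhaustive minimum-cost path enumeration for a single row and a single
# left-to-right scan: Viterbi ground truth for the path recurrence
oracle_enumerate_row <- function(Crow, P1, P2) {
  n <- nrow(Crow); D <- ncol(Crow)
  trans <- function(a, b) {
    dd <- abs(a - b)
    if (dd == 0) 0 else if (dd == 1) P1 else P2
  }
  seqs <- as.matrix(expand.grid(rep(list(1:D), n)))
  best_end <- rep(Inf, D)
  for (i in seq_len(nrow(seqs))) {
    s <- seqs[i, ]
    cost <- sum(Crow[cbind(1:n, s)])
    if (n > 1) {
      for (j in 2:n) cost <- cost + trans(s[j - 1], s[j])
    }
    dend <- s[n]
    if (cost < best_end[dend]) best_end[dend] <- cost
  }
  best_end
}
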