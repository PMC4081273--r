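# Independent oracles used to cross-check the package implementations.
# They deliberately use different algorithms from the package internals
# (breadth-first flood fill vs union-find; brute-force window scans vs
# separable max filters).

# flood-fill BFS labeling, row-major first-encounter numbering
label_oracle <- function(binary, connectivity = 2L) {
  b <- binary != 0
  nr <- nrow(b); nc <- ncol(b)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 1L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 1L),
         c(1L, -1L), c(1L, 0L), c(1L, 1L))
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!b[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        q <- p + o
        if (q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L && q[2L] <= nc &&
            b[q[1L], q[2L]] && lab[q[1L], q[2L]] == 0L) {
          lab[q[1L], q[2L]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  list(labels = lab, n_labels = nxt)
}

# exhaustive peak detection + greedy suppression, brute force
peak_oracle <- function(v, min_distance) {
  nr <- nrow(v); nc <- ncol(v)
  # window max by explicit (non-separable) offset scan
  mx <- matrix(-Inf, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (dr in -min_distance:min_distance) for (dc in -min_distance:min_distance) {
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
    sh <- matrix(-Inf, nr, nc)
    sh[rok, cok] <- v[rs[rok], cs[cok]]
    mx <- pmax(mx, sh)
  }
  cand <- which(v >= mx)
  strict <- vapply(cand, function(i) {
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    win <- v[max(1L, r - min_distance):min(nr, r + min_distance),
             max(1L, c - min_distance):min(nc, c + min_distance)]
    sum(win == v[i]) == 1L
  }, logical(1))
  cand <- cand[strict]
  r <- (cand - 1L) %% nr + 1L; c <- (cand - 1L) %/% nr + 1L
  val <- v[cand]
  taken_r <- integer(0); taken_c <- integer(0)
  remaining <- order(-val, r, c)
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    remaining <- remaining[-1L]
    if (length(taken_r) == 0L ||
        all((taken_r - r[i])^2 + (taken_c - c[i])^2 > min_distance^2)) {
      taken_r <- c(taken_r, r[i]); taken_c <- c(taken_c, c[i])
    }
  }
  list(rows = taken_r, cols = taken_c)
}

# exhaustive Otsu threshold over the 256 u8 levels
otsu_oracle <- function(values_u8) {
  best_t <- 0L; best_v <- -1
  for (t in 0:254) {
    lo <- values_u8[values_u8 <= t]; hi <- values_u8[values_u8 > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# distance from points to the continuous outline of an axis-aligned
# rectangle given by half-sample edges (r0.5, r1.5) x (c0.5, c1.5)
rect_outline_distance <- function(rows, cols, r_lo, r_hi, c_lo, c_hi) {
  seg <- function(pr, pc, ar, ac, br, bc) {
    t <- pmin(pmax(((pr - ar) * (br - ar) + (pc - ac) * (bc - ac)) /
                     ((br - ar)^2 + (bc - ac)^2), 0), 1)
    sqrt((ar + t * (br - ar) - pr)^2 + (ac + t * (bc - ac) - pc)^2)
  }
  pmin(seg(rows, cols, r_lo, c_lo, r_lo, c_hi),
       seg(rows, cols, r_hi, c_lo, r_hi, c_hi),
       seg(rows, cols, r_lo, c_lo, r_hi, c_lo),
       seg(rows, cols, r_lo, c_hi, r_hi, c_hi))
}

random_projective <- function() {
  m <- diag(3)
  m[1:2, 1:2] <- m[1:2, 1:2] + matrix(stats::runif(4, -0.15, 0.15), 2)
  m[1:2, 3L] <- stats::runif(2, -20, 20)
  m[3L, 1:2] <- stats::runif(2, -2e-4, 2e-4)
  transform_from_matrix(m, "projective")
}

random_transform <- function(kind) {
  switch(kind,
    similarity = transform_similarity(scale = stats::runif(1, 0.5, 2),
                                      rotation = stats::runif(1, -pi, pi),
                                      translation = stats::runif(2, -30, 30)),
    affine = {
      m <- diag(3)
      m[1:2, 1:2] <- matrix(stats::runif(4, -1, 1), 2) + diag(2)
      m[1:2, 3L] <- stats::runif(2, -30, 30)
      transform_from_matrix(m, "affine")
    },
    projective = random_projective())
}

# 70/30 robust-estimation problem with truth known by construction:
# outliers are redrawn until they are genuinely gross (farther than
# 3x the inlier threshold from the true mapping), so the true inlier
# set is well defined
make_ransac_problem <- function(t_true, n_in = 70L, n_out = 30L,
                                threshold = 2) {
  src_in <- cbind(stats::runif(n_in, 0, 100), stats::runif(n_in, 0, 100))
  dst_in <- transform_apply(t_true, src_in)
  src_out <- matrix(0, 0, 2); dst_out <- matrix(0, 0, 2)
  while (nrow(src_out) < n_out) {
    s <- cbind(stats::runif(n_out, 0, 100), stats::runif(n_out, 0, 100))
    d <- cbind(stats::runif(n_out, 0, 100), stats::runif(n_out, 0, 100))
    resid <- sqrt(rowSums((transform_apply(t_true, s) - d)^2))
    keep <- resid > 3 * threshold
    src_out <- rbind(src_out, s[keep, , drop = FALSE])
    dst_out <- rbind(dst_out, d[keep, , drop = FALSE])
  }
  list(src = rbind(src_in, src_out[seq_len(n_out), , drop = FALSE]),
       dst = rbind(dst_in, dst_out[seq_len(n_out), , drop = FALSE]),
       mask = rep(c(TRUE, FALSE), c(n_in, n_out)))
}
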