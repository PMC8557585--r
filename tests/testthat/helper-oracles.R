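# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the implementation under test.

# scalar point-in-polygon by winding of ray crossings, one point at a time
oracle_point_in_polygon <- function(pr, pc, verts) {
  n <- nrow(verts)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    ri <- verts[i, 1]; ci <- verts[i, 2]
    rj <- verts[j, 1]; cj <- verts[j, 2]
    if ((ri > pr) != (rj > pr)) {
      x_cross <- (cj - ci) * (pr - ri) / (rj - ri) + ci
      if (pc < x_cross) inside <- !inside
    }
  }
  inside
}

oracle_rasterize <- function(verts, h, w) {
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      mask[i, j] <- oracle_point_in_polygon(i - 0.5, j - 0.5, verts)
    }
  }
  mask
}

oracle_mean_gray <- function(image, mask) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (mask[i, j]) { tot <- tot + image[i, j]; n <- n + 1 }
    }
  }
  tot / n
}

oracle_area_fraction <- function(image, mask, thr) {
  pos <- 0; n <- 0
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (mask[i, j]) {
        n <- n + 1
        if (image[i, j] >= thr) pos <- pos + 1
      }
    }
  }
  pos / n
}

# intermeans iteration on the raw masked values, run to convergence in
# double precision, then rounded like the implementation
oracle_isodata <- function(values) {
  t_cur <- mean(values)
  repeat {
    lo <- values[values < t_cur]
    hi <- values[values >= t_cur]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < 1e-10) break
    t_cur <- t_new
  }
  t_cur
}

# exact Wilcoxon two-sided p by bitmask enumeration of all subsets of
# size n1 (feasible for n1 + n2 <= ~16)
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  stats <- c()
  for (bits in 0:(2^n - 1)) {
    sel <- which(bitwAnd(bits, 2^(0:(n - 1))) > 0)
    if (length(sel) == n1) stats <- c(stats, sum(r[sel]))
  }
  p_lo <- mean(stats <= w_obs + 1e-9)
  p_hi <- mean(stats >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# exact Spearman two-sided p by full n! enumeration using recursive
# permutation generation on index vectors
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r_obs <- cor(rx, ry)
  n <- length(x)
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rs <- vapply(perm_rec(seq_len(n)), function(p) cor(rx, ry[p]), numeric(1))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# small disjoint node/parenchyma rectangles for scene tests
test_polygons <- function(side = 130, role_node = "node_A") {
  list(node = roi_polygon(rbind(c(10, 10), c(60, 60)), role = role_node),
       par = roi_polygon(rbind(c(10, 70), c(60, 120)),
                         role = "parenchyma_B"))
}

default_smi_spec <- function(node_frac, par_frac, speckle_sd = 0, seed = 1,
                             side = 130) {
  p <- test_polygons(side)
  smi_scene_spec(side, side, p$node, p$par, node_frac, par_frac,
                 vessel_intensity_mean = 200,
                 background_intensity_mean = 20,
                 speckle_sd = speckle_sd, seed = seed)
}
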