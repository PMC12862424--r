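# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force / direct formula) kept separate from the
# package's code paths.

# Monte-Carlo area of a 2D region given by an inside() predicate
mc_area_2d <- function(inside, xlim, ylim, n = 4e5, seed = 99) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    x <- runif(n, xlim[1], xlim[2])
    y <- runif(n, ylim[1], ylim[2])
    mean(inside(x, y)) * diff(xlim) * diff(ylim)
  })
}

# 6-neighbourhood binary erosion (shift-based, tiny grids)
erode6_oracle <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (ax in 1:3) for (dirn in c(-1, 1)) {
    sh <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    rng <- seq_len(d[ax] - 1)
    idx_dst[[ax]] <- if (dirn == 1) rng + 1 else rng
    idx_src[[ax]] <- if (dirn == 1) rng else rng + 1
    sh[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out <- out & sh
  }
  out
}

# connected components by naive label propagation (tiny grids)
components_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(sum(mask))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  repeat {
    changed <- FALSE
    idx <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]
      for (o in seq_len(nrow(offs))) {
        q <- p + as.integer(offs[o, ])
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] &&
            lab[q[1], q[2], q[3]] < lab[p[1], p[2], p[3]]) {
          lab[p[1], p[2], p[3]] <- lab[q[1], q[2], q[3]]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# total-least-squares plane through a point set
plane_lstsq_oracle <- function(pts) {
  ctr <- colMeans(pts)
  v <- svd(sweep(pts, 2, ctr), nu = 0)$v[, 3]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(point = ctr, normal = v)
}

# OLS by explicit normal equations
ols_oracle <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

# ICC(2,1) from aov() mean squares
icc21_aov_oracle <- function(a, b) {
  n <- length(a)
  dat <- data.frame(y = c(a, b),
                    subj = factor(rep(seq_len(n), 2)),
                    meth = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + meth, data = dat))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# noncentral-F upper tail as a Poisson mixture of incomplete betas
ncf_tail_oracle <- function(crit, df1, df2, lambda, jmax = 500) {
  x <- df1 * crit / (df1 * crit + df2)
  sum(vapply(0:jmax, function(j)
    stats::dpois(j, lambda / 2) *
      stats::pbeta(x, df1 / 2 + j, df2 / 2, lower.tail = FALSE),
    numeric(1)))
}

# hand-built footprint_patch for morphometry tests
fake_patch <- function(pts, plane_point = colMeans(pts),
                       plane_normal = c(0, 0, 1),
                       spacing = c(0.1, 0.1, 0.1),
                       region_tag = "deep") {
  structure(list(voxel_indices = NULL, world_points = pts,
                 plane = list(point = plane_point,
                              normal = plane_normal /
                                sqrt(sum(plane_normal^2))),
                 inlier_flags = rep(TRUE, nrow(pts)),
                 source_labels = c(soft = 3L, bone = 2L),
                 region_tag = region_tag, spacing = spacing,
                 connectivity = 26L, inlier_threshold_mm = 0.15,
                 seed = 1L),
            class = "footprint_patch")
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
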