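# Shared fixtures and independent oracles used across test files.

square_xy <- function(s = 1, x0 = 0, y0 = 0) {
  cbind(x = x0 + c(0, s, s, 0), y = y0 + c(0, 0, s, s))
}

# Convex polygon with vertices on a random ellipse at sorted random angles
# (points in angular order on a convex curve always form a convex polygon).
random_convex_polygon <- function(n = 8, r_range = c(5, 50), center = c(0, 0)) {
  a <- runif(1, r_range[1], r_range[2])
  b <- runif(1, r_range[1], r_range[2])
  th <- sort(runif(n, 0, 2 * pi))
  rot <- runif(1, 0, 2 * pi)
  x <- a * cos(th); y <- b * sin(th)
  cbind(x = center[1] + x * cos(rot) - y * sin(rot),
        y = center[2] + x * sin(rot) + y * cos(rot))
}

rotate_xy <- function(xy, theta, about = c(0, 0)) {
  x <- xy[, 1] - about[1]; y <- xy[, 2] - about[2]
  cbind(x = about[1] + x * cos(theta) - y * sin(theta),
        y = about[2] + x * sin(theta) + y * cos(theta))
}

# Monte-Carlo rasterization oracle for polygon area: uniform points in the
# bounding box, even-odd (crossing number) inclusion test, vectorized per edge.
mc_polygon_area <- function(xy, n_samples = 1e6) {
  bx <- range(xy[, 1]); by <- range(xy[, 2])
  px <- runif(n_samples, bx[1], bx[2])
  py <- runif(n_samples, by[1], by[2])
  inside <- rep(FALSE, n_samples)
  nv <- nrow(xy)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mean(inside) * diff(bx) * diff(by)
}

# Brute-force two-sided Mann-Whitney p by full enumeration of all label
# assignments (no ties assumed).
enumerate_mw_p <- function(g0, g1) {
  pooled <- c(g0, g1)
  n1 <- length(g1)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(length(g0) + seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# Transform every geometry of a scene in place.
transform_scene <- function(sc, f) {
  sc$xy <- lapply(sc$xy, f)
  sc
}

# Tiny deterministic 15000x scene: outer square of side s (perimeter 4 s)
# with straight inner traces of a prescribed total length.
membrane_square_scene <- function(id = "m15k", side = 10, inner_total = 40,
                                  n_mito = 1) {
  membranes <- lapply(seq_len(n_mito), function(i) {
    x0 <- (side + 5) * (i - 1)
    list(
      outer = square_xy(side, x0 = x0),
      inner = list(cbind(x = c(x0, x0 + inner_total), y = c(side / 2, side / 2)))
    )
  })
  names(membranes) <- paste0("m", seq_len(n_mito))
  scene(id, 15000, membranes = membranes)
}
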