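# Plain-R reference implementations used as independent oracles for the
# compiled search paths and the breakpoint fit. Deliberately literal:
# nested loops, no vectorised shortcuts beyond per-wavelength arithmetic.

# grid coordinates mirroring the package convention: when the origin is an
# integer multiple of the step, points are exact multiples of the step
oracle_grid_points <- function(lo, hi, step) {
  n <- as.integer(floor((hi - lo) / step + 1e-9)) + 1L
  i0 <- round(lo / step)
  if (abs(lo / step - i0) < 1e-9) (i0 + seq_len(n) - 1) * step
  else lo + (seq_len(n) - 1) * step
}

# tie-break chain of the exhaustive (dn, dz) search: smaller error, then
# smaller |dz|, then smaller |dn|, then lexicographic (dz, dn)
oracle_better <- function(err, dz, dn, berr, bdz, bdn) {
  if (err != berr) return(err < berr)
  if (abs(dz) != abs(bdz)) return(abs(dz) < abs(bdz))
  if (abs(dn) != abs(bdn)) return(abs(dn) < abs(bdn))
  if (dz != bdz) return(dz < bdz)
  dn < bdn
}

# literal double-loop scan over the full (dn, dz) grid
oracle_search_dn_dz <- function(ihat, lambdas, n1, a, b, grid) {
  m <- ihat - 1
  dns <- oracle_grid_points(grid$dn_min, grid$dn_max, grid$dn_step)
  dzs <- oracle_grid_points(grid$dz_min, grid$dz_max, grid$dz_step)
  berr <- Inf; bdz <- 0; bdn <- 0
  for (dz in dzs) {
    k <- 4 * pi * n1 / lambdas
    C <- cos(k * (a + dz)) - cos(k * (b + dz))
    for (dn in dns) {
      e <- 0
      for (l in seq_along(m)) {
        r <- m[l] - dn * C[l]
        e <- e + r * r
      }
      if (oracle_better(e, dz, dn, berr, bdz, bdn)) {
        berr <- e; bdz <- dz; bdn <- dn
      }
    }
  }
  list(delta_n = bdn, delta_z = bdz, residual = berr)
}

# literal double-loop scan over the (thickness, dz) grid. Uses the same
# cosine-addition arithmetic as the compiled scan so that the exact
# symmetry ties C(t, dz) = C(t + 2 dz, -dz) resolve identically; the
# identity itself is pinned against the literal cosine difference in
# test-inversion.R.
oracle_search_wafer <- function(ihat, lambdas, n1, dn, grid) {
  m <- ihat - 1
  ts <- oracle_grid_points(grid$t_min, grid$t_max, grid$t_step)
  dzs <- oracle_grid_points(grid$dz_min, grid$dz_max, grid$dz_step)
  k <- 4 * pi * n1 / lambdas
  berr <- Inf; bdz <- 0; bt <- 0
  for (dz in dzs) {
    cz <- cos(k * dz); sz <- sin(k * dz)
    for (t in ts) {
      ct <- cos(k * t); st <- sin(k * t)
      C <- cz - (ct * cz - st * sz)
      e <- 0
      for (l in seq_along(m)) {
        r <- m[l] - dn * C[l]
        e <- e + r * r
      }
      if (e < berr || (e == berr && (abs(dz) < abs(bdz) ||
          (abs(dz) == abs(bdz) && (t < bt || (t == bt && dz < bdz)))))) {
        berr <- e; bdz <- dz; bt <- t
      }
    }
  }
  list(thickness = bt, delta_z = bdz, residual = berr)
}

# brute-force two-segment piecewise-linear fit: try every breakpoint,
# fit each segment by lm(), keep the first minimal total SSE
oracle_growth_rates <- function(mass, timepoints = seq_along(mass)) {
  n <- length(mass)
  best <- NULL
  for (k in 2:(n - 1L)) {
    sse <- 0
    for (idx in list(1:k, k:n)) {
      f <- stats::lm(mass[idx] ~ timepoints[idx])
      sse <- sse + sum(stats::residuals(f)^2)
    }
    if (is.null(best) || sse < best$sse) best <- list(k = k, sse = sse)
  }
  list(phase1 = (mass[best$k] - mass[1]) / mass[1],
       phase2 = (mass[n] - mass[best$k]) / mass[best$k],
       boundary_index = best$k)
}

# Dice overlap of two boolean masks
dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
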