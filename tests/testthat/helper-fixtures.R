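# Shared fixtures and independent oracles for the test suite.

# small parameter set for desk-scale unit runs
tiny_params <- function(...) {
  model_params(L0 = 100L, gamma = 0.5, seed = 42L, ...)
}

# random valid lattice states for property-style tests
random_state <- function(L = 20L, p_motor = 0.4, max_stack = 3L) {
  motor <- as.integer(runif(L) < p_motor)
  cargo <- ifelse(motor == 1L, sample(0:max_stack, L, replace = TRUE), 0L)
  nucleotide <- sample(NUCLEOTIDE_STATES, L, replace = TRUE)
  lattice_state(L, motor, as.integer(cargo), nucleotide)
}

# Exact stationary per-site motor density of the finite motor-only model
# (hop + Langmuir + open plus-boundary, static lattice) by brute force:
# build the 2^L-state master-equation generator and solve for its null
# vector. Independent of the simulation engine.
exact_motor_density <- function(L, p, omega_a, omega_d) {
  n_states <- 2^L
  occ <- function(s) as.integer(intToBits(s))[seq_len(L)]
  Q <- matrix(0, n_states, n_states)
  for (s in 0:(n_states - 1L)) {
    o <- occ(s)
    for (i in seq_len(L)) {
      if (o[i] == 0L) {                     # attachment
        Q[s + 1L, s + 1L + 2^(i - 1L)] <- Q[s + 1L, s + 1L + 2^(i - 1L)] + omega_a
      } else {
        Q[s + 1L, s + 1L - 2^(i - 1L)] <- Q[s + 1L, s + 1L - 2^(i - 1L)] + omega_d
        if (i < L && o[i + 1L] == 0L) {     # hop towards the plus-end
          s2 <- s - 2^(i - 1L) + 2^i
          Q[s + 1L, s2 + 1L] <- Q[s + 1L, s2 + 1L] + p
        }
        if (i == L)                         # walk off the open plus-boundary
          Q[s + 1L, s + 1L - 2^(i - 1L)] <- Q[s + 1L, s + 1L - 2^(i - 1L)] + p
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  pi_vec <- abs(Re(eigen(t(Q))$vectors[, n_states]))
  pi_vec <- pi_vec / sum(pi_vec)
  vapply(seq_len(L), function(i)
    sum(pi_vec[which(vapply(0:(n_states - 1L),
                            function(s) occ(s)[i] == 1L, logical(1)))]),
    numeric(1))
}

# per-site snapshot density and a batch-means standard error
snapshot_density <- function(series, n_batches = 20L) {
  mat <- t(vapply(series$states, function(st) as.numeric(st$motor),
                  numeric(series$states[[1L]]$length)))
  batches <- split(seq_len(nrow(mat)),
                   cut(seq_len(nrow(mat)), n_batches, labels = FALSE))
  bm <- t(vapply(batches, function(ix) colMeans(mat[ix, , drop = FALSE]),
                 numeric(ncol(mat))))
  list(mean = colMeans(mat),
       se = apply(bm, 2, sd) / sqrt(length(batches)))
}

# mean motor density over the last W sites of each snapshot, with a
# batch-means standard error (robust to growing lattices)
tip_window_density <- function(series, W, n_batches = 20L) {
  vals <- vapply(series$states, function(st)
    mean(st$motor[seq.int(st$length, by = -1L, length.out = W)]), numeric(1))
  batches <- split(vals, cut(seq_along(vals), n_batches, labels = FALSE))
  bm <- vapply(batches, mean, numeric(1))
  list(mean = mean(vals), se = sd(bm) / sqrt(length(bm)))
}

# naive grey-level opening with a ball structuring element (direct R
# implementation, the oracle for the compiled rolling-ball path)
naive_ball_opening <- function(img, radius) {
  ri <- floor(radius)
  offs <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  h <- sqrt(radius^2 - offs$dx^2 - offs$dy^2)
  nr <- nrow(img); nc <- ncol(img)
  morph <- function(im, erode) {
    out <- matrix(if (erode) Inf else -Inf, nr, nc)
    for (k in seq_len(nrow(offs))) {
      xs <- seq_len(nr) + offs$dx[k]
      ys <- seq_len(nc) + offs$dy[k]
      vx <- xs >= 1 & xs <= nr
      vy <- ys >= 1 & ys <= nc
      sub <- im[xs[vx], ys[vy], drop = FALSE] + (if (erode) -h[k] else h[k])
      cur <- out[vx, vy, drop = FALSE]
      out[vx, vy] <- if (erode) pmin(cur, sub) else pmax(cur, sub)
    }
    out
  }
  morph(morph(img, TRUE), FALSE)
}

# triangular test profile used for alignment tests
triangle_profile <- function(n = 60L, peak_at = 30L, width = 12L,
                             pixel_size_um = 0.107) {
  y <- pmax(0, 1 - abs(seq_len(n) - peak_at) / width)
  intensity_profile(y, pixel_size_um)
}
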