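# Independent brute-force oracles and small-session builders used across
# the test files. The oracle code deliberately shares no helpers with the
# package implementation: full correlation matrix via cor(), explicit
# neighbour enumeration, and naive set-expansion region growing.

# Wrap a t x V series matrix (over the voxels of `mask`) as a bold_session.
session_from_series <- function(series, dims, mask = NULL, tr = 2,
                                voxel_size = 3) {
  nt <- nrow(series)
  vox <- if (is.null(mask)) seq_len(prod(dims)) else which(mask)
  stopifnot(ncol(series) == length(vox))
  data <- array(0, dim = c(dims, nt))
  flat <- matrix(0, prod(dims), nt)
  flat[vox, ] <- t(series)
  data <- aperm(array(t(flat), dim = c(nt, dims)), c(2, 3, 4, 1))
  bold_session(data, voxel_size = voxel_size, tr = tr,
               subject_id = "test", session_index = 1L, days_post_onset = 0,
               motion = matrix(0, nt, 6))
}

# All-pairs correlation with constant series treated as uncorrelated.
bf_cor <- function(series) {
  R <- suppressWarnings(cor(series))
  R[is.na(R)] <- 0
  diag(R) <- 1
  R
}

bf_adjacent <- function(c1, c2, neighborhood) {
  d <- abs(c1 - c2)
  if (all(d == 0)) return(FALSE)
  switch(as.character(neighborhood),
         "6" = sum(d) == 1,
         "18" = max(d) <= 1 && sum(d) <= 2,
         "26" = max(d) <= 1)
}

# Brute-force global / short / long FCD over the in-mask voxels.
bf_fcd <- function(series, dims, mask, r_threshold = 0.6, neighborhood = 26) {
  vox <- which(mask)
  V <- length(vox)
  coords <- arrayInd(vox, dims)
  R <- bf_cor(series)
  adj <- matrix(FALSE, V, V)
  for (a in seq_len(V)) for (b in seq_len(V)) {
    adj[a, b] <- bf_adjacent(coords[a, ], coords[b, ], neighborhood)
  }
  global <- integer(V); short <- integer(V)
  for (v in seq_len(V)) {
    conn <- which(R[v, ] > r_threshold & seq_len(V) != v)
    global[v] <- length(conn)
    # naive growth: start from the seed, repeatedly absorb any connected
    # voxel adjacent to the grown set (seed included)
    grown <- v
    repeat {
      add <- conn[!(conn %in% grown) &
                    vapply(conn, function(j) any(adj[j, grown]), TRUE)]
      if (length(add) == 0) break
      grown <- c(grown, add)
    }
    short[v] <- length(grown) - 1L
  }
  list(global = global, short = short, long = global - short, vox = vox)
}

# Random small test session: a few latent-driven voxel groups + noise.
random_small_session <- function(seed, max_dim = 6L, nt = 30L) {
  set.seed(seed)
  dims <- sample(4:max_dim, 3, replace = TRUE)
  n_vox <- prod(dims)
  mask <- array(runif(n_vox) < 0.85, dim = dims)
  if (sum(mask) < 4) mask[seq_len(4)] <- TRUE
  V <- sum(mask)
  n_lat <- sample(1:3, 1)
  L <- matrix(rnorm(nt * n_lat), nt, n_lat)
  assign_lat <- sample(0:n_lat, V, replace = TRUE)
  load <- runif(V, 0.8, 1.5)
  series <- matrix(rnorm(nt * V, sd = 0.4), nt, V)
  for (v in seq_len(V)) {
    if (assign_lat[v] > 0) series[, v] <- series[, v] + load[v] * L[, assign_lat[v]]
  }
  # occasionally a constant series to exercise the degenerate path
  if (runif(1) < 0.2) series[, sample(V, 1)] <- 5
  list(series = series, dims = dims, mask = mask)
}

# Independent REML log-likelihood via dense matrix algebra (no Woodbury).
bf_reml_loglik <- function(X, y, subject, sigma_b2, sigma_e2) {
  n <- length(y)
  Z <- outer(subject, unique(subject), `==`) * 1
  V <- sigma_b2 * tcrossprod(Z) + sigma_e2 * diag(n)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  p <- ncol(X)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
                       t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}

# Small synthetic longitudinal dataset for mixed-model tests.
make_lmm_data <- function(seed, n_subj = 8, days = c(3, 13, 31, 98, 370),
                          u = 1, beta1 = 0.01, beta2 = 0,
                          sigma_b = 0.5, sigma_e = 0.2) {
  set.seed(seed)
  d <- expand.grid(subject = seq_len(n_subj), j = seq_along(days))
  d$x <- days[d$j]
  b <- rnorm(n_subj, sd = sigma_b)
  d$y <- u + b[d$subject] + beta1 * d$x + beta2 * d$x^2 +
    rnorm(nrow(d), sd = sigma_e)
  d
}

# Compact simulation config for unit tests: 12^3 grid, two bilateral
# 27-voxel hubs sharing one latent, three patient sessions.
small_sim_config <- function(seed = 1L, n_patients = 4L, n_controls = 4L,
                             ...) {
  dims <- c(12L, 12L, 12L)
  hub_a <- list(x = c(2, 4), y = c(2, 4), z = c(8, 10))
  hub_b <- list(x = c(9, 11), y = c(2, 4), z = c(8, 10))
  cog <- list(x = c(2, 4), y = c(9, 11), z = c(8, 10))
  cog_b <- list(x = c(9, 11), y = c(9, 11), z = c(8, 10))
  mk <- function(box) {
    grid <- expand.grid(x = box$x[1]:box$x[2], y = box$y[1]:box$y[2],
                        z = box$z[1]:box$z[2])
    as.integer(grid$x + dims[1] * (grid$y - 1) + dims[1] * dims[2] * (grid$z - 1))
  }
  comms <- list(
    community_spec("smc_ipsi", mk(hub_a), "sensorimotor", 0.20,
                   (0.60 - 0.20) / 370, 0.60, latent = "smc"),
    community_spec("smc_contra", mk(hub_b), "sensorimotor", 0.20,
                   (0.60 - 0.20) / 370, 0.60, latent = "smc"),
    community_spec("dlpfc_ipsi", mk(cog), "cognitive", 0.55,
                   (0.30 - 0.55) / 370, 0.30, latent = "dlpfc"),
    community_spec("dlpfc_contra", mk(cog_b), "cognitive", 0.55,
                   (0.30 - 0.55) / 370, 0.30, latent = "dlpfc")
  )
  sim_config(grid_shape = dims, n_patients = n_patients,
             n_controls = n_controls,
             session_days = c(3, 98, 370), communities = comms,
             lesion_box = list(x = c(6, 7), y = c(6, 7), z = c(3, 4)),
             seed = seed, ...)
}
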