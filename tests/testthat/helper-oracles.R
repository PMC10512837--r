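# Independent reference implementations used as oracles. Deliberately
# plain, loop-based R, written against the definitions, not against the
# package internals.

naive_zncc <- function(A, B) {
  a <- A - mean(A)
  b <- B - mean(B)
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den == 0) 0 else sum(a * b) / den
}

naive_ncc_surface <- function(block, region) {
  nr <- nrow(block); nc <- ncol(block)
  nlr <- nrow(region) - nr + 1
  nlc <- ncol(region) - nc + 1
  out <- matrix(0, nlr, nlc)
  for (lj in seq_len(nlc))
    for (li in seq_len(nlr))
      out[li, lj] <- naive_zncc(block,
                                region[li:(li + nr - 1), lj:(lj + nc - 1)])
  out
}

naive_lag_preferred <- function(di, dj, bi, bj) {
  k1 <- c(di^2 + dj^2, abs(di), abs(dj), di, dj)
  k2 <- c(bi^2 + bj^2, abs(bi), abs(bj), bi, bj)
  for (q in seq_along(k1)) {
    if (k1[q] < k2[q]) return(TRUE)
    if (k1[q] > k2[q]) return(FALSE)
  }
  FALSE
}

# Brute-force triple-loop block matcher (integer lags only).
naive_block_match <- function(pre, post, block_ax, block_lat,
                              shift_ax, shift_lat, ma, ml) {
  nr <- nrow(pre); nc <- ncol(pre)
  i0s <- integer(0); i0 <- ma + 1
  while (i0 + block_ax - 1 + ma <= nr) { i0s <- c(i0s, i0); i0 <- i0 + shift_ax }
  j0s <- integer(0); j0 <- ml + 1
  while (j0 + block_lat - 1 + ml <= nc) { j0s <- c(j0s, j0); j0 <- j0 + shift_lat }
  d_ax <- matrix(0, length(i0s), length(j0s))
  d_lat <- matrix(0, length(i0s), length(j0s))
  ncc <- matrix(0, length(i0s), length(j0s))
  for (l in seq_along(j0s)) for (a in seq_along(i0s)) {
    i0 <- i0s[a]; j0 <- j0s[l]
    B <- pre[i0:(i0 + block_ax - 1), j0:(j0 + block_lat - 1)]
    bv <- -2; bdi <- 0; bdj <- 0; have <- FALSE
    for (dj in -ml:ml) for (di in -ma:ma) {
      C <- post[(i0 + di):(i0 + di + block_ax - 1),
                (j0 + dj):(j0 + dj + block_lat - 1)]
      v <- naive_zncc(B, C)
      if (!have || v > bv || (v == bv && naive_lag_preferred(di, dj, bdi, bdj))) {
        have <- TRUE; bv <- v; bdi <- di; bdj <- dj
      }
    }
    d_ax[a, l] <- bdi; d_lat[a, l] <- bdj; ncc[a, l] <- bv
  }
  list(i0 = i0s, j0 = j0s, d_axial = d_ax, d_lateral = d_lat, peak_ncc = ncc)
}

# Brute-force exact Mann-Whitney p by enumerating all group labelings,
# computing U by direct pair counting (no ranks).
brute_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

brute_mw_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  mu <- na * length(b) / 2
  U <- brute_u(a, b)
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(ii) brute_u(pooled[ii], pooled[-ii]))
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(us - mu) >= abs(U - mu) - eps),
         greater = mean(us >= U - eps),
         less = mean(us <= U + eps))
}

# Small speckle frame pair with a pure sub-sample (scatterer-level) axial
# shift; shift_samples in RF samples.
make_speckle_pair <- function(shift_samples, seed,
                              region = c(0, 6, 0, 6), density = 200,
                              psf = psf_params()) {
  s <- make_scatterer_field(region, density, seed = seed)
  dz <- mm_per_sample(psf)
  f1 <- render_rf_frame(s, psf)
  s2 <- warp_scene(s, function(z, x)
    list(d_axial_mm = rep(shift_samples * dz, length(z)),
         d_lateral_mm = rep(0, length(z))))
  f2 <- render_rf_frame(s2, psf, nrow(f1$samples), ncol(f1$samples))
  list(f_pre = f1, f_post = f2, psf = psf)
}

# Non-circular integer row shift: rows k+1..n of the output are rows
# 1..n-k of the input; vacated rows get independent noise.
shift_rows <- function(M, k, fill_seed = 999) {
  n <- nrow(M)
  out <- matrix(withr::with_seed(fill_seed, rnorm(length(M))), n, ncol(M))
  if (k >= 0) out[(k + 1):n, ] <- M[1:(n - k), ]
  else out[1:(n + k), ] <- M[(1 - k):n, ]
  out
}

circular_shift_rows <- function(M, k) {
  n <- nrow(M)
  idx <- ((seq_len(n) - 1 - k) %% n) + 1
  M[idx, , drop = FALSE]
}
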