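# Independent brute-force oracles, written straight from the
# definitions with explicit loops. These deliberately share no code
# with the package internals.

DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1),
  c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

in_bounds <- function(v, dm) all(v >= 1) && all(v <= dm)

# wrap an integer level array (NA outside the ROI) as a quantized_roi
make_q <- function(lev) {
  ng <- max(lev, na.rm = TRUE)
  structure(list(levels = lev, mask = roi_mask(!is.na(lev)),
                 ng = ng, ng_effective = ng, codebook = seq_len(ng),
                 range = c(1, ng), iterations = 0L,
                 mse_trace = numeric(0)),
            class = "quantized_roi")
}

random_level_roi <- function(max_dim = 6, max_lev = 5) {
  dm <- c(sample(2:max_dim, 1), sample(2:max_dim, 1), sample(2:max_dim, 1))
  nl <- sample(2:max_lev, 1)
  lev <- array(sample(seq_len(nl), prod(dm), replace = TRUE), dm)
  drop <- array(runif(prod(dm)) < 0.2, dm)
  if (sum(!drop) < 2) drop[] <- FALSE
  lev[drop] <- NA
  # ensure top level occupied so codebook length == max level
  if (!any(lev == nl, na.rm = TRUE)) lev[which(!is.na(lev))[1]] <- nl
  lev
}

oracle_glcm_dir <- function(lev, d) {
  dm <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  M <- matrix(0, ng, ng)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    g <- lev[x, y, z]
    if (is.na(g)) next
    v2 <- c(x, y, z) + d
    if (!in_bounds(v2, dm)) next
    h <- lev[v2[1], v2[2], v2[3]]
    if (is.na(h)) next
    M[g, h] <- M[g, h] + 1
    M[h, g] <- M[h, g] + 1
  }
  M
}

oracle_glcm <- function(lev, normalize = TRUE) {
  M <- Reduce(`+`, lapply(seq_len(nrow(DIRS13)),
                          function(i) oracle_glcm_dir(lev, DIRS13[i, ])))
  if (normalize) M / sum(M) else M
}

# runs identified as maximal same-level segments: each run is keyed by
# the voxel at its negative-direction end
oracle_glrlm <- function(lev) {
  dm <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  runs <- list()
  for (i in seq_len(nrow(DIRS13))) {
    d <- DIRS13[i, ]
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      g <- lev[x, y, z]
      if (is.na(g)) next
      prev <- c(x, y, z) - d
      if (in_bounds(prev, dm) &&
          isTRUE(lev[prev[1], prev[2], prev[3]] == g)) next
      len <- 0
      v <- c(x, y, z)
      while (in_bounds(v, dm) && isTRUE(lev[v[1], v[2], v[3]] == g)) {
        len <- len + 1
        v <- v + d
      }
      runs[[length(runs) + 1]] <- c(g, len)
    }
  }
  runs <- do.call(rbind, runs)
  M <- matrix(0, ng, max(runs[, 2]))
  for (r in seq_len(nrow(runs)))
    M[runs[r, 1], runs[r, 2]] <- M[runs[r, 1], runs[r, 2]] + 1
  M
}

# flood-fill 26-connected constant-level components
oracle_glszm <- function(lev) {
  dm <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  seen <- array(FALSE, dm)
  zones <- list()
  coords <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    v0 <- coords[r, ]
    if (seen[v0[1], v0[2], v0[3]]) next
    g <- lev[v0[1], v0[2], v0[3]]
    queue <- list(v0)
    seen[v0[1], v0[2], v0[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- v + c(dx, dy, dz)
        if (!in_bounds(w, dm)) next
        if (seen[w[1], w[2], w[3]]) next
        if (isTRUE(lev[w[1], w[2], w[3]] == g)) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  zones <- do.call(rbind, zones)
  M <- matrix(0, ng, max(zones[, 2]))
  for (r in seq_len(nrow(zones)))
    M[zones[r, 1], zones[r, 2]] <- M[zones[r, 1], zones[r, 2]] + 1
  M
}

oracle_ngtdm <- function(lev) {
  dm <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  s <- numeric(ng)
  N <- numeric(ng)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    g <- lev[x, y, z]
    if (is.na(g)) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- c(x + dx, y + dy, z + dz)
      if (!in_bounds(w, dm)) next
      h <- lev[w[1], w[2], w[3]]
      if (!is.na(h)) nb <- c(nb, h)
    }
    if (length(nb) > 0) {
      s[g] <- s[g] + abs(g - mean(nb))
      N[g] <- N[g] + 1
    }
  }
  list(s = s, N = N)
}

# feature formulas as explicit double loops
oracle_features_glcm <- function(P) {
  ng <- nrow(P)
  contrast <- dissim <- energy <- entropy <- homog <- sumavg <- 0
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    dissim <- dissim + abs(i - j) * p
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log2(p)
    homog <- homog + p / (1 + abs(i - j))
    sumavg <- sumavg + (i + j) * p
    px[i] <- px[i] + p
  }
  mu <- sum((1:ng) * px)
  sig2 <- sum(((1:ng) - mu)^2 * px)
  variance <- 0
  cross <- 0
  for (i in 1:ng) for (j in 1:ng) {
    variance <- variance + (i - mu)^2 * P[i, j]
    cross <- cross + i * j * P[i, j]
  }
  corr <- if (sig2 > 0) (cross - mu^2) / sig2 else NA_real_
  c(GLCM_Contrast = contrast, GLCM_Correlation = corr,
    GLCM_Dissimilarity = dissim, GLCM_Energy = energy,
    GLCM_Entropy = entropy, GLCM_Homogeneity = homog,
    GLCM_SumAverage = sumavg, GLCM_Variance = variance)
}

oracle_features_rl <- function(M, nvox, prefix = "GLRLM", ndir = 13) {
  ng <- nrow(M); nr <- ncol(M); Ns <- sum(M)
  acc <- function(f) {
    tot <- 0
    for (g in 1:ng) for (r in 1:nr) tot <- tot + f(g, r) * M[g, r]
    tot / Ns
  }
  gln <- sum(sapply(1:ng, function(g) sum(M[g, ])^2)) / Ns
  n2 <- sum(sapply(1:nr, function(r) sum(M[, r])^2)) / Ns
  mu_g <- acc(function(g, r) g)
  mu_r <- acc(function(g, r) r)
  vals <- c(
    GLN = gln,
    GLV = acc(function(g, r) (g - mu_g)^2),
    HG = acc(function(g, r) g^2),
    LE = acc(function(g, r) r^2),
    LH = acc(function(g, r) g^2 * r^2),
    LL = acc(function(g, r) r^2 / g^2),
    LG = acc(function(g, r) 1 / g^2),
    SV = acc(function(g, r) (r - mu_r)^2),
    PCT = Ns / (nvox * ndir),
    N2 = n2,
    SE = acc(function(g, r) 1 / r^2),
    SH = acc(function(g, r) g^2 / r^2),
    SL = acc(function(g, r) 1 / (g^2 * r^2))
  )
  if (prefix == "GLRLM") {
    setNames(vals, paste0("GLRLM_", c("GLN", "GLV", "HGRE", "LRE", "LRHGE",
                                      "LRLGE", "LGRE", "RLV", "RP", "RLN",
                                      "SRE", "SRHGE", "SRLGE")))
  } else {
    setNames(vals, paste0("GLSZM_", c("GLN", "GLV", "HGZE", "LZE", "LZHGE",
                                      "LZLGE", "LGZE", "ZSV", "ZP", "ZSN",
                                      "SZE", "SZHGE", "SZLGE")))
  }
}

oracle_features_ngtdm <- function(s, N, eps = 1e-6) {
  occ <- which(N > 0)
  n <- sum(N)
  p <- N / n
  ngp <- length(occ)
  ps <- 0
  for (i in occ) ps <- ps + p[i] * s[i]
  coarse <- 1 / (eps + ps)
  if (ngp >= 2) {
    a <- 0
    for (i in occ) for (j in occ) a <- a + p[i] * p[j] * (i - j)^2
    contrast <- a / (ngp * (ngp - 1)) * sum(s) / n
    den <- 0
    for (i in occ) for (j in occ) den <- den + abs(i * p[i] - j * p[j])
    busy <- if (den > 0) ps / den else 0
    cplx <- 0
    for (i in occ) for (j in occ)
      cplx <- cplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
        (p[i] + p[j])
    cplx <- cplx / n
    stren <- 0
    for (i in occ) for (j in occ) stren <- stren + (p[i] + p[j]) * (i - j)^2
    stren <- stren / (eps + sum(s))
  } else {
    contrast <- busy <- cplx <- stren <- 0
  }
  c(NGTDM_Busyness = busy, NGTDM_Coarseness = coarse,
    NGTDM_Complexity = cplx, NGTDM_Contrast = contrast,
    NGTDM_Strength = stren)
}

oracle_features_intensity <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(IS_Kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    IS_Skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    IS_Variance = m2)
}

oracle_vn <- function(raw, s, N, V, eps = 1e-6) {
  occ <- which(N > 0)
  n <- sum(N)
  p <- N / n
  num <- 0
  for (i in occ) num <- num + p[i] * s[i] / N[i]
  den <- 0
  for (i in occ) for (j in occ) den <- den + abs(i * p[i] - j * p[j])
  out <- raw
  for (k in c("GLRLM_GLN", "GLRLM_RLN", "GLSZM_GLN", "GLSZM_ZSN"))
    out[k] <- raw[k] / V
  out["NGTDM_Strength"] <- raw["NGTDM_Strength"] * V
  out["NGTDM_Busyness"] <- if (den > 0) num / den else NA_real_
  out["NGTDM_Coarseness"] <- 1 / (eps + num)
  out
}

# full 42-feature oracle vector (VN applied) for a level array + raw
# intensities on a 1 mm grid
oracle_all_features <- function(lev, raw) {
  nvox <- sum(!is.na(lev))
  glcm <- oracle_features_glcm(oracle_glcm(lev))
  glrlm <- oracle_features_rl(oracle_glrlm(lev), nvox, "GLRLM")
  glszm <- oracle_features_rl(oracle_glszm(lev), nvox, "GLSZM", ndir = 1)
  nt <- oracle_ngtdm(lev)
  ngtdm <- oracle_features_ngtdm(nt$s, nt$N)
  is_f <- oracle_features_intensity(raw[!is.na(lev)])
  raw_all <- c(glcm, glrlm, is_f, ngtdm, glszm)
  oracle_vn(raw_all, nt$s, nt$N, V = nvox)
}

# rank with average ties, from sorting
oracle_rank <- function(x) {
  n <- length(x)
  o <- order(x)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x)
  ry <- oracle_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# step-up BH by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  pmin(adj, 1)
}
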