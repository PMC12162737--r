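# Brute-force oracles for the texture-matrix features, written as direct
# transcriptions of the reference formulas with explicit loops. They are
# deliberately independent of the package's native engines: matrices are
# assembled by exhaustive enumeration (all pixel pairs, rle-based line
# scans, BFS flood fill, per-pixel neighbor scans) and the features are
# computed from the assembled matrices with plain R sums.

oracle_offsets <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                       `135` = c(-1, -1))

# ---- GLCM ------------------------------------------------------------------

oracle_glcm_matrix <- function(L, ng, off, dist, symmetric = TRUE) {
  P <- matrix(0, ng, ng)
  nr <- nrow(L); nc <- ncol(L)
  for (r1 in seq_len(nr)) for (c1 in seq_len(nc)) {
    for (r2 in seq_len(nr)) for (c2 in seq_len(nc)) {
      if (r2 - r1 == off[1] * dist && c2 - c1 == off[2] * dist &&
          !is.na(L[r1, c1]) && !is.na(L[r2, c2])) {
        P[L[r1, c1], L[r2, c2]] <- P[L[r1, c1], L[r2, c2]] + 1
        if (symmetric) P[L[r2, c2], L[r1, c1]] <- P[L[r2, c2], L[r1, c1]] + 1
      }
    }
  }
  P
}

oracle_glcm_angle <- function(P) {
  ng <- nrow(P)
  if (sum(P) == 0) return(rep(NA_real_, 24))
  p <- P / sum(P)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx2 <- sum(px * (seq_len(ng) - mux)^2)
  sigy2 <- sum(py * (seq_len(ng) - muy)^2)
  pm <- sapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]))
  pp <- sapply(2:(2 * ng), function(k) sum(p[(i + j) == k]))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  hxy1 <- -sum(p[p > 0] * log2((px[i] * py[j])[p > 0]))
  hxy2 <- { q <- outer(px, py); ent(q) }
  hx <- ent(px); hy <- ent(py)
  da <- sum((0:(ng - 1)) * pm)
  mcc <- if (sum(px > 0) <= 1) 1 else {
    occ <- which(px > 0)
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      Q[a, b] <- sum(p[occ[a], occ] * p[occ[b], occ] /
                       (px[occ[a]] * py[occ]))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(Autocorrelation = sum(p * i * j),
    ClusterProminence = sum(p * (i + j - mux - muy)^4),
    ClusterShade = sum(p * (i + j - mux - muy)^3),
    ClusterTendency = sum(p * (i + j - mux - muy)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = if (sigx2 > 0 && sigy2 > 0)
      (sum(p * i * j) - mux * muy) / sqrt(sigx2 * sigy2) else NA_real_,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pm),
    DifferenceVariance = sum(pm * ((0:(ng - 1)) - da)^2),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_,
    Imc2 = sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)),
    InverseVariance = if (ng > 1)
      sum(pm[-1] / (seq_len(ng - 1))^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum((2:(2 * ng)) * pp),
    SumEntropy = ent(pp),
    SumSquares = sum(p * (i - mux)^2))
}

oracle_glcm <- function(L, ng, angles = c(0, 45, 90, 135), dist = 1,
                        symmetric = TRUE) {
  per <- sapply(as.character(angles), function(a)
    oracle_glcm_angle(oracle_glcm_matrix(L, ng, oracle_offsets[[a]], dist,
                                         symmetric)))
  out <- rowMeans(per, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  stats::setNames(out, paste0("glcm_", rownames(per)))
}

# ---- shared (level, size) feature algebra for GLRLM / GLSZM ---------------

oracle_rl_features <- function(P, np, prefix, jname) {
  nr <- sum(P)
  i <- row(P); j <- col(P)
  pn <- P / nr
  glv_mu <- sum(i * pn); rv_mu <- sum(j * pn)
  vals <- c(
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    GrayLevelVariance = sum(pn * (i - glv_mu)^2),
    HighGrayLevel = sum(P * i^2) / nr,
    Long = sum(P * j^2) / nr,
    LongHighGrayLevel = sum(P * i^2 * j^2) / nr,
    LongLowGrayLevel = sum(P * j^2 / i^2) / nr,
    LowGrayLevel = sum(P / i^2) / nr,
    Entropy = { q <- pn[pn > 0]; -sum(q * log2(q)) },
    LengthNonUniformity = sum(colSums(P)^2) / nr,
    LengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    Percentage = nr / np,
    Variance = sum(pn * (j - rv_mu)^2),
    Short = sum(P / j^2) / nr,
    ShortHighGrayLevel = sum(P * i^2 / j^2) / nr,
    ShortLowGrayLevel = sum(P / (i^2 * j^2)) / nr
  )
  vals
}

# ---- GLRLM: rle scan over explicit lines ----------------------------------

extract_lines <- function(L, off) {
  nr <- nrow(L); nc <- ncol(L)
  if (all(off == c(0, 1))) {
    lapply(seq_len(nr), function(r) L[r, ])
  } else if (all(off == c(-1, 0))) {
    lapply(seq_len(nc), function(c) rev(L[, c]))
  } else if (all(off == c(-1, 1))) {      # anti-diagonals, walking up-right
    lapply(seq_len(nr + nc - 1), function(d) {
      cells <- which(row(L) + col(L) == d + 1, arr.ind = TRUE)
      cells <- cells[order(-cells[, 1]), , drop = FALSE]
      L[cells]
    })
  } else {                                 # (-1,-1): diagonals, up-left
    lapply(seq_len(nr + nc - 1), function(d) {
      cells <- which(row(L) - col(L) == d - nc, arr.ind = TRUE)
      cells <- cells[order(-cells[, 1]), , drop = FALSE]
      L[cells]
    })
  }
}

oracle_glrlm_matrix <- function(L, ng, off) {
  maxlen <- max(dim(L))
  P <- matrix(0, ng, maxlen)
  for (line in extract_lines(L, off)) {
    r <- rle(ifelse(is.na(line), -1, line))
    for (k in seq_along(r$values)) {
      if (r$values[k] > 0)
        P[r$values[k], r$lengths[k]] <- P[r$values[k], r$lengths[k]] + 1
    }
  }
  P
}

oracle_glrlm <- function(L, ng, angles = c(0, 45, 90, 135)) {
  np <- sum(!is.na(L))
  per <- sapply(as.character(angles), function(a)
    oracle_rl_features(oracle_glrlm_matrix(L, ng, oracle_offsets[[a]]), np))
  out <- rowMeans(per, na.rm = TRUE)
  nm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
          "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
          "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
          "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
          "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
          "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
          "ShortRunLowGrayLevelEmphasis")
  stats::setNames(out, paste0("glrlm_", nm))
}

# ---- GLSZM: BFS flood fill -------------------------------------------------

oracle_zones <- function(L) {
  nr <- nrow(L); nc <- ncol(L)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(L[r, c]) || seen[r, c]) next
    queue <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- q[1] + dr; cc <- q[2] + dc
        if (rr >= 1 && cc >= 1 && rr <= nr && cc <= nc && !seen[rr, cc] &&
            !is.na(L[rr, cc]) && L[rr, cc] == L[r, c]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = L[r, c], size = size)
  }
  zones
}

oracle_glszm <- function(L, ng) {
  zones <- oracle_zones(L)
  np <- sum(!is.na(L))
  maxsz <- max(vapply(zones, `[[`, 0, "size"))
  P <- matrix(0, ng, maxsz)
  for (z in zones) P[z["level"], z["size"]] <- P[z["level"], z["size"]] + 1
  v <- oracle_rl_features(P, np)
  nm <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
          "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
          "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
          "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
          "ZoneEntropy", "SizeZoneNonUniformity",
          "SizeZoneNonUniformityNormalized", "ZonePercentage",
          "ZoneVariance", "SmallAreaEmphasis",
          "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis")
  stats::setNames(unname(v), paste0("glszm_", nm))
}

# ---- GLDM: per-pixel neighbor scan ----------------------------------------

oracle_gldm <- function(L, ng, alpha = 0) {
  nr <- nrow(L); nc <- ncol(L)
  P <- matrix(0, ng, 9)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(L[r, c])) next
    dep <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && cc >= 1 && rr <= nr && cc <= nc && !is.na(L[rr, cc]) &&
          abs(L[rr, cc] - L[r, c]) <= alpha) dep <- dep + 1
    }
    P[L[r, c], dep + 1] <- P[L[r, c], dep + 1] + 1
  }
  nz <- sum(P)
  i <- row(P); j <- col(P)
  pn <- P / nz
  mu_i <- sum(i * pn); mu_j <- sum(j * pn)
  vals <- c(
    DependenceEntropy = { q <- pn[pn > 0]; -sum(q * log2(q)) },
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    DependenceVariance = sum(pn * (j - mu_j)^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    GrayLevelVariance = sum(pn * (i - mu_i)^2),
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz
  )
  stats::setNames(vals, paste0("gldm_", names(vals)))
}

# ---- NGTDM: per-pixel neighborhood means ----------------------------------

oracle_ngtdm <- function(L, ng) {
  nr <- nrow(L); nc <- ncol(L)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(L[r, c])) next
    nbr <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && cc >= 1 && rr <= nr && cc <= nc && !is.na(L[rr, cc]))
        nbr <- c(nbr, L[rr, cc])
    }
    if (!length(nbr)) next
    n_i[L[r, c]] <- n_i[L[r, c]] + 1
    s_i[L[r, c]] <- s_i[L[r, c]] + abs(L[r, c] - mean(nbr))
  }
  nvp <- sum(n_i)
  if (nvp == 0)
    return(stats::setNames(rep(NA_real_, 5),
                           paste0("ngtdm_", c("Busyness", "Coarseness",
                                              "Complexity", "Contrast",
                                              "Strength"))))
  p_i <- n_i / nvp
  occ <- which(p_i > 0)
  ngp <- length(occ)
  sum_ps <- sum(p_i * s_i)
  busy_den <- 0; cplx <- 0; str_num <- 0; ctr <- 0
  for (a in occ) for (b in occ) {
    busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
    cplx <- cplx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
      (p_i[a] + p_i[b])
    str_num <- str_num + (p_i[a] + p_i[b]) * (a - b)^2
    ctr <- ctr + p_i[a] * p_i[b] * (a - b)^2
  }
  vals <- c(
    Busyness = if (busy_den > 0) sum_ps / busy_den else 0,
    Coarseness = if (sum_ps > 0) 1 / sum_ps else 1e6,
    Complexity = cplx / nvp,
    Contrast = if (ngp > 1) ctr / (ngp * (ngp - 1)) * sum(s_i) / nvp else 0,
    Strength = if (sum(s_i) > 0) str_num / sum(s_i) else 0
  )
  stats::setNames(vals, paste0("ngtdm_", names(vals)))
}

# random masked test region: intensities equal to levels (bin width 1)
random_region <- function(seed, nr = 8, nc = 8, ng_max = 6,
                          mask_frac = 0.85) {
  set.seed(seed)
  vals <- matrix(sample(seq_len(sample(2:ng_max, 1)), nr * nc,
                        replace = TRUE), nr, nc)
  mask <- matrix(runif(nr * nc) < mask_frac, nr, nc)
  if (!any(mask)) mask[1, 1] <- TRUE
  img <- image_slice(vals + 0, spacing_mm = c(1, 1))
  list(image = img,
       mask = radiomap:::new_seg_mask(mask, img))
}
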