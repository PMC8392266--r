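# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive enumeration/loops and are kept separate from
# the package code paths they check.

# Half-sample symmetric padding of a vector: padL on the left, padR right.
oraclePadSym <- function(v, padL, padR) {
  n <- length(v)
  left <- if (padL > 0) v[pmin(padL:1, n)] else numeric(0)
  right <- if (padR > 0) v[pmax(n:(n - padR + 1), 1)] else numeric(0)
  c(left, v, right)
}

# Direct (non-separable) 3D filtering with the outer-product kernel of three
# 1D filters, same alignment and boundary handling as the package transform:
# y[i,j,k] = sum f1[a] f2[b] f3[c] xpad[i+a-1, j+b-1, k+c-1].
oracleConv3D <- function(x, f1, f2, f3) {
  d <- dim(x)
  L <- length(f1)
  padL <- (L - 1) %/% 2; padR <- L - 1 - padL
  # pad the whole array axis by axis
  padAxis <- function(a, axis) {
    dm <- dim(a)
    idx <- lapply(dm, seq_len)
    n <- dm[axis]
    ord <- c(pmin(padL:1, n), seq_len(n), pmax(n:(n - padR + 1), 1))
    if (padL == 0) ord <- c(seq_len(n), pmax(n:(n - padR + 1), 1))
    idx[[axis]] <- ord
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  xp <- padAxis(padAxis(padAxis(x, 1), 2), 3)
  y <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in seq_len(L)) for (b in seq_len(L)) for (cc in seq_len(L))
      acc <- acc + f1[a] * f2[b] * f3[cc] * xp[i + a - 1, j + b - 1, k + cc - 1]
    y[i, j, k] <- acc
  }
  y
}

# Symmetric co-occurrence probability matrix by explicit enumeration of all
# ordered voxel pairs at displacement d (levels: array with NA off-mask).
oracleGLCMMatrix <- function(lev, d, ng) {
  dm <- dim(lev)
  C <- matrix(0, ng, ng)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- lev[i, j, k]
    ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
    if (is.na(a) || ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
        kk < 1 || kk > dm[3]) next
    b <- lev[ii, jj, kk]
    if (is.na(b)) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

# Independent implementation of the 26 co-occurrence features from a
# normalized symmetric matrix (plain-loop formulas).
oracleGLCMFeatures <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(as.vector(P))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    m <- px[i] * py[j]
    if (m > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(m)
      hxy2 <- hxy2 - m * log2(m)
    }
  }
  # note hxy1 must include zero-P terms with nonzero marginals: 0*log is 0
  hx <- ent(px); hy <- ent(py)
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  f <- c(joint_maximum = max(P), joint_average = mux, joint_variance = 0,
         joint_entropy = hxy, difference_average = 0,
         difference_variance = 0, difference_entropy = 0, sum_average = 0,
         sum_variance = 0, sum_entropy = 0, energy = sum(P^2), contrast = 0,
         dissimilarity = 0, homogeneity1 = 0, idn = 0, homogeneity2 = 0,
         idmn = 0, inverse_variance = 0, correlation = 0,
         autocorrelation = 0, cluster_tendency = 0, cluster_shade = 0,
         cluster_prominence = 0, imc1 = 0, imc2 = 0, mcc = 0)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
    ps[i + j - 1] <- ps[i + j - 1] + p
    f["joint_variance"] <- f["joint_variance"] + (i - mux)^2 * p
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * p
    f["homogeneity1"] <- f["homogeneity1"] + p / (1 + abs(i - j))
    f["idn"] <- f["idn"] + p / (1 + abs(i - j) / ng)
    f["homogeneity2"] <- f["homogeneity2"] + p / (1 + (i - j)^2)
    f["idmn"] <- f["idmn"] + p / (1 + (i - j)^2 / ng^2)
    if (i != j) f["inverse_variance"] <- f["inverse_variance"] + p / (i - j)^2
    f["autocorrelation"] <- f["autocorrelation"] + i * j * p
    f["cluster_tendency"] <- f["cluster_tendency"] + (i + j - mux - muy)^2 * p
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - mux - muy)^3 * p
    f["cluster_prominence"] <- f["cluster_prominence"] +
      (i + j - mux - muy)^4 * p
  }
  f["difference_average"] <- sum((0:(ng - 1)) * pd)
  f["difference_variance"] <- sum(((0:(ng - 1)) - f["difference_average"])^2 * pd)
  f["difference_entropy"] <- ent(pd)
  f["sum_average"] <- sum((2:(2 * ng)) * ps)
  f["sum_variance"] <- sum(((2:(2 * ng)) - f["sum_average"])^2 * ps)
  f["sum_entropy"] <- ent(ps)
  if (sx > 0 && sy > 0) {
    co <- 0
    for (i in 1:ng) for (j in 1:ng) co <- co + i * j * P[i, j]
    f["correlation"] <- (co - mux * muy) / (sx * sy)
  }
  if (max(hx, hy) > 0) f["imc1"] <- (hxy - hxy1) / max(hx, hy)
  f["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  keep <- which(px > 0)
  if (length(keep) >= 2) {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (k in keep)
        s <- s + P[keep[a], k] * P[keep[b], k] / (px[keep[a]] * py[k])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    f["mcc"] <- sqrt(max(0, min(1, ev[2])))
  }
  f
}

# Direction-averaged GLCM features by the enumeration oracle.
oracleGLCMAveraged <- function(lev, ng, directions) {
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(directions))) {
    P <- oracleGLCMMatrix(lev, directions[r, ], ng)
    if (is.null(P)) next
    ff <- oracleGLCMFeatures(P)
    acc <- if (is.null(acc)) ff else acc + ff
    nd <- nd + 1
  }
  acc / nd
}

# Run list (gray level, length) for one direction by walking each line from
# its start voxel.
oracleRuns <- function(lev, d) {
  dm <- dim(lev)
  gl <- integer(0); len <- integer(0)
  inGrid <- function(p) all(p >= 1) && all(p <= dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    p <- c(i, j, k)
    if (inGrid(p - d)) next            # not a line start
    seqv <- c()
    while (inGrid(p)) {
      seqv <- c(seqv, lev[p[1], p[2], p[3]])
      p <- p + d
    }
    r <- rle(seqv)
    # NA breaks: rle treats each NA as its own run; drop them
    ok <- !is.na(r$values)
    gl <- c(gl, r$values[ok]); len <- c(len, r$lengths[ok])
  }
  list(levels = gl, lengths = len)
}

oracleGLRLMFeatures <- function(gl, len, nVox) {
  nr <- length(gl)
  f <- c(sre = 0, lre = 0, gln = 0, rln = 0, rp = nr / nVox, lgre = 0,
         hgre = 0, srlge = 0, srhge = 0, lrlge = 0, lrhge = 0, glv = 0,
         rlv = 0)
  for (r in seq_len(nr)) {
    f["sre"] <- f["sre"] + 1 / len[r]^2 / nr
    f["lre"] <- f["lre"] + len[r]^2 / nr
    f["lgre"] <- f["lgre"] + 1 / gl[r]^2 / nr
    f["hgre"] <- f["hgre"] + gl[r]^2 / nr
    f["srlge"] <- f["srlge"] + 1 / (gl[r]^2 * len[r]^2) / nr
    f["srhge"] <- f["srhge"] + gl[r]^2 / len[r]^2 / nr
    f["lrlge"] <- f["lrlge"] + len[r]^2 / gl[r]^2 / nr
    f["lrhge"] <- f["lrhge"] + gl[r]^2 * len[r]^2 / nr
  }
  for (g in unique(gl)) f["gln"] <- f["gln"] + sum(gl == g)^2 / nr
  for (l in unique(len)) f["rln"] <- f["rln"] + sum(len == l)^2 / nr
  mg <- mean(gl); ml <- mean(len)
  f["glv"] <- mean((gl - mg)^2)
  f["rlv"] <- mean((len - ml)^2)
  f
}

# riu2 LBP code of one pixel by explicit bitstring enumeration.
oracleLBPCode <- function(slice, r, c) {
  offs <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  bits <- sapply(1:8, function(k)
    as.integer(slice[r + offs[k, 1], c + offs[k, 2]] >= slice[r, c]))
  transitions <- sum(abs(diff(c(bits, bits[1]))))
  if (transitions <= 2) sum(bits) else 9L
}

# Trilinear interpolation at a single fractional index by the textbook
# formula.
oracleTrilinear <- function(data, p) {
  d <- dim(data)
  i0 <- pmin(pmax(floor(p), 1), d - 1)
  f <- p - i0
  acc <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
         (if (cc) f[3] else 1 - f[3])
    acc <- acc + w * data[i0[1] + a, i0[2] + b, i0[3] + cc]
  }
  acc
}

# The 13 canonical co-occurrence directions, duplicated here so tests do not
# depend on the package internals they validate.
oracleDirections <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# Random small discretized ROI fixture (levels array with NA off-mask).
randomROIFixture <- function(dims, ng, maskProb = 0.8) {
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  m <- array(stats::runif(prod(dims)) < maskProb, dims)
  if (!any(m)) m[1] <- TRUE
  lev[!m] <- NA_integer_
  lev
}
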