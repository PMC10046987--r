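# Independent brute-force oracles. These deliberately use plain nested loops
# and direct formula transcription, sharing no code path with the package.

# co-occurrence counts by explicit pair enumeration
glcm_oracle <- function(q, L, theta, d = 1, symmetric = TRUE) {
  off <- switch(as.character(theta),
    "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  C <- matrix(0, L, L)
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        i <- q[r, c] + 1; j <- q[r2, c2] + 1
        C[i, j] <- C[i, j] + 1
        if (symmetric) C[j, i] <- C[j, i] + 1
      }
    }
  }
  C / sum(C)
}

# the 22 co-occurrence features by direct formula transcription (loops)
glcm_features_oracle <- function(P) {
  L <- nrow(P)
  lg <- function(v) if (v > 0) log2(v) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:L) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sdx <- sqrt(sum(((1:L) - mux)^2 * px)); sdy <- sqrt(sum(((1:L) - muy)^2 * py))
  mu <- (mux + muy) / 2
  psum <- numeric(2 * L); pdif <- numeric(L) # index k+1 for pdif (k = 0..L-1)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  HX <- 0; for (i in 1:L) HX <- HX - px[i] * lg(px[i])
  HY <- 0; for (j in 1:L) HY <- HY - py[j] * lg(py[j])
  HXY <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in 1:L) for (j in 1:L) {
    HXY <- HXY - P[i, j] * lg(P[i, j])
    HXY1 <- HXY1 - P[i, j] * lg(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  acc <- cp <- cs <- con <- dis <- ene <- hom <- idm <- sos <- idn <- idmn <- 0
  for (i in 1:L) for (j in 1:L) {
    acc <- acc + i * j * P[i, j]
    cp <- cp + (i + j - 2 * mu)^4 * P[i, j]
    cs <- cs + (i + j - 2 * mu)^3 * P[i, j]
    con <- con + (i - j)^2 * P[i, j]
    dis <- dis + abs(i - j) * P[i, j]
    ene <- ene + P[i, j]^2
    hom <- hom + P[i, j] / (1 + (i - j)^2)
    idm <- idm + P[i, j] / (1 + abs(i - j))
    sos <- sos + (i - mux)^2 * P[i, j]
    idn <- idn + P[i, j] / (1 + abs(i - j) / L)
    idmn <- idmn + P[i, j] / (1 + (i - j)^2 / L^2)
  }
  corr <- if (sdx == 0 || sdy == 0) 0 else (acc - mux * muy) / (sdx * sdy)
  de <- 0; for (k in 0:(L - 1)) de <- de - pdif[k + 1] * lg(pdif[k + 1])
  mudif <- sum((0:(L - 1)) * pdif)
  dv <- sum(((0:(L - 1)) - mudif)^2 * pdif)
  sa <- 0; se <- 0
  for (k in 2:(2 * L)) { sa <- sa + k * psum[k]; se <- se - psum[k] * lg(psum[k]) }
  sv <- sum(((2:(2 * L)) - sa)^2 * psum[2:(2 * L)])
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  keep <- which(px > 0 & py > 0)
  mcc <- 0
  if (length(keep) >= 2) {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (kk in seq_along(keep)) {
        s <- s + P[keep[a], keep[kk]] * P[keep[b], keep[kk]] /
          (px[keep[a]] * py[keep[kk]])
      }
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(min(max(ev[2], 0), 1))
  }
  c(acc, cp, cs, con, corr, de, dv, dis, ene, HXY, hom, imc1, imc2, idm,
    max(P), sa, se, sos, sv, mcc, idn, idmn)
}

# run-length counts by explicit line scanning
glrlm_oracle <- function(q, L, theta) {
  nr <- nrow(q); nc <- ncol(q)
  get_lines <- function() {
    if (theta == 0) return(lapply(seq_len(nr), function(r) q[r, ]))
    if (theta == 90) return(lapply(seq_len(nc), function(c) q[, c]))
    lines <- list()
    if (theta == 45) {
      for (s in (1 + 1):(nr + nc)) { # r + c = s
        v <- c()
        for (r in seq(nr, 1)) {
          c2 <- s - r
          if (c2 >= 1 && c2 <= nc) v <- c(v, q[r, c2])
        }
        if (length(v)) lines[[length(lines) + 1]] <- v
      }
    } else {
      for (s in (1 - nc):(nr - 1)) { # r - c = s
        v <- c()
        for (r in seq_len(nr)) {
          c2 <- r - s
          if (c2 >= 1 && c2 <= nc) v <- c(v, q[r, c2])
        }
        if (length(v)) lines[[length(lines) + 1]] <- v
      }
    }
    lines
  }
  R <- matrix(0, L, max(nr, nc))
  for (v in get_lines()) {
    k <- 1
    while (k <= length(v)) {
      len <- 1
      while (k + len <= length(v) && v[k + len] == v[k]) len <- len + 1
      R[v[k] + 1, len] <- R[v[k] + 1, len] + 1
      k <- k + len
    }
  }
  R
}

glrlm_features_oracle <- function(R, n_pixels) {
  nr <- sum(R)
  sre <- lre <- lgre <- hgre <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    sre <- sre + R[i, j] / j^2
    lre <- lre + R[i, j] * j^2
    lgre <- lgre + R[i, j] / i^2
    hgre <- hgre + R[i, j] * i^2
  }
  c(sre / nr, lre / nr, sum(rowSums(R)^2) / nr, nr / n_pixels,
    sum(colSums(R)^2) / nr, lgre / nr, hgre / nr)
}

# AUC by exhaustive positive-negative pair counting, ties worth 1/2
auc_oracle <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (s[p] > s[n]) 1 else if (s[p] == s[n]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# quadratic-time ReliefF reference: min-max scaling, Manhattan neighbors,
# index tie-breaks — transcribed independently of the package implementation
relieff_oracle <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  S <- X
  for (f in seq_len(p)) {
    rng <- max(X[, f]) - min(X[, f])
    S[, f] <- if (rng > 0) (X[, f] - min(X[, f])) / rng else 0
  }
  w <- numeric(p)
  for (m in seq_len(n)) {
    d <- numeric(n)
    for (o in seq_len(n)) d[o] <- sum(abs(S[m, ] - S[o, ]))
    d_self <- d; d_self[m] <- Inf
    hits <- order(d_self)
    hits <- hits[y[hits] == y[m]][seq_len(k)]
    miss <- order(d)[y[order(d)] != y[m]][seq_len(k)]
    for (f in seq_len(p)) {
      w[f] <- w[f] + sum(abs(S[miss, f] - S[m, f])) - sum(abs(S[hits, f] - S[m, f]))
    }
  }
  w / (n * k)
}

# dense numerical quadrature of the circular mean (10000 angles, bilinear)
circular_mean_oracle <- function(img, x0, y0, r, n = 10000) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  xs <- x0 + r * sin(th); ys <- y0 - r * cos(th)
  v <- numeric(n)
  for (k in seq_len(n)) {
    x <- min(max(xs[k], 1), ncol(img)); y <- min(max(ys[k], 1), nrow(img))
    x0i <- min(floor(x), ncol(img) - 1); y0i <- min(floor(y), nrow(img) - 1)
    fx <- x - x0i; fy <- y - y0i
    v[k] <- (1 - fy) * ((1 - fx) * img[y0i, x0i] + fx * img[y0i, x0i + 1]) +
      fy * ((1 - fx) * img[y0i + 1, x0i] + fx * img[y0i + 1, x0i + 1])
  }
  mean(v)
}

# small eye phantom shared by segmentation tests
phantom_eye <- function(nr = 128, nc = 128, pupil = circle(64, 66, 18),
                        iris = circle(64, 64, 48), levels = c(30, 110, 220)) {
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  img <- matrix(levels[3], nr, nc)
  img[(xs - iris$x0)^2 + (ys - iris$y0)^2 <= iris$r^2] <- levels[2]
  img[(xs - pupil$x0)^2 + (ys - pupil$y0)^2 <= pupil$r^2] <- levels[1]
  img
}
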