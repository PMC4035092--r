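# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations.

# --- plateau regions of equal value (8-connected), plain BFS ---------------
bf_regions <- function(img, mask) {
  nr <- nrow(img); nc <- ncol(img)
  lab <- matrix(NA_integer_, nr, nc)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  k <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || !is.na(lab[i, j])) next
    k <- k + 1L
    v <- img[i, j]
    queue <- list(c(i, j)); lab[i, j] <- k
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (q in seq_len(nrow(nb))) {
        ni <- p[1L] + nb$dr[q]; nj <- p[2L] + nb$dc[q]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (mask[ni, nj] && is.na(lab[ni, nj]) && img[ni, nj] == v) {
          lab[ni, nj] <- k
          queue <- c(queue, list(c(ni, nj)))
        }
      }
    }
  }
  lab
}

# --- brute-force prominence of every local-maximum plateau -----------------
# Prominence = height minus the highest level v at which the connected
# component of {img >= v} containing the maximum also contains a dominating
# maximum (higher value, or equal value with smaller minimum linear index);
# maxima never dominated take height - min(masked values).
bf_prominences <- function(img, mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  lab <- bf_regions(img, mask)
  nreg <- max(lab, na.rm = TRUE)
  rval <- vapply(seq_len(nreg), function(r) img[which(lab == r)[1L]], 0)
  rmin <- vapply(seq_len(nreg), function(r) min(which(lab == r)), 0L)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  higher_nbr <- function(r) {
    px <- which(lab == r, arr.ind = TRUE)
    for (p in seq_len(nrow(px))) for (q in seq_len(nrow(nb))) {
      ni <- px[p, 1L] + nb$dr[q]; nj <- px[p, 2L] + nb$dc[q]
      if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
      if (mask[ni, nj] && img[ni, nj] > rval[r]) return(TRUE)
    }
    FALSE
  }
  ismax <- !vapply(seq_len(nreg), higher_nbr, TRUE)
  # 8-neighbourhood of a logical matrix via shifts (vectorized)
  neighbors8 <- function(s) {
    grow <- function(m) {
      g <- m
      g[-1, ] <- g[-1, ] | m[-nr, , drop = FALSE]
      g[-nr, ] <- g[-nr, ] | m[-1, , drop = FALSE]
      g2 <- g
      g2[, -1] <- g2[, -1] | g[, -nc, drop = FALSE]
      g2[, -nc] <- g2[, -nc] | g[, -1, drop = FALSE]
      g2
    }
    grow(s) & !s
  }
  out <- lapply(which(ismax), function(r) {
    h <- rval[r]
    dom_px <- mask & (img > h | (img == h & lab != r & rmin[lab] < rmin[r]))
    inset <- lab == r & !is.na(lab)
    prom <- h - min(img[mask])
    repeat {
      fr <- neighbors8(inset) & mask & !inset
      if (!any(fr)) break
      v <- max(img[fr])                 # highest pixel touching the flood
      repeat {                          # close the component at level >= v
        add <- neighbors8(inset) & mask & !inset & img >= v
        if (!any(add)) break
        inset <- inset | add
      }
      if (any(inset & dom_px)) { prom <- h - v; break }
    }
    data.frame(region = r, height = h, min_index = rmin[r], prominence = prom)
  })
  do.call(rbind, out)
}

# --- exhaustive Otsu over all 8-bit cut points -----------------------------
bf_otsu_8bit <- function(vals) {
  best <- -Inf; best_t <- NA_real_
  for (t in 0:254) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / length(vals)) * (length(hi) / length(vals)) *
      (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12 * max(best, 1)) { best <- bcv; best_t <- t }
  }
  best_t
}

# --- exact permutation two-sided p for the two-sample t statistic ----------
# Enumerates every split of the pooled sample (vectorized over splits).
bf_permutation_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a); N <- length(pool)
  idx <- combn(N, n)
  M <- matrix(0, N, ncol(idx))
  M[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n))] <- 1
  sa <- crossprod(M, pool); sa2 <- crossprod(M, pool^2)
  sb <- sum(pool) - sa; sb2 <- sum(pool^2) - sa2
  ma <- sa / n; mb <- sb / (N - n)
  va <- (sa2 - n * ma^2) / (n - 1)
  vb <- (sb2 - (N - n) * mb^2) / (N - n - 1)
  sp2 <- ((n - 1) * va + (N - n - 1) * vb) / (N - 2)
  tt <- abs((ma - mb) / sqrt(sp2 * (1 / n + 1 / (N - n))))
  spo <- ((n - 1) * var(a) + (N - n - 1) * var(b)) / (N - 2)
  obs <- abs((mean(a) - mean(b)) / sqrt(spo * (1 / n + 1 / (N - n))))
  mean(tt >= obs - 1e-12)
}

# detected-vs-truth matching stats via the package's greedy matcher
recovery_stats <- function(fs, centers, max_dist = 3) {
  m <- wmquant:::match_foci(fs$coordinates, centers, max_dist)
  c(recall = m / nrow(centers), precision = m / max(1L, nrow(fs$coordinates)),
    n_detected = nrow(fs$coordinates), n_true = nrow(centers))
}
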