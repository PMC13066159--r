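# Independent brute-force oracles. These deliberately use different
# algorithms / code paths than the package implementation.

# Per-pixel radial binning by an explicit double loop (0-based pixel centers).
oracle_radial_profile <- function(img, cx, cy) {
  nr <- nrow(img); nc <- ncol(img)
  maxr <- as.integer(round(sqrt(nr^2 + nc^2))) + 2L
  sums <- numeric(maxr + 1L); cnts <- integer(maxr + 1L)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r <- as.integer(round(sqrt((j - 1 - cx)^2 + (i - 1 - cy)^2)))
      sums[r + 1L] <- sums[r + 1L] + img[i, j]
      cnts[r + 1L] <- cnts[r + 1L] + 1L
    }
  }
  radii <- which(cnts > 0L) - 1L
  data.frame(r_px = radii, intensity = sums[radii + 1L] / cnts[radii + 1L],
             n_px = cnts[radii + 1L])
}

# Connected components by BFS flood fill.
oracle_flood_fill <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      qi <- (q - 1L) %% nr + 1L; qj <- (q - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nb))) {
        ii <- qi + nb[k, 1]; jj <- qj + nb[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- c(queue, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  lab
}

# Triangle construction evaluated bin by bin with the normalized point-line
# distance formula (line through the peak and the tail end).
oracle_triangle_bin <- function(h) {
  peak <- which.max(h)
  nz <- which(h > 0)
  first <- nz[1]; last <- nz[length(nz)]
  tail_bin <- if ((peak - first) > (last - peak)) first else last
  rng <- setdiff(seq(min(peak, tail_bin), max(peak, tail_bin)), c(peak, tail_bin))
  if (!length(rng)) return(peak)
  # line a*x + b*y + c = 0 through (peak, h[peak]) and (tail, h[tail])
  a <- h[tail_bin] - h[peak]
  b <- peak - tail_bin
  cc <- -(a * peak + b * h[peak])
  d <- abs(a * rng + b * h[rng] + cc) / sqrt(a^2 + b^2)
  cand <- rng[d >= max(d) - 1e-9]
  cand[which.min(abs(cand - peak))]
}

# Exact two-tailed Mann-Whitney p by enumerating binary group assignments and
# counting pairs (not rank sums): U = #(x_i > y_j) + 0.5 #(x_i == y_j).
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_of <- function(sel) {
    a <- pooled[sel]; b <- pooled[!sel]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  sel0 <- c(rep(TRUE, nx), rep(FALSE, n - nx))
  mu <- nx * (n - nx) / 2
  obs <- abs(u_of(sel0) - mu)
  tot <- 0L; ge <- 0L
  for (bits in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(bits, 2^(0:(n - 1))))
    if (sum(sel) != nx) next
    tot <- tot + 1L
    if (abs(u_of(sel) - mu) >= obs - 1e-9) ge <- ge + 1L
  }
  ge / tot
}

# Kruskal-Wallis H from first principles with midranks and tie correction.
oracle_kw_h <- function(groups) {
  vals <- unlist(groups)
  n <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(vals)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
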