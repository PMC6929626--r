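# Independent oracles, kept deliberately separate from the package's own
# numerics: exhaustive grid search for the VFA fit, closed-form textbook
# statistics, and exact rank-sum enumeration.

# Brute-force T1 grid search minimizing the profiled residual sum of
# squares of the spoiled-GRE model. S: n x k signal matrix.
oracle_t1_grid <- function(S, flip_deg, tr_ms,
                           t1_grid = seq(0.05, 5, by = 0.001)) {
  a <- flip_deg * pi / 180
  e1 <- exp(-(tr_ms / 1000) / t1_grid)        # length G
  FF <- sapply(seq_along(a), function(k)
    sin(a[k]) * (1 - e1) / (1 - e1 * cos(a[k])))  # G x k
  sumf2 <- rowSums(FF^2)
  SF <- S %*% t(FF)                            # n x G
  ss <- rowSums(S^2)
  rss <- ss - sweep(SF^2, 2, sumf2, "/")
  t1_grid[max.col(-rss, ties.method = "first")]
}

# Welch statistic, Satterthwaite df and two-sided p from first principles.
oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Pearson r via the covariance / sd-product formula.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Exact two-sided rank-sum p by enumerating all group-A rank assignments.
oracle_ranksum_exact <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  all_r <- rank(seq_len(n))  # no ties by construction in callers
  ws <- apply(combs, 2, function(ii) sum(all_r[ii])) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# 6-connectivity connected-component count on a sparse 3D mask.
count_components_3d <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(0L)
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  key <- function(p) (p[, 3] - 1) * d[1] * d[2] + (p[, 2] - 1) * d[1] + p[, 1]
  k0 <- key(pos)
  edges <- NULL
  for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- sweep(pos, 2, off, "+")
    ok <- nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    m <- match(key(nb[ok, , drop = FALSE]), k0)
    hit <- !is.na(m)
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], m[hit]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  as.integer(igraph::components(g)$no)
}

# Plant non-touching bright discs on a uniform background; returns the image
# and the ground-truth table.
planted_disc_image <- function(n_discs = 20, size = 400, background = 10,
                               intensity = 50, diam_range = c(4, 20),
                               noise_frac = 0, seed = 5) {
  set.seed(seed)
  img <- matrix(background, size, size)
  truth <- data.frame(row = numeric(), col = numeric(), diam_px = numeric())
  guard <- max(diam_range) + 6
  while (nrow(truth) < n_discs) {
    r0 <- runif(1, guard, size - guard)
    c0 <- runif(1, guard, size - guard)
    if (nrow(truth) > 0 &&
        any(sqrt((truth$row - r0)^2 + (truth$col - c0)^2) <
              max(diam_range) + 6)) next
    truth <- rbind(truth, data.frame(row = r0, col = c0,
                                     diam_px = runif(1, diam_range[1],
                                                     diam_range[2])))
  }
  rr <- row(img); cc <- col(img)
  for (i in seq_len(nrow(truth))) {
    disc <- (rr - truth$row[i])^2 + (cc - truth$col[i])^2 <=
      (truth$diam_px[i] / 2)^2
    img[disc] <- intensity
  }
  if (noise_frac > 0)
    img <- pmax(img + matrix(rnorm(length(img), 0, noise_frac * intensity),
                             size), 0)
  list(image = img, truth = truth)
}
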