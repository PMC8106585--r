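# Independent brute-force oracle for the min-max optimisation on small
# tables: re-derives the worst-case scenario distances from first principles
# (plain loops, no package internals) and scans the share simplex on a fixed
# grid instead of solving an LP.
oracle_distance_rows <- function(tab, m, weights = NULL) {
  L <- length(tab$land_uses)
  if (is.null(weights)) weights <- setNames(rep(1, length(tab$indicators)),
                                            tab$indicators)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), L)))
  rows <- NULL
  for (i in tab$indicators) {
    dir <- tab$directions[[i]]
    mu <- tab$mean[, i]
    wc <- if (dir == "more") mu - m * tab$sd[, i] else mu + m * tab$sd[, i]
    for (r in seq_len(nrow(subsets))) {
      cc <- ifelse(subsets[r, ], wc, mu)
      tgt <- if (dir == "more") max(cc) else min(cc)
      wst <- if (dir == "more") min(cc) else max(cc)
      if (abs(tgt - wst) < 1e-12) next
      d <- if (dir == "more") 100 * (tgt - cc) / (tgt - wst)
           else 100 * (cc - tgt) / (wst - tgt)
      rows <- rbind(rows, weights[[i]] * d)
    }
  }
  rows
}

# worst weighted distance of one portfolio (brute force over scenarios)
oracle_worst_distance <- function(tab, shares, m, weights = NULL) {
  rows <- oracle_distance_rows(tab, m, weights)
  max(c(rows %*% shares, 0))
}

# minimal worst distance over the 3-land-use simplex at the given grid step
oracle_grid_beta <- function(tab, m, step = 0.01) {
  stopifnot(length(tab$land_uses) == 3)
  a1 <- seq(0, 1, step)
  pts <- do.call(rbind, lapply(a1, function(x)
    cbind(x, seq(0, 1 - x + 1e-12, step))))
  pts <- cbind(pts, pmax(1 - pts[, 1] - pts[, 2], 0))
  rows <- oracle_distance_rows(tab, m)
  betas <- apply(rows %*% t(pts), 2, max)
  min(betas)
}

subtable <- function(tab, rows) {
  indicator_table(tab$mean[rows, , drop = FALSE],
                  tab$sd[rows, , drop = FALSE], tab$directions)
}
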