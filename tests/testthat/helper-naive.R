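# Independent naive reference implementations used as oracles.  Everything
# here works from the full pairwise distance matrix with explicit per-center,
# per-size loops, sharing no code with the package's swept/indexed path.

naive_dist_matrix <- function(ps) {
  as.matrix(stats::dist(cbind(ps$x, ps$y)))
}

# Neighbor walk: center first, remaining points by (distance, id).
naive_walk <- function(ps, i, d) {
  rest <- setdiff(seq_len(nrow(ps)), i)
  c(i, rest[order(d[rest], ps$id[rest], method = "radix")])
}

# One LOOCV entry computed the slow way: mean over centers of (p - q)^2 with
# empty-training / unreached-target centers excluded, plus the achieved-size
# summary (captured population for geographic, last-capture distance for the
# population kinds).
naive_loocv_entry <- function(ps, kind, size, include_center = TRUE) {
  D <- naive_dist_matrix(ps)
  n <- nrow(ps)
  se <- rep(NA_real_, n)
  ach <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    ord <- naive_walk(ps, i, d)
    pops <- ps$population[ord]
    poss <- ps$positives[ord]
    if (kind == "geographic") {
      m <- sum(d <= size)
      tpop <- sum(pops[seq_len(m)][-1])
      tpos <- sum(poss[seq_len(m)][-1])
      a <- sum(pops[seq_len(m)])
      unreached <- FALSE
    } else {
      acc <- if (include_center) cumsum(pops) else cumsum(pops) - pops[1L]
      hit <- which(acc >= size)
      unreached <- length(hit) == 0L
      m <- if (unreached) n else hit[1L]
      if (kind == "fixed_population" && !unreached && m > 1L) {
        w <- (size - acc[m - 1L]) / pops[m]
        tpop <- sum(pops[seq_len(m - 1L)][-1]) + w * pops[m]
        tpos <- sum(poss[seq_len(m - 1L)][-1]) + w * poss[m]
      } else {
        tpop <- sum(pops[seq_len(m)][-1])
        tpos <- sum(poss[seq_len(m)][-1])
      }
      a <- d[ord[m]]
    }
    if (!unreached && tpop > 0) {
      p <- ps$positives[i] / ps$population[i]
      se[i] <- (p - tpos / tpop)^2
      ach[i] <- a
    }
  }
  inc <- !is.na(se)
  list(mse = if (any(inc)) mean(se[inc]) else NA_real_,
       n_included = sum(inc), n_excluded = sum(!inc),
       summary_mean = if (any(inc)) mean(ach[inc]) else NA_real_,
       summary_min = if (any(inc)) min(ach[inc]) else NA_real_,
       summary_max = if (any(inc)) max(ach[inc]) else NA_real_)
}

# Random test point sets, mixed spatial patterns, id labels shuffled so the
# tie rule is exercised independently of generation order.
random_ps <- function(n, pattern = c("uniform", "clustered"), seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is.null(seed)) set.seed(seed)
  if (pattern == "uniform") {
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
  } else {
    k <- max(2L, round(n / 25))
    cxy <- matrix(runif(2 * k, 0, 500), ncol = 2)
    g <- sample(k, n, replace = TRUE)
    x <- cxy[g, 1] + rnorm(n, sd = 20)
    y <- cxy[g, 2] + rnorm(n, sd = 20)
  }
  pop <- 1 + rpois(n, 3)
  point_set(id = sample(sprintf("q%04d", seq_len(n))), x = x, y = y,
            population = pop, positives = rbinom(n, pop, 0.5))
}

# Rigid motion: rotate by theta and translate; distances are preserved.
rigid_motion <- function(ps, theta, dx, dy) {
  out <- ps
  out$x <- cos(theta) * ps$x - sin(theta) * ps$y + dx
  out$y <- sin(theta) * ps$x + cos(theta) * ps$y + dy
  out
}
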