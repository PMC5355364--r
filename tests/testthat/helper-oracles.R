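# Independent oracles, deliberately implemented along different routes
# than the package code they check.

# Liebig feasibility oracle for the limiting score: r is the largest output
# level lambda the diet can stoichiometrically support, where each unpaired
# essential must cover lambda * p_i and each conditional precursor must
# cover its own requirement plus any dependent shortfall mole-for-mole.
# Found by bisection rather than by the score/argmin algebra.
oracle_limiting_r <- function(d, p, eaa = eaa_config()) {
  d <- d / sum(d); p <- p / sum(p)
  pairs <- Filter(function(pr) pr[2] %in% names(d), eaa$conditional_pairs)
  prec <- vapply(pairs, `[`, "", 1L)
  unpaired <- setdiff(eaa$essential, prec)
  feasible <- function(lam) {
    for (i in unpaired) if (d[[i]] < lam * p[[i]]) return(FALSE)
    for (pr in pairs) {
      P <- pr[1]; D <- pr[2]
      if (d[[P]] < lam * p[[P]] + max(0, lam * p[[D]] - d[[D]]))
        return(FALSE)
    }
    TRUE
  }
  lo <- 0
  hi <- max(d[eaa$essential] / p[eaa$essential]) + 1
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) lo <- mid else hi <- mid
  }
  lo
}

# Dense grid search over the sphere-simplex shell for 3-letter alphabets:
# the best achievable distance from B among C with ||C - A|| = ||B - A||,
# sum(C) = 1, C >= 0.
oracle_mismatch_best_dist <- function(A, B, n_grid = 400001L) {
  R <- sqrt(sum((A - B)^2))
  u1 <- c(1, -1, 0) / sqrt(2)
  u2 <- c(1, 1, -2) / sqrt(6)
  th <- seq(0, 2 * pi, length.out = n_grid)
  C <- sweep(R * (outer(cos(th), u1) + outer(sin(th), u2)), 2, A, "+")
  ok <- rowSums(C < -1e-9) == 0
  if (!any(ok)) stop("grid oracle found no feasible point")
  sqrt(max(rowSums(sweep(C[ok, , drop = FALSE], 2, B, "-")^2)))
}

# Exhaustive null for the mean-rank test on small universes: enumerate all
# size-k subsets of the pooled ranks.
oracle_enum_mean_rank_p <- function(pool, k, obs_mean) {
  combs <- utils::combn(pool, k)
  mean(colMeans(combs) <= obs_mean + 1e-12)
}
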