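# Independent brute-force oracle for the Bayesian IVIM posterior: a dense
# LINEAR grid over the full prior box with an explicit s0 axis, direct
# evaluation of the Gaussian likelihood at every node, and discrete
# weighted medians. No analytic amplitude integral, no log spacing, no
# refinement, no interpolation -- deliberately a different computational
# path from the package's grid engine.
oracle_ivim_posterior <- function(b, y, sigma, priors = prior_spec(),
                                  n = 100L) {
  if (is.null(priors$s0_hi)) priors$s0_hi <- 2 * max(y)
  fx <- seq(priors$f[1], priors$f[2], length.out = n)
  dx <- seq(priors$d[1], priors$d[2], length.out = n)
  dsx <- seq(priors$d_star[1], priors$d_star[2], length.out = n)
  s0x <- seq(priors$s0_hi / (2 * n), priors$s0_hi, length.out = n)
  sy2 <- sum(y^2)
  twoss <- 2 * sigma^2
  # numerical stabiliser: smallest SSR on a coarse sub-grid
  coarse <- seq(1L, n, length.out = 12L)
  ssr_min <- Inf
  for (f in fx[coarse]) for (d in dx[coarse]) for (ds in dsx[coarse]) {
    g <- f * exp(-b * ds) + (1 - f) * exp(-b * d)
    for (s0 in s0x[coarse]) {
      ssr <- sum((y - s0 * g)^2)
      if (ssr < ssr_min) ssr_min <- ssr
    }
  }
  ed <- exp(-outer(b, dx)); eds <- exp(-outer(b, dsx))
  m_f <- numeric(n); m_d <- numeric(n); m_ds <- numeric(n); m_s0 <- numeric(n)
  for (i in seq_len(n)) {
    f <- fx[i]
    # sum over b of g^2 and y*g at every (d, d_star) node
    sg2 <- f^2 * matrix(colSums(eds^2), n, n, byrow = TRUE) +
      2 * f * (1 - f) * crossprod(ed, eds) +
      (1 - f)^2 * matrix(colSums(ed^2), n, n)
    syg <- f * matrix(drop(crossprod(eds, y)), n, n, byrow = TRUE) +
      (1 - f) * matrix(drop(crossprod(ed, y)), n, n)
    md_i <- numeric(n); mds_i <- numeric(n)
    for (k in seq_len(n)) {
      s0 <- s0x[k]
      lik <- exp(-(sy2 - 2 * s0 * syg + s0^2 * sg2 - ssr_min) / twoss)
      tot <- sum(lik)
      m_f[i] <- m_f[i] + tot
      m_s0[k] <- m_s0[k] + tot
      md_i <- md_i + rowSums(lik)
      mds_i <- mds_i + colSums(lik)
    }
    m_d <- m_d + md_i
    m_ds <- m_ds + mds_i
  }
  med <- function(x, m) x[which(cumsum(m) / sum(m) >= 0.5)[1]]
  list(f = med(fx, m_f), d = med(dx, m_d), d_star = med(dsx, m_ds),
       s0 = med(s0x, m_s0),
       marginals = list(f = cbind(fx, m_f), d = cbind(dx, m_d),
                        d_star = cbind(dsx, m_ds), s0 = cbind(s0x, m_s0)))
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all sign
# assignments (no ties, no zeros assumed).
oracle_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Permutation oracle for the one-way repeated-measures omnibus test:
# permute timepoint labels within each unit and compare the F statistic.
oracle_rm_anova_p <- function(wide, n_perm = 400, seed = 99) {
  f_stat <- function(w) {
    gm <- mean(w)
    ss_time <- nrow(w) * sum((colMeans(w) - gm)^2)
    ss_unit <- ncol(w) * sum((rowMeans(w) - gm)^2)
    ss_tot <- sum((w - gm)^2)
    ss_err <- ss_tot - ss_time - ss_unit
    df_t <- ncol(w) - 1; df_e <- (nrow(w) - 1) * (ncol(w) - 1)
    (ss_time / df_t) / (ss_err / df_e)
  }
  obs <- f_stat(wide)
  set.seed(seed)
  perm <- replicate(n_perm, {
    w2 <- t(apply(wide, 1, sample))
    f_stat(w2)
  })
  mean(c(obs, perm) >= obs)
}
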