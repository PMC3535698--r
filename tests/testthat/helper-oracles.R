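# Independent oracles and random-case generators. Everything here
# recomputes quantities from first principles (direct probability products,
# brute-force pairwise counts, naive double loops, grid search) so the
# package's log-space / vectorized implementations are checked against a
# different computational path.

# Density of a cond_density evaluated directly from its parameters with
# stats d* functions (scalar, probability scale, with the same floor).
oracle_density <- function(fc, x) {
  p <- fc$params
  tr <- fc$transform
  d <- switch(fc$family,
    gamma_reflected = if (x < tr$reflect)
      dgamma(tr$reflect - x, shape = p$shape, scale = p$scale) else 0,
    gamma = if (x > 0) dgamma(x, shape = p$shape, scale = p$scale) else 0,
    negative_binomial = {
      cnt <- round(tr$scale * (x - tr$shift))
      if (cnt >= 0) dnbinom(cnt, size = p$size, mu = p$mu) * tr$scale else 0
    },
    gaussian = dnorm(x, p$mean, p$sd),
    gaussian_mixture = p$w1 * dnorm(x, p$mean1, p$sd1) +
      p$w2 * dnorm(x, p$mean2, p$sd2),
    exponential_shifted = if (x >= tr$shift)
      dexp(x - tr$shift, rate = p$rate) else 0)
  max(d, fc$floor)
}

# Direct (non-log) Bayes rule for one record.
oracle_posterior <- function(model, scores) {
  lik <- c(pos = 1, neg = 1)
  for (j in seq_along(model$tools)) {
    t <- model$tools[[j]]
    x <- scores[j]
    if (is.na(x)) {
      lik["pos"] <- lik["pos"] * t$fnr
      lik["neg"] <- lik["neg"] * t$tnr
    } else {
      lik["pos"] <- lik["pos"] * oracle_density(t$pos, x) * t$tpr
      lik["neg"] <- lik["neg"] * oracle_density(t$neg, x) * t$fpr
    }
  }
  num <- model$prior * lik[["pos"]]
  num / (num + (1 - model$prior) * lik[["neg"]])
}

# Random conditional density (well-behaved parameter ranges so direct
# probability products stay inside double range for <= 6 tools).
random_cond <- function() {
  fam <- sample(c("gaussian", "gamma", "gamma_reflected",
                  "exponential_shifted", "gaussian_mixture",
                  "negative_binomial"), 1L)
  mk <- mirfuse:::new_cond_density
  switch(fam,
    gaussian = mk("gaussian", list(mean = runif(1, -5, 5),
                                   sd = runif(1, 0.5, 3))),
    gamma = mk("gamma", list(shape = runif(1, 0.8, 6),
                             scale = runif(1, 0.3, 3))),
    gamma_reflected = mk("gamma_reflected",
                         list(shape = runif(1, 0.8, 6),
                              scale = runif(1, 0.3, 3)),
                         transform = list(reflect = runif(1, -1, 2))),
    exponential_shifted = mk("exponential_shifted",
                             list(rate = runif(1, 0.2, 3)),
                             transform = list(shift = runif(1, -2, 2))),
    gaussian_mixture = {
      w1 <- runif(1, 0.2, 0.8)
      mk("gaussian_mixture",
         list(w1 = w1, w2 = 1 - w1, mean1 = runif(1, -5, 0),
              mean2 = runif(1, 1, 6), sd1 = runif(1, 0.5, 2),
              sd2 = runif(1, 0.5, 2)))
    },
    negative_binomial = {
      size <- runif(1, 1, 10)
      mu <- runif(1, 2, 30)
      mk("negative_binomial",
         list(size = size, mu = mu, prob = size / (size + mu)),
         transform = list(shift = runif(1, -3, 3), scale = 1))
    })
}

# Random small fusion model with 3-6 tools.
random_model <- function(k = sample(3:6, 1L)) {
  tools <- lapply(seq_len(k), function(j) {
    list(name = paste0("tool", j), pos = random_cond(), neg = random_cond(),
         tpr = runif(1, 0.05, 0.95), fpr = runif(1, 0.05, 0.95))
  })
  fusion_model(runif(1, 0.01, 0.9), tools)
}

# Random score record for a model: per tool, missing with probability
# miss_p, otherwise drawn from the positive or negative conditional.
random_record <- function(model, miss_p = 0.3) {
  vapply(model$tools, function(t) {
    if (runif(1) < miss_p) return(NA_real_)
    rcond_density(if (runif(1) < 0.5) t$pos else t$neg, 1L)
  }, numeric(1))
}

# Brute-force AUC: pairwise concordance over all positive-negative pairs,
# ties (including shared missingness, ranked below everything) count 1/2.
auc_concordance <- function(score, label) {
  s <- ifelse(is.na(score), -Inf, as.numeric(score))
  pos <- s[label == 1]
  neg <- s[label == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Grid-search Gamma MLE (profile likelihood in the scale): independent
# maximizer used to validate the closed-form/uniroot fit.
gamma_grid_mle <- function(z, shapes = seq(0.5, 8, by = 0.002)) {
  ll <- vapply(shapes, function(a) {
    sum(dgamma(z, shape = a, scale = mean(z) / a, log = TRUE))
  }, numeric(1))
  a <- shapes[which.max(ll)]
  c(shape = a, scale = mean(z) / a)
}

# Method-of-moments Negative Binomial estimate.
nb_moments <- function(counts) {
  m <- mean(counts)
  v <- var(counts)
  size <- m^2 / (v - m)
  c(size = size, prob = size / (size + m))
}

# Naive double-loop A(n) on ranked fold changes.
naive_A <- function(f, n) {
  total <- 0
  for (t in seq_len(n)) {
    ct <- 0
    for (j in seq_len(t)) ct <- ct + f[j]
    total <- total + ct
  }
  total
}

# Small labeled score table fixture built in code.
toy_table <- function() {
  scores <- rbind(c(-0.3, 150, NA),
                  c(NA, NA, 2.5),
                  c(-0.1, 160, 1.0),
                  c(NA, 145, NA))
  colnames(scores) <- c("TargetScan", "miRanda", "PicTar")
  score_table(c("miR-124", "miR-124", "let-7b", "let-7b"),
              c("GAPDH", "TP53", "GAPDH", "MYC"),
              scores, label = c(1L, 0L, 1L, 0L))
}
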