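# Shared fixtures, computed lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small genotyped cohort with confounding and a true causal effect 0.3
fx_confounded_cohort <- function() {
  fixture("confounded_cohort", {
    cfg <- sim_config(
      n_individuals = 20000, n_variants = 30, ld_block_size = 1,
      within_block_r = 0, exposure_h2 = 0.3, true_causal_effect = 0.3,
      confounder_effect_x = 0.6, confounder_effect_y = 0.6, seed = 11
    )
    g <- simulate_genotypes(cfg)
    ct <- simulate_traits(g)
    dat <- ct$cohort
    dat$score <- build_allele_score(g$dosages, ct$truth$variant_effects)
    list(genotypes = g, sim = ct, data = dat, cfg = cfg)
  })
}

# deterministic 10-instrument set with known generating slope 0.3
fx_instruments <- function() {
  fixture("instruments", {
    set.seed(42)
    k <- 10
    ins <- tibble::tibble(
      beta_x = runif(k, 0.1, 0.5), se_x = 0.02,
      se_y = runif(k, 0.02, 0.08)
    )
    ins$beta_y <- 0.3 * ins$beta_x + rnorm(k, 0, ins$se_y)
    ins
  })
}

# brute-force weighted-median oracle: cumulative-weight interpolation
oracle_weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(v[1])
  if (cum[length(v)] <= 0.5) return(v[length(v)])
  i <- max(which(cum < 0.5))
  v[i] + (v[i + 1] - v[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

# direct optimiser of the Jeffreys-penalised logistic log-likelihood
oracle_firth <- function(X, y) {
  pll <- function(b) {
    eta <- drop(X %*% b)
    pr <- plogis(eta)
    I <- crossprod(X * sqrt(pr * (1 - pr)))
    sum(y * eta - log1p(exp(eta))) +
      0.5 * as.numeric(determinant(I, logarithm = TRUE)$modulus)
  }
  optim(rep(0, ncol(X)), function(b) -pll(b), method = "BFGS",
        control = list(reltol = 1e-15, maxit = 1000))$par
}
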