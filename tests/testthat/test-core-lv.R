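test_that("host selection keeps only well-replicated species", {
  spec <- community_spec(n_hosts = 3, n_otus = 40, replicates_per_host = 6,
                         depth = 2000, gen_min = 3, spec_max = 2, seed = 4)
  com <- gen_bipartite_community(spec)
  # Host01: drop two replicates so it has 4 < 5
  keep <- sample_ids(com$counts)[!sample_ids(com$counts) %in%
                                   c("Host01_rep01", "Host01_rep02")]
  x <- subset_counts(com$counts, samples = keep)
  sel <- select_hosts(x, com$meta, min_reps = 5, seed = 1)
  expect_false("Host01" %in% names(sel))
  expect_setequal(names(sel), c("Host02", "Host03"))
  expect_true(all(vapply(sel, function(t) nrow(t$counts), 0) == 5))
  # identical seed, identical subsample; exact-count hosts need no sampling
  sel2 <- select_hosts(x, com$meta, min_reps = 5, seed = 1)
  expect_identical(sample_ids(sel$Host02), sample_ids(sel2$Host02))
  sel6 <- select_hosts(x, com$meta, min_reps = 6, seed = 9)
  expect_setequal(sample_ids(sel6$Host02),
                  sample_ids(com$counts)[grepl("Host02", sample_ids(com$counts))])
})

test_that("core extraction enforces the prevalence ceiling and abundance floor", {
  M <- 47
  ids <- sprintf("rep%02d", 1:M)
  # OtuHigh in 40/47 replicates (pass), OtuLow in 39/47 (fail),
  # OtuThin everywhere but at 0.9% of reads (fail)
  m <- matrix(0L, M, 3, dimnames = list(ids, c("OtuHigh", "OtuLow", "OtuThin")))
  m[1:40, "OtuHigh"] <- 100L
  m[1:39, "OtuLow"] <- 100L
  m[, "OtuThin"] <- 2L  # 94 reads
  # pad OtuHigh so the grand total is 9500: 94/9500 = 0.99% < 1%
  m[1, "OtuHigh"] <- m[1, "OtuHigh"] + (9500L - sum(m))
  expect_true(sum(m[, "OtuThin"]) / sum(m) < 0.01)
  core <- extract_core(count_table(m), host_species = "T")
  expect_identical(core$otu_ids, "OtuHigh")
  expect_equal(ceiling(0.85 * 47), 40)
  # raising OtuThin above 1% admits it
  m2 <- m; m2[, "OtuThin"] <- 3L
  expect_true(sum(m2[, "OtuThin"]) / sum(m2) >= 0.01)
  expect_setequal(extract_core(count_table(m2))$otu_ids,
                  c("OtuHigh", "OtuThin"))
  # empty cores report near misses: one OTU fails prevalence, one abundance
  m3 <- matrix(0L, M, 2, dimnames = list(ids, c("OtuRare", "OtuThin2")))
  m3[1:30, "OtuRare"] <- 1000L  # fails prevalence (30/47)
  m3[, "OtuThin2"] <- 1L        # fails abundance (47/30047 = 0.16%)
  expect_error(extract_core(count_table(m3)), "near")
})

test_that("replicate ordering policies behave as documented", {
  m <- matrix(1L, 4, 2, dimnames = list(c("b", "d", "a", "c"), c("x", "y")))
  x <- count_table(m)
  expect_equal(sample_ids(x)[order_replicates(x, "sorted_id")],
               c("a", "b", "c", "d"))
  expect_equal(order_replicates(x, "given"), 1:4)
  expect_identical(order_replicates(x, "random", seed = 3),
                   order_replicates(x, "random", seed = 3))
})

test_that("variance decomposition matches the diagonal closed form", {
  # J_ii = 1 - r = 0.5, sigma = 1: v = 1/(1-0.25) = 4/3,
  # shares (interactions, density dependence, stochasticity) = (0, 1/4, 3/4)
  sh <- spongenet:::decompose_one(r = c(0.5, 0.5), k = c(1, 2),
                                  alpha = matrix(0, 2, 2), sigma = c(1, 1))
  expect_equal(unname(sh$v), c(4 / 3, 4 / 3), tolerance = 1e-9)
  expect_equal(unname(sh$shares[, 1]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(sh$shares[, 2]), c(0.25, 0.25), tolerance = 1e-9)
  expect_equal(unname(sh$shares[, 3]), c(0.75, 0.75), tolerance = 1e-9)
  expect_equal(rowSums(sh$shares), c(1, 1), tolerance = 1e-12)
})

test_that("the Lyapunov solution matches long-run simulated variance", {
  withr::with_seed(11, {
    J <- matrix(c(0.5, 0.15, -0.1, 0.6), 2, 2)
    sig <- c(0.8, 1.2)
    V <- spongenet:::solve_dlyap(J, diag(sig^2))
    n <- c(0, 0); draws <- matrix(0, 2, 1e5)
    for (t in 1:1e5) {
      n <- as.vector(J %*% n) + rnorm(2, 0, sig)
      draws[, t] <- n
    }
    expect_equal(diag(V), c(var(draws[1, ]), var(draws[2, ])),
                 tolerance = 0.05)
  })
})

test_that("posterior sampling validates its inputs", {
  y <- matrix(rpois(12, 50), 1, 12)
  expect_error(sample_posterior(y, quick_lv_cfg()), "at least 2")
  y2 <- matrix(rpois(10, 50), 2, 5)
  expect_error(sample_posterior(y2, quick_lv_cfg()), "at least 10")
})

test_that("the sampler returns a coherent posterior on a small community", {
  truth <- random_lv_truth(S = 3, p_link = 0.2, seed = 5)
  sim <- gen_lv_series(truth, n_replicates = 60, depth_mean = 2e4, seed = 6)
  post <- sample_posterior(t(sim$counts$counts), quick_lv_cfg(seed = 3))
  expect_s3_class(post, "lv_posterior")
  expect_equal(post$S, 3)
  expect_length(post$pip, 6)
  expect_true(all(post$pip >= 0 & post$pip <= 1))
  k_draws <- do.call(rbind, lapply(post$chains, `[[`, "k"))
  expect_true(all(k_draws > 0))
  g_draws <- do.call(rbind, lapply(post$chains, `[[`, "g"))
  expect_true(all(g_draws %in% c(0L, 1L)))
  expect_true(all(is.finite(do.call(rbind, lapply(post$chains, `[[`, "r")))))
  expect_length(post$gamma_jumps, 6)
  expect_true(any(post$gamma_jumps > 0)) # indicators actually mix
  expect_true(is.finite(post$diagnostics$max_rhat))
  s <- lv_summary(post)
  expect_equal(nrow(s$parameters), 9)
  expect_equal(nrow(s$interactions), 6)

  vs <- variance_decomposition(post)
  sh <- as.matrix(vs$shares[, c("interactions", "density_dependence",
                                "stochasticity")])
  expect_equal(unname(rowSums(sh)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(sh >= 0))
  expect_lt(vs$skip_fraction, 0.5)
})

test_that("representative networks follow the posterior link count", {
  post <- fake_lv_posterior()
  # inclusion probabilities 0.9, 0.8, 0.2, 0.1, 0, 0 -> mean links = 2
  rn <- representative_network(post)
  expect_equal(rn$n_links, 2)
  expect_setequal(rn$links$inclusion_prob, c(0.9, 0.8))
  expect_equal(rn$connectance, 2 / 6)
  expect_lt(rn$connectance_gap * 6, 1) # within one link of posterior mean
  expect_equal(rn$links$sign, c(-1, 1))
})

test_that("interaction types cover the ecological taxonomy", {
  base <- fake_lv_posterior()
  rn <- representative_network(base)
  # OtuA -(neg)-> OtuB, OtuA -(pos)-> OtuC, no reverse links
  ty <- classify_interactions(rn)
  expect_equal(as.integer(ty$tally[c("amensalism", "commensalism", "none")]),
               c(1L, 1L, 1L))
  # force a mutualism: both directions positive
  rn2 <- rn
  rn2$links <- data.frame(from = c("OtuA", "OtuB"), to = c("OtuB", "OtuA"),
                          sign = c(1, 1), inclusion_prob = c(0.9, 0.8),
                          mean_strength = c(0.5, 0.4))
  expect_equal(unname(classify_interactions(rn2)$tally[["mutualism"]]), 1L)
  rn3 <- rn2; rn3$links$sign <- c(-1, -1)
  expect_equal(unname(classify_interactions(rn3)$tally[["competition"]]), 1L)
  rn4 <- rn2; rn4$links$sign <- c(1, -1)
  expect_equal(unname(classify_interactions(rn4)$tally[["exploitation"]]), 1L)
})

test_that("connectance arithmetic matches its definition", {
  post <- fake_lv_posterior(pip_target = c(1, 1, 1, 1, 1, 0),
                            alpha_mean = c(-1, 0.5, 0.3, -0.2, 0.4, 0))
  rn <- representative_network(post)
  expect_equal(rn$n_links, 5)
  expect_equal(rn$connectance, 5 / (3 * 2))
})

test_that("the sampler agrees with an independent JAGS implementation", {
  # two-species null system with strong mean reversion, where the
  # posterior is well identified and both samplers converge quickly
  truth <- lv_ground_truth(r = c(1, 1), k = c(0.8, 0.5),
                           alpha = matrix(0, 2, 2), sigma = c(0.3, 0.3))
  sim <- gen_lv_series(truth, n_replicates = 150, depth_mean = 2e4, seed = 13)
  y <- t(sim$counts$counts)
  cfg <- lv_config("test", chains = 2, iterations = 8000, burn_in = 3000,
                   thin = 4, pilot_iterations = 1500, seed = 5)
  post <- sample_posterior(y, cfg)
  r_own <- colMeans(do.call(rbind, lapply(post$chains, `[[`, "r")))
  k_own <- colMeans(do.call(rbind, lapply(post$chains, `[[`, "k")))
  s_own <- colMeans(do.call(rbind, lapply(post$chains, `[[`, "sigma")))

  ei <- post$ei; ej <- post$ej; E <- length(ei)
  model <- "
  model {
    for (i in 1:S) {
      r[i] ~ dnorm(0, 0.1)
      k[i] ~ dexp(1)
      sig[i] ~ dnorm(0, 1) T(0,)
      taup[i] <- pow(sig[i], -2)
      n[i, 1] ~ dnorm(log(k[i]), 1)
      A[i, i] <- 0
    }
    for (e in 1:E) {
      g[e] ~ dbern(P)
      alpha[e] ~ dnorm((1 - g[e]) * pm[e],
                       g[e] / vslab[e] + (1 - g[e]) / pv[e])
      A[ei[e], ej[e]] <- g[e] * alpha[e]
    }
    for (m in 1:M) {
      Pi[m] ~ dnorm(0, 1.0E-4)
      for (i in 1:S) {
        Nl[i, m] <- exp(n[i, m])
        y[i, m] ~ dpois(exp(n[i, m] + logN[m] + Pi[m]))
      }
    }
    for (m in 2:M) {
      for (i in 1:S) {
        n[i, m] ~ dnorm(n[i, m - 1] + r[i] * (1 - (Nl[i, m - 1] -
          inprod(A[i, 1:S], Nl[1:S, m - 1])) / k[i]), taup[i])
      }
    }
  }"
  slab_var <- cfg$slab_multiplier * post$pseudo$var
  dat <- list(S = 2, M = ncol(y), E = E, ei = ei, ej = ej, y = y,
              logN = log(colSums(y)), P = cfg$inclusion_prob,
              pm = post$pseudo$mean, pv = post$pseudo$var,
              vslab = slab_var)
  inits <- list(n = log(sweep(y, 2, colSums(y), "/") + 1e-6),
                .RNG.name = "base::Mersenne-Twister", .RNG.seed = 1)
  jm <- rjags::jags.model(textConnection(model), data = dat, inits = inits,
                          n.chains = 2, n.adapt = 1000, quiet = TRUE)
  sm <- rjags::jags.samples(jm, c("r", "k", "g", "sig"), n.iter = 8000,
                            thin = 4, progress.bar = "none")
  r_jags <- apply(sm$r, 1, mean)
  k_jags <- apply(sm$k, 1, mean)
  s_jags <- apply(sm$sig, 1, mean)
  pip_jags <- apply(sm$g, 1, mean)

  # tolerances sized to the Monte Carlo spread of the two samplers:
  # carrying capacities and noise converge fast, growth rates are
  # diffuse (prior variance 10), indicators have low effective size
  expect_equal(k_own, k_jags, tolerance = 0.15)
  expect_lt(max(abs(s_own - s_jags)), 0.05)
  expect_lt(max(abs(r_own - r_jags)), 0.35)
  expect_lt(max(abs(post$pip - pip_jags)), 0.1)
})
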