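test_that("community generation conserves depth and is reproducible", {
  spec <- community_spec(n_hosts = 6, n_otus = 80, replicates_per_host = 4,
                         depth = 1500, n_seawater_samples = 3,
                         gen_min = 4, spec_max = 2, seed = 7)
  com <- gen_bipartite_community(spec)
  expect_true(all(sample_totals(com$counts) == 1500))
  com2 <- gen_bipartite_community(spec)
  expect_identical(com$counts$counts, com2$counts$counts)
  expect_identical(com$truth, com2$truth)
  expect_true(all(com$truth$degree >= 1 & com$truth$degree <= 6))
  expect_setequal(unique(com$meta$habitat), c("sponge", "seawater"))
})

test_that("full prevalence puts every OTU in all replicates of its hosts", {
  spec <- community_spec(n_hosts = 4, n_otus = 25, replicates_per_host = 3,
                         prevalence_by_class = c(specialist = 1,
                                                 generalist = 1,
                                                 opportunist = 1),
                         abundance_law = c(meanlog = 0, sdlog = 0.5),
                         depth = 1e5, gen_min = 3, spec_max = 2, seed = 3)
  com <- gen_bipartite_community(spec)
  sp <- com$meta$host_species[match(sample_ids(com$counts), com$meta$sample_id)]
  for (o in seq_len(nrow(com$truth))) {
    hosts <- com$truth$hosts[[o]]
    rows <- which(sp %in% hosts)
    expect_true(all(com$counts$counts[rows, com$truth$otu_id[o]] > 0),
                label = paste("OTU", o, "present in all host replicates"))
  }
})

test_that("class windows respect explicit class fractions", {
  spec <- community_spec(n_hosts = 60, n_otus = 300,
                         class_fractions = c(0.5, 0.2, 0.3),
                         gen_min = 40, spec_max = 5, seed = 1)
  com <- gen_bipartite_community(spec)
  tab <- table(com$truth$class)
  expect_equal(as.integer(tab[c("specialist", "generalist", "opportunist")]),
               c(150L, 60L, 90L))
  expect_true(all(com$truth$degree[com$truth$class == "specialist"] < 5))
  expect_true(all(com$truth$degree[com$truth$class == "generalist"] > 40))
})

test_that("single-species dynamics settle at log carrying capacity", {
  truth <- lv_ground_truth(r = 0.5, k = 0.8, alpha = matrix(0, 1, 1),
                           sigma = 1e-12)
  sim <- gen_lv_series(truth, n_replicates = 10, depth_mean = 1e4, seed = 1)
  expect_true(all(abs(sim$latent - log(0.8)) < 1e-6))
})

test_that("a strong negative interaction depresses the victim's abundance", {
  base <- lv_ground_truth(r = c(0.5, 0.5), k = c(1, 0.5),
                          alpha = matrix(0, 2, 2), sigma = c(0.05, 0.05))
  harmed <- base
  harmed$alpha[1, 2] <- -0.5; harmed$gamma[1, 2] <- 1
  s0 <- gen_lv_series(base, n_replicates = 400, depth_mean = 2e4, seed = 5)
  s1 <- gen_lv_series(harmed, n_replicates = 400, depth_mean = 2e4, seed = 5)
  expect_lt(mean(s1$latent[1, ]), mean(s0$latent[1, ]))
  # equilibrium of the harmed species shifts to k1 + a12 k2 = 0.75
  expect_equal(mean(s1$latent[1, ]), log(0.75), tolerance = 0.05)
})

test_that("noise-free dynamics are constant across replicates after burn-in", {
  truth <- lv_ground_truth(r = c(0.4, 0.6), k = c(0.5, 0.9),
                           alpha = matrix(0, 2, 2), sigma = c(0, 0))
  sim <- gen_lv_series(truth, n_replicates = 5, depth_mean = 1e4,
                       pi_sd = 0, seed = 2)
  expect_true(all(abs(sim$latent - sim$latent[, 1]) < 1e-12))
})

test_that("diverging dynamics abort naming the offending OTU", {
  truth <- lv_ground_truth(r = c(3, 0.5), k = c(1, 1),
                           alpha = matrix(c(0, 0, -50, 0), 2, 2,
                                          byrow = TRUE),
                           sigma = c(0.01, 0.01))
  expect_error(gen_lv_series(truth, n_replicates = 10, seed = 1),
               "diverged for OTU")
})

test_that("latent variance matches the AR(1) closed form without interactions", {
  # linearized map at equilibrium: J = 1 - r, stationary var s^2/(1-J^2)
  r <- 0.6; sig <- 0.1
  truth <- lv_ground_truth(r = r, k = 0.7, alpha = matrix(0, 1, 1),
                           sigma = sig)
  sim <- gen_lv_series(truth, n_replicates = 1e4, depth_mean = 1e4, seed = 9)
  v_emp <- var(sim$latent[1, ])
  v_theory <- sig^2 / (1 - (1 - r)^2)
  expect_equal(v_emp, v_theory, tolerance = 0.1)
})

test_that("hit-table scenarios deliver their advertised structure", {
  clean <- gen_hit_table(n_queries = 4, scenario = "clean", seed = 1)
  expect_true(all(clean$percent_identity > 75))
  expect_true(all(clean$ref_cluster == "SC55"))
  expect_equal(nrow(clean), 40)

  low <- gen_hit_table(scenario = "below_threshold", seed = 1)
  expect_true(all(low$percent_identity < 75))

  mb <- gen_hit_table(n_queries = 1, scenario = "majority_boundary",
                      n_majority = 6, seed = 1)
  expect_equal(sum(mb$ref_cluster == "SC55", na.rm = TRUE), 6)
  expect_equal(mb$percent_identity[1], mb$percent_identity[2]) # tie at top
  expect_identical(gen_hit_table(seed = 3), gen_hit_table(seed = 3))
})

test_that("Brownian traits scale with tree depth; random traits do not", {
  # two-tip trees: (xA - xB) / sqrt(2 T) is standard normal under BM
  z <- vapply(1:800, function(s) {
    tt <- gen_tree_and_traits(2, model = "BM", seed = s)
    T_depth <- ape::vcv.phylo(tt$tree)[1, 1]
    (tt$traits[1] - tt$traits[2]) / sqrt(2 * T_depth)
  }, 0)
  expect_equal(var(z), 1, tolerance = 0.15)
  expect_equal(mean(z), 0, tolerance = 0.1)
  # i.i.d. traits on a 50-tip tree have weak phylogenetic signal
  ks <- vapply(1:30, function(s) {
    tt <- gen_tree_and_traits(50, model = "random", seed = s)
    blombergs_k(tt$tree, tt$traits, n_perm = 0, seed = 1)$statistic
  }, 0)
  expect_lt(mean(ks), 0.5)
  expect_identical(gen_tree_and_traits(10, seed = 4)$traits,
                   gen_tree_and_traits(10, seed = 4)$traits)
})

test_that("random ground truths are stable and feasible", {
  for (s in 1:5) {
    tr <- random_lv_truth(S = 6, p_link = 0.15, seed = s)
    eq <- spongenet:::lv_equilibrium(tr$alpha, tr$k)
    expect_true(all(eq > 0))
    J <- spongenet:::lv_jacobian(tr$r, tr$k, tr$alpha, eq)
    expect_lt(max(Mod(eigen(J)$values)), 1)
    expect_true(all(tr$alpha[tr$gamma == 0] == 0))
  }
})
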