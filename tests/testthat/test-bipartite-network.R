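test_that("network construction applies the occupancy threshold and link rule", {
  com <- toy_network_community()
  # OtuA occupies 8 samples, OtuB 4, OtuC 12
  net <- build_network(com$counts, com$meta, min_samples = 5)
  expect_setequal(net$otu_nodes, c("OtuA", "OtuC"))
  net1 <- build_network(com$counts, com$meta, min_samples = 1)
  links <- paste(net1$links$host, net1$links$otu)
  expect_setequal(links, c("S1 OtuA", "S2 OtuA", "S2 OtuB",
                           "S1 OtuC", "S2 OtuC", "S3 OtuC"))
  expect_equal(unname(net1$otu_degree[c("OtuA", "OtuB", "OtuC")]), c(2, 1, 3))
  expect_equal(unname(net1$host_degree[c("S1", "S2", "S3")]), c(2, 3, 1))
  # boundary: exactly min_samples occupancy is included (OtuB occupies 4)
  net4 <- build_network(com$counts, com$meta, min_samples = 4)
  expect_true("OtuB" %in% net4$otu_nodes)
})

test_that("an OTU confined to one well-sampled species has degree 1", {
  com <- toy_network_community()
  net <- build_network(com$counts, com$meta, min_samples = 4)
  expect_equal(unname(net$otu_degree["OtuB"]), 1)
})

test_that("empty networks raise an error naming the filter", {
  com <- toy_network_community()
  expect_error(build_network(com$counts, com$meta, min_samples = 99),
               ">= 99 samples")
})

test_that("ccdf is a proper complementary cumulative distribution", {
  cc <- ccdf(c(1, 1, 2))
  expect_equal(cc$pc, c(1, 1 / 3))
  expect_equal(ccdf(rep(7, 5))$pc, 1)
  # duplicating every node leaves the distribution unchanged
  d <- c(1, 2, 2, 5, 9)
  expect_equal(ccdf(c(d, d)), ccdf(d))
  expect_true(all(diff(ccdf(d)$pc) <= 0))
  expect_equal(ccdf(d)$pc[1], 1)
  # lower-tail variant
  expect_equal(ccdf(c(1, 1, 2), lower_tail = TRUE)$pc, c(2 / 3, 1))
})

test_that("truncated power-law fit recovers exact-curve parameters", {
  k <- 1:81
  pts <- data.frame(k = k, pc = k^(-0.32) * exp(-k / 7.44))
  fit <- fit_truncated_power_law(pts)
  expect_equal(fit$a, 0.32, tolerance = 1e-3)
  expect_equal(fit$b, 7.44, tolerance = 1e-3)
  expect_false(fit$no_cutoff_support)
  # pure power law: fitted cutoff escapes beyond the data range
  pure <- data.frame(k = k, pc = k^(-0.7))
  fit2 <- fit_truncated_power_law(pure)
  expect_true(fit2$no_cutoff_support)
  expect_error(fit_truncated_power_law(pts[1:3, ]), "at least 4")
})

test_that("exponential fit recovers the host-side scale", {
  k <- seq(10, 7000, by = 50)
  pts <- data.frame(k = k, pc = exp(-k / 1849))
  fit <- fit_exponential(pts)
  expect_equal(fit$lambda, 1849, tolerance = 1e-3 * 1849)
  flat <- data.frame(k = k[1:20], pc = rep(0.9, 20))
  expect_true(fit_exponential(flat)$no_decay_support)
  expect_error(fit_exponential(pts[1:2, ]), "at least 3")
})

test_that("null networks preserve node and link counts with expected degrees", {
  com <- toy_network_community()
  spec <- community_spec(n_hosts = 10, n_otus = 150, replicates_per_host = 2,
                         depth = 5000, gen_min = 8, spec_max = 3, seed = 21)
  big <- gen_bipartite_community(spec)
  net <- build_network(big$counts, big$meta, min_samples = 1)
  nn <- null_network(net, seed = 1)
  expect_equal(length(nn$otu_nodes), length(net$otu_nodes))
  expect_equal(length(nn$host_nodes), length(net$host_nodes))
  expect_equal(nrow(nn$links), nrow(net$links))
  expect_identical(null_network(net, seed = 5)$links,
                   null_network(net, seed = 5)$links)
  # uniform rewiring: mean OTU degree equals L / n_otus on average
  mean_deg <- mean(vapply(1:100, function(s)
    mean(null_network(net, seed = s)$otu_degree), 0))
  expect_equal(mean_deg, nrow(net$links) / length(net$otu_nodes),
               tolerance = 0.02)
})

test_that("degree classes split at strict thresholds with prevalence fractions", {
  deg <- c(4, 5, 50, 51)
  hosts <- paste0("H", 1:60)
  # synthetic network object with four OTUs of known degree
  links <- do.call(rbind, lapply(seq_along(deg), function(i)
    data.frame(host = hosts[seq_len(deg[i])], otu = paste0("O", i))))
  ids <- unlist(lapply(seq_along(deg), function(i)
    paste0(hosts, "_r", i)[seq_len(deg[i])]))
  # one replicate per host; OTU i present in all its hosts' replicates
  m <- matrix(0L, length(hosts), length(deg),
              dimnames = list(paste0(hosts, "_r1"), paste0("O", 1:4)))
  meta <- data.frame(sample_id = rownames(m), host_species = hosts,
                     stringsAsFactors = FALSE)
  for (i in seq_along(deg)) m[seq_len(deg[i]), i] <- 1L
  net <- build_network(count_table(m), meta, min_samples = 1)
  cls <- classify_otus(net, count_table(m), meta)
  got <- cls$classification
  expect_equal(got$class[match(paste0("O", 1:4), got$otu_id)],
               c("specialist", "intermediate", "intermediate", "generalist"))
  expect_true(all(got$prevalence_fraction == 1))
  expect_equal(cls$diagnostics$mean_degree, mean(deg))
})

test_that("prevalence fractions count samples of linked species only", {
  com <- toy_network_community()
  m <- com$counts$counts
  m["S1_2", "OtuA"] <- 0L  # OtuA in 3/4 of S1 and 4/4 of S2
  net <- build_network(count_table(m), com$meta, min_samples = 1)
  cls <- classify_otus(net, count_table(m), com$meta)$classification
  expect_equal(cls$prevalence_fraction[cls$otu_id == "OtuA"], 7 / 8)
  expect_equal(cls$prevalence_fraction[cls$otu_id == "OtuC"], 1)
})

test_that("prevalence spline interpolates structure and spans the degree range", {
  cl <- data.frame(otu_id = paste0("o", 1:30), degree = 1:30,
                   class = "intermediate",
                   prevalence_fraction = rep(0.6, 30))
  sp <- prevalence_spline(cl)
  expect_equal(sp$fit, rep(0.6, nrow(sp)), tolerance = 1e-6)
  expect_equal(range(sp$k), c(1, 30))
  # near-interpolation of a smooth noiseless trend at low smoothing
  cl2 <- cl; cl2$prevalence_fraction <- seq(0.2, 0.9, length.out = 30)
  sp2 <- prevalence_spline(cl2, smoothing = "fixed", spar = 0.1)
  at_data <- approx(sp2$k, sp2$fit, xout = cl2$degree)$y
  expect_equal(at_data, cl2$prevalence_fraction, tolerance = 1e-3)
})

test_that("core degree enrichment finds the crossing degree", {
  spec <- community_spec(n_hosts = 12, n_otus = 200, replicates_per_host = 2,
                         depth = 5000, gen_min = 8, spec_max = 3, seed = 8)
  com <- gen_bipartite_community(spec)
  net <- build_network(com$counts, com$meta, min_samples = 1)
  # core = all OTUs: curve collapses onto the 1:1 line
  all_core <- core_degree_enrichment(net, net$otu_nodes)
  expect_equal(all_core$curve$core_frac, all_core$curve$global_frac)
  # core = top-degree OTUs: curve sits above the global fraction
  top <- names(sort(net$otu_degree, decreasing = TRUE))[1:20]
  enr <- core_degree_enrichment(net, top)
  above <- enr$curve$k > min(net$otu_degree)
  expect_true(all(enr$curve$core_frac[above] >= enr$curve$global_frac[above]))
  expect_false(is.na(enr$break_k))
  expect_error(core_degree_enrichment(net, character(0)), "empty")
})
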