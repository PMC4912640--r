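# Shared in-code fixtures for the suite.  Everything is generated
# deterministically; nothing is read from disk except through the
# package's own writers.

toy_counts <- function() {
  m <- rbind(
    SpA_r1 = c(5, 0, 3, 10),
    SpA_r2 = c(4, 0, 0, 12),
    SpA_r3 = c(6, 1, 2, 9),
    SpB_r1 = c(0, 7, 0, 20),
    SpB_r2 = c(0, 8, 1, 18),
    Sea_1  = c(0, 2, 50, 100),
    Sea_2  = c(1, 3, 60, 90))
  colnames(m) <- c("Otu001", "Otu002", "Otu003", "Otu004")
  count_table(m)
}

toy_meta <- function() {
  data.frame(
    sample_id = c("SpA_r1", "SpA_r2", "SpA_r3", "SpB_r1", "SpB_r2",
                  "Sea_1", "Sea_2"),
    host_species = c("SpA", "SpA", "SpA", "SpB", "SpB", NA, NA),
    habitat = c(rep("sponge", 5), "seawater", "seawater"),
    stringsAsFactors = FALSE)
}

# Replicate-level community for network tests: 3 species x 4
# replicates, hand-designed presence so link sets are enumerable.
toy_network_community <- function() {
  species <- rep(c("S1", "S2", "S3"), each = 4)
  ids <- paste0(species, "_", rep(1:4, 3))
  m <- matrix(0L, 12, 3, dimnames = list(ids, c("OtuA", "OtuB", "OtuC")))
  m[species == "S1", "OtuA"] <- 5L       # OtuA: S1 + S2 (degree 2)
  m[species == "S2", "OtuA"] <- 2L
  m[species == "S2", "OtuB"] <- 7L       # OtuB: S2 only (degree 1)
  m[, "OtuC"] <- 1L                      # OtuC: everywhere (degree 3)
  list(counts = count_table(m),
       meta = data.frame(sample_id = ids, host_species = species,
                         habitat = "sponge", stringsAsFactors = FALSE))
}

# A small posterior object with known draws, for testing the
# representative-network extraction rules without MCMC.
fake_lv_posterior <- function(pip_target = c(0.9, 0.8, 0.2, 0.1, 0, 0),
                              alpha_mean = c(-1, 0.5, 0.3, -0.2, 0, 0),
                              S = 3, n_draw = 200) {
  stopifnot(S == 3) # 6 directed edges
  ei <- c(2, 3, 1, 3, 1, 2); ej <- c(1, 1, 2, 2, 3, 3)
  g <- sapply(pip_target, function(p) rep(c(1, 0), round(c(p, 1 - p) * n_draw)))
  a <- matrix(rep(alpha_mean, each = n_draw), n_draw, 6)
  chains <- list(list(r = matrix(0.5, n_draw, S), k = matrix(1, n_draw, S),
                      sigma = matrix(0.1, n_draw, S), alpha = a, g = g,
                      Pi = matrix(0, n_draw, 10), jumps = rep(1L, 6)))
  structure(list(chains = chains, S = S, M = 10,
                 otu_ids = c("OtuA", "OtuB", "OtuC"),
                 ei = ei, ej = ej, cfg = lv_config("test"),
                 pip = colMeans(g), alpha_mean = colMeans(a),
                 alpha_mean_active = alpha_mean,
                 gamma_jumps = rep(1L, 6),
                 diagnostics = list(max_rhat = 1, rhat_warn = FALSE)),
            class = "lv_posterior")
}

quick_lv_cfg <- function(...) {
  lv_config("test", chains = 1, iterations = 1200, burn_in = 600, thin = 3,
            pilot_iterations = 400, ...)
}
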