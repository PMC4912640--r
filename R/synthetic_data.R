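#' Specification for a synthetic host-microbiome community
#'
#' Describes the statistical structure the downstream analyses assume: a
#' host x OTU presence network whose OTU-side complementary cumulative
#' degree distribution follows a truncated power law
#' Pc(k) = k^-a exp(-k/b), an exponentially heterogeneous host side,
#' replicate-level presence governed by class-specific prevalence
#' (specialists and generalists consistently present, opportunists
#' sporadic), lognormal base abundances, and fixed sequencing depth.
#'
#' `class_fractions = NULL` (the default) assigns classes from the
#' degree law itself: every OTU's degree is drawn from the law on
#' `[1, n_hosts]` and its class follows from the degree windows
#' (specialist < `spec_max` hosts, generalist > `gen_min`, opportunist
#' in between), so the overall degree distribution is exactly the
#' target law.  Explicit fractions instead draw each class's degree
#' from the law truncated to its window.
#'
#' @param n_hosts number of host species (>= 2).
#' @param n_otus number of OTUs.
#' @param replicates_per_host replicate specimens per host species.
#' @param otu_degree_law c(a = exponent, b = cutoff in hosts) of the
#'   truncated power law.
#' @param host_degree_scale scale of the exponential host-weight
#'   heterogeneity shaping the host-side degree distribution.
#' @param class_fractions NULL, or proportions c(specialist,
#'   generalist, opportunist) summing to 1.
#' @param prevalence_by_class probability that an OTU occurs in a
#'   replicate of a connected host, per class.
#' @param abundance_law c(meanlog, sdlog) of lognormal base abundances.
#' @param depth reads per sample.
#' @param spec_max,gen_min degree windows separating the classes.
#' @param n_seawater_samples,n_seawater_otus optional seawater
#'   background community; a fraction of host OTUs
#'   (`seawater_overlap`) also occurs in seawater.
#' @param seawater_overlap fraction of host-associated OTUs leaking
#'   into the seawater background.
#' @param seed integer seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_hosts = 81, n_otus = 3000, replicates_per_host = 8,
                           otu_degree_law = c(a = 0.32, b = 7.44),
                           host_degree_scale = 1,
                           class_fractions = NULL,
                           prevalence_by_class = c(specialist = 0.9,
                                                   generalist = 0.9,
                                                   opportunist = 0.2),
                           abundance_law = c(meanlog = 0, sdlog = 1.5),
                           depth = 10000,
                           spec_max = 5, gen_min = 50,
                           n_seawater_samples = 0, n_seawater_otus = 200,
                           seawater_overlap = 0.05,
                           seed = 1) {
  if (n_hosts < 2) stop("need at least 2 host species")
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(class_fractions)) {
    if (abs(sum(class_fractions) - 1) > 1e-8)
      stop("class_fractions must sum to 1")
    if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  }
  if (any(prevalence_by_class < 0 | prevalence_by_class > 1))
    stop("prevalences must lie in [0, 1]")
  structure(list(n_hosts = n_hosts, n_otus = n_otus,
                 replicates_per_host = replicates_per_host,
                 otu_degree_law = otu_degree_law,
                 host_degree_scale = host_degree_scale,
                 class_fractions = class_fractions,
                 prevalence_by_class = prevalence_by_class,
                 abundance_law = abundance_law, depth = depth,
                 spec_max = spec_max, gen_min = gen_min,
                 n_seawater_samples = n_seawater_samples,
                 n_seawater_otus = n_seawater_otus,
                 seawater_overlap = seawater_overlap,
                 seed = seed), class = "community_spec")
}

# Discrete degree pmf on 1..kmax whose complementary cumulative
# distribution follows C(k) = k^-a exp(-k/b): pmf(k) = C(k) - C(k+1),
# C(kmax+1) := 0, normalized by C(1).  (A pmf proportional to the law
# itself would give a CCDF of a different shape and the refit oracle
# would not recover the parameters.)
tpl_pmf <- function(a, b, kmax) {
  k <- seq_len(kmax + 1)
  C <- k^(-a) * exp(-k / b)
  C[kmax + 1] <- 0
  p <- C[seq_len(kmax)] - C[-1]
  p / sum(p)
}

# Inverse-CDF sampler on the discrete law, optionally restricted to a
# degree window [lo, hi].
sample_tpl_degrees <- function(n, a, b, kmax, lo = 1, hi = kmax, seed = NULL) {
  pmf <- tpl_pmf(a, b, kmax)
  win <- lo:hi
  p <- pmf[win]
  if (sum(p) <= 0) stop("degree window [", lo, ", ", hi, "] has no support")
  draw <- function() win[findInterval(stats::runif(n), cumsum(p / sum(p))) + 1L]
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a replicate-level community with bipartite structure
#'
#' Draws each OTU's host degree from the discrete truncated power law
#' by inverse CDF, links it to hosts by exponential-weight sampling
#' without replacement, then generates replicate-level presence
#' (Bernoulli with class prevalence) and counts (multinomial at the
#' requested depth over present OTUs with lognormal base abundances).
#' Column/row sums of the returned table equal `depth` exactly for
#' every sample.
#'
#' @param spec a [community_spec].
#' @return list with `counts` ([count_table], samples x OTUs), `meta`
#'   (sample metadata), and `truth` (per-OTU degree, hosts, class,
#'   base abundance).
#' @export
gen_bipartite_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, gen_bipartite_community_impl(spec))
}

gen_bipartite_community_impl <- function(spec) {
  a <- spec$otu_degree_law[["a"]]; b <- spec$otu_degree_law[["b"]]
  H <- spec$n_hosts; S <- spec$n_otus
  spec_hi <- min(spec$spec_max - 1L, H)
  opp_hi <- min(spec$gen_min, H)

  if (is.null(spec$class_fractions)) {
    deg <- sample_tpl_degrees(S, a, b, H)
    cls <- ifelse(deg < spec$spec_max, "specialist",
                  ifelse(deg > spec$gen_min, "generalist", "opportunist"))
  } else {
    n_by <- stats::setNames(round(spec$class_fractions * S),
                            c("specialist", "generalist", "opportunist"))
    n_by[1] <- S - sum(n_by[-1]) # keep the total exact
    windows <- list(specialist = c(1L, spec_hi),
                    generalist = c(min(spec$gen_min + 1L, H), H),
                    opportunist = c(min(spec$spec_max, H), opp_hi))
    deg <- integer(0); cls <- character(0)
    for (cl in names(n_by)) {
      if (n_by[cl] == 0) next
      w <- windows[[cl]]
      deg <- c(deg, sample_tpl_degrees(n_by[cl], a, b, H, w[1], w[2]))
      cls <- c(cls, rep(cl, n_by[cl]))
    }
    perm <- sample.int(S)
    deg <- deg[perm]; cls <- cls[perm]
  }

  host_ids <- sprintf("Host%02d", seq_len(H))
  otu_ids <- sprintf("Otu%05d", seq_len(S))
  host_w <- stats::rexp(H, rate = 1 / spec$host_degree_scale)
  hosts_of <- lapply(deg, function(k) {
    sample.int(H, k, prob = host_w)
  })

  base_ab <- stats::rlnorm(S, spec$abundance_law[["meanlog"]],
                           spec$abundance_law[["sdlog"]])
  prev <- spec$prevalence_by_class[cls]

  R <- spec$replicates_per_host
  smp_ids <- as.vector(t(outer(host_ids, seq_len(R),
                               function(h, r) sprintf("%s_rep%02d", h, r))))
  counts <- matrix(0, nrow = H * R, ncol = S,
                   dimnames = list(smp_ids, otu_ids))
  linked <- vector("list", H) # OTU indices linked to each host
  for (h in seq_len(H)) linked[[h]] <- integer(0)
  for (o in seq_len(S)) for (h in hosts_of[[o]])
    linked[[h]] <- c(linked[[h]], o)

  row <- 0L
  for (h in seq_len(H)) {
    lo <- linked[[h]]
    for (r in seq_len(R)) {
      row <- row + 1L
      if (!length(lo)) next
      present <- lo[stats::runif(length(lo)) < prev[lo]]
      if (!length(present)) present <- lo[which.max(base_ab[lo])]
      p <- base_ab[present]
      counts[row, present] <- stats::rmultinom(1, spec$depth, p / sum(p))[, 1]
    }
  }

  meta <- data.frame(sample_id = smp_ids,
                     host_species = rep(host_ids, each = R),
                     habitat = "sponge", stringsAsFactors = FALSE)

  if (spec$n_seawater_samples > 0) {
    sw_otus <- sprintf("SwOtu%04d", seq_len(spec$n_seawater_otus))
    leak <- sample.int(S, max(1, round(spec$seawater_overlap * S)))
    pool <- c(sw_otus, otu_ids[leak])
    sw_ab <- stats::rlnorm(length(pool), spec$abundance_law[["meanlog"]],
                           spec$abundance_law[["sdlog"]])
    sw_ids <- sprintf("Seawater_%02d", seq_len(spec$n_seawater_samples))
    swm <- matrix(0, spec$n_seawater_samples, length(sw_otus) + S,
                  dimnames = list(sw_ids, c(colnames(counts), sw_otus)))
    for (i in seq_len(spec$n_seawater_samples)) {
      cnt <- stats::rmultinom(1, spec$depth, sw_ab / sum(sw_ab))[, 1]
      swm[i, pool] <- cnt
    }
    counts <- cbind(counts, matrix(0, nrow(counts), length(sw_otus),
                                   dimnames = list(NULL, sw_otus)))
    counts <- rbind(counts, swm)
    meta <- rbind(meta, data.frame(sample_id = sw_ids,
                                   host_species = NA_character_,
                                   habitat = "seawater",
                                   stringsAsFactors = FALSE))
  }

  truth <- data.frame(otu_id = otu_ids, degree = deg, class = cls,
                      base_abundance = base_ab, stringsAsFactors = FALSE)
  truth$hosts <- I(lapply(hosts_of, function(h) host_ids[h]))
  list(counts = count_table(counts), meta = meta, truth = truth)
}

#' Ground truth for a sparse Lotka-Volterra community
#'
#' Bundles intrinsic growth rates `r`, carrying capacities `k` (on the
#' scale of exponentiated latent abundance), the per-capita interaction
#' matrix `alpha` with structural zeros where the inclusion matrix
#' `gamma` is 0, and process-noise standard deviations `sigma`.
#'
#' @param r,k,sigma numeric vectors of length S (k > 0, sigma > 0).
#' @param alpha S x S interaction matrix, zero diagonal.
#' @param gamma S x S binary inclusion matrix, zero diagonal.
#' @return an `lv_ground_truth` list.
#' @export
lv_ground_truth <- function(r, k, alpha, gamma = NULL, sigma) {
  S <- length(r)
  alpha <- as.matrix(alpha)
  if (is.null(gamma)) gamma <- (alpha != 0) * 1
  gamma <- as.matrix(gamma)
  stopifnot(length(k) == S, length(sigma) == S,
            all(dim(alpha) == c(S, S)), all(dim(gamma) == c(S, S)))
  if (any(k <= 0)) stop("carrying capacities k must be positive")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  diag(alpha) <- 0; diag(gamma) <- 0
  alpha[gamma == 0] <- 0
  structure(list(r = r, k = k, alpha = alpha, gamma = gamma, sigma = sigma),
            class = "lv_ground_truth")
}

#' Draw a random stable sparse Lotka-Volterra ground truth
#'
#' Interaction pairs are included with probability `p_link`, with
#' magnitudes uniform on `alpha_range` and random sign.  Draws are
#' rejected until the community has a feasible positive equilibrium and
#' the linearized map is stable (spectral radius < 1), so simulated
#' replicate series fluctuate around coexistence rather than crashing.
#'
#' @param S number of OTUs.
#' @param p_link probability a directed interaction is present.
#' @param alpha_range magnitude range of interaction coefficients.
#' @param r_range,k_range,sigma ranges/value for growth rates,
#'   carrying capacities, and process noise.
#' @param seed integer seed.
#' @param max_tries rejection budget.
#' @return an `lv_ground_truth`.
#' @export
random_lv_truth <- function(S, p_link = 0.1, alpha_range = c(0.5, 1.5),
                            r_range = c(0.3, 0.8), k_range = c(0.2, 1),
                            sigma = 0.15, seed = 1, max_tries = 1000) {
  withr::with_seed(seed, {
    for (t in seq_len(max_tries)) {
      r <- stats::runif(S, r_range[1], r_range[2])
      k <- stats::runif(S, k_range[1], k_range[2])
      gamma <- matrix(stats::rbinom(S * S, 1, p_link), S, S)
      diag(gamma) <- 0
      alpha <- matrix(0, S, S)
      ne <- sum(gamma)
      alpha[gamma == 1] <- sample(c(-1, 1), ne, TRUE) *
        stats::runif(ne, alpha_range[1], alpha_range[2])
      tr <- lv_ground_truth(r, k, alpha, gamma, rep(sigma, S))
      eq <- lv_equilibrium(tr$alpha, tr$k)
      if (any(!is.finite(eq)) || any(eq <= 0)) next
      J <- lv_jacobian(tr$r, tr$k, tr$alpha, eq)
      if (max(Mod(eigen(J, only.values = TRUE)$values)) < 1) return(tr)
    }
    stop("no stable feasible ground truth found in ", max_tries, " tries")
  })
}

# Deterministic equilibrium N*: N*_i - sum_{j!=i} alpha_ij N*_j = k_i
# (alpha_ij is the per-capita effect of j on the growth of i; positive
# alpha promotes growth).
lv_equilibrium <- function(alpha, k) {
  S <- length(k)
  tryCatch(solve(diag(S) - alpha, k), error = function(e) rep(NA_real_, S))
}

# Jacobian of the latent log-abundance map at equilibrium Nstar:
# J_ii = 1 - (r_i/k_i) N*_i, J_ij = (r_i/k_i) alpha_ij N*_j.
lv_jacobian <- function(r, k, alpha, Nstar) {
  S <- length(r)
  J <- (r / k) * alpha * rep(Nstar, each = S)
  dim(J) <- c(S, S)
  diag(J) <- 1 - (r / k) * Nstar
  J
}

#' Simulate replicate series from the Lotka-Volterra model
#'
#' Iterates the latent log-abundance dynamics
#' n_i,m = n_i,m-1 + r_i (1 - (N_i,m-1 - sum_j alpha_ij N_j,m-1)/k_i)
#' + eps_i,m with eps ~ N(0, sigma_i^2) and N = exp(n) (positive
#' alpha_ij means OTU j promotes the growth of OTU i), starting from
#' n_i = log(k_i) and discarding `burn_in` steps, then emits counts
#' y_i,m ~ Poisson(exp(n_i,m + log(depth) + Pi_m)) with a per-replicate
#' lognormal depth offset Pi_m ~ N(0, pi_sd^2).
#'
#' @param truth an [lv_ground_truth].
#' @param n_replicates number of replicates to emit (>= 3).
#' @param depth_mean nominal reads per replicate.
#' @param burn_in discarded initial steps.
#' @param pi_sd s.d. of the per-replicate depth offset.
#' @param seed integer seed.
#' @param diverge_bound abort when |n| exceeds this bound.
#' @return list with `counts` ([count_table], replicates x OTUs),
#'   `latent` (S x M log-abundance matrix), `pi` (offsets), `depth`.
#' @export
gen_lv_series <- function(truth, n_replicates, depth_mean = 20000,
                          burn_in = 100, pi_sd = 0.1, seed = 1,
                          diverge_bound = 50) {
  stopifnot(inherits(truth, "lv_ground_truth"))
  if (n_replicates < 3) stop("need at least 3 replicates")
  S <- length(truth$r)
  A <- truth$alpha * truth$gamma
  withr::with_seed(seed, {
    n <- log(truth$k)
    lat <- matrix(NA_real_, S, n_replicates)
    for (t in seq_len(burn_in + n_replicates)) {
      N <- exp(n)
      n <- n + truth$r * (1 - (N - as.vector(A %*% N)) / truth$k) +
        stats::rnorm(S, 0, truth$sigma)
      if (any(abs(n) > diverge_bound)) {
        bad <- which.max(abs(n))
        stop("latent dynamics diverged for OTU ", bad,
             " (|n| = ", round(max(abs(n)), 1), ") at step ", t)
      }
      if (t > burn_in) lat[, t - burn_in] <- n
    }
    Pi <- stats::rnorm(n_replicates, 0, pi_sd)
    lambda <- exp(sweep(lat, 2, log(depth_mean) + Pi, "+"))
    y <- matrix(stats::rpois(S * n_replicates, lambda), S, n_replicates)
    dimnames(y) <- list(sprintf("Otu%03d", seq_len(S)),
                        sprintf("rep%03d", seq_len(n_replicates)))
    list(counts = count_table(t(y)), latent = lat, pi = Pi,
         depth = depth_mean)
  })
}

#' Generate a synthetic similarity hit table
#'
#' Emits top-10-per-query tabular hits with controlled identities and
#' reference cluster labels, for exercising the cluster-assignment
#' rules.  Scenarios: `"clean"` (all hits well above threshold, one
#' cluster), `"below_threshold"` (all identities < 75), and
#' `"majority_boundary"` (tied top hits, `n_majority` of 10 references
#' in the focal cluster).
#'
#' @param n_queries number of query OTUs.
#' @param n_refs reference pool size.
#' @param scenario one of `"clean"`, `"below_threshold"`,
#'   `"majority_boundary"`, `"random"`.
#' @param cluster name of the focal cluster label.
#' @param n_majority for `"majority_boundary"`, number of the 10 hits
#'   carrying the focal cluster label.
#' @param seed integer seed.
#' @return data.frame with `query_id`, `ref_id`, `percent_identity`,
#'   `ref_cluster` (NA = outside any cluster), `rank`.
#' @export
gen_hit_table <- function(n_queries = 5, n_refs = 50,
                          scenario = c("clean", "below_threshold",
                                       "majority_boundary", "random"),
                          cluster = "SC55", n_majority = 6, seed = 1) {
  scenario <- match.arg(scenario)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_queries), function(q) {
      refs <- sprintf("Ref%04d", sample.int(n_refs, 10))
      id <- switch(scenario,
        clean = sort(stats::runif(10, 80, 99), decreasing = TRUE),
        below_threshold = sort(stats::runif(10, 50, 74.9), decreasing = TRUE),
        majority_boundary = c(88, 88, sort(stats::runif(8, 76, 87), decreasing = TRUE)),
        random = sort(stats::runif(10, 60, 99), decreasing = TRUE))
      cl <- switch(scenario,
        clean = rep(cluster, 10),
        below_threshold = rep(cluster, 10),
        majority_boundary = {
          # tie at the top: hit 1 in-cluster, hit 2 outside; n_majority
          # of the 10 retained references carry the focal label
          v <- rep(NA_character_, 10)
          v[c(1L, 2L + seq_len(n_majority - 1L))] <- cluster
          v
        },
        random = ifelse(stats::runif(10) < 0.5, cluster, NA_character_))
      data.frame(query_id = sprintf("Query%03d", q), ref_id = refs,
                 percent_identity = id, ref_cluster = cl,
                 rank = seq_len(10), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a random tree with traits
#'
#' Yule (pure-birth) tree with `n_tips` tips; traits evolve by Brownian
#' motion along branches (`model = "BM"`, unit rate) or are i.i.d.
#' standard normal (`model = "random"`, no phylogenetic signal).
#'
#' @param n_tips number of tips.
#' @param model `"BM"` or `"random"`.
#' @param seed integer seed.
#' @return list with `tree` (an `ape::phylo`) and `traits` (named
#'   numeric vector).
#' @export
gen_tree_and_traits <- function(n_tips, model = c("BM", "random"), seed = 1) {
  model <- match.arg(model)
  withr::with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    traits <- if (model == "BM") {
      V <- ape::vcv.phylo(tree)
      as.vector(t(chol(V)) %*% stats::rnorm(n_tips))
    } else {
      stats::rnorm(n_tips)
    }
    names(traits) <- tree$tip.label
    list(tree = tree, traits = traits)
  })
}

#' Write ground truth as JSON
#'
#' @param truth an [lv_ground_truth] or the `truth` element of
#'   [gen_bipartite_community()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
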