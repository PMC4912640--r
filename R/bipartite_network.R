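#' Build the host-OTU bipartite network
#'
#' OTUs enter the network only when they occur (count > 0) in at least
#' `min_samples` distinct samples across the whole data set; a link
#' (host species, OTU) exists when the OTU occurs in at least one
#' replicate of that species.
#'
#' @param x a [count_table] of host-associated samples.
#' @param meta metadata with `sample_id` and `host_species`.
#' @param min_samples minimum number of distinct samples an OTU must
#'   occupy to become a node (default 25).
#' @return object of class `bipartite_network`: list with `links`
#'   (data.frame host, otu), `host_nodes`, `otu_nodes`, `otu_degree`
#'   (hosts per OTU), `host_degree` (OTUs per host).
#' @export
build_network <- function(x, meta, min_samples = 25) {
  stopifnot_count_table(x)
  n_samples <- colSums(x$counts > 0)
  keep <- n_samples >= min_samples
  if (!any(keep))
    stop("empty network: no OTU occurs in >= ", min_samples, " samples")
  xt <- count_table(x$counts[, keep, drop = FALSE])
  agg <- aggregate_presence_by_species(xt, meta)
  pres <- agg$presence
  idx <- which(pres, arr.ind = TRUE)
  links <- data.frame(host = rownames(pres)[idx[, 1]],
                      otu = colnames(pres)[idx[, 2]],
                      stringsAsFactors = FALSE)
  links <- links[order(links$host, links$otu), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(
    links = links,
    host_nodes = rownames(pres),
    otu_nodes = colnames(pres),
    otu_degree = colSums(pres),
    host_degree = rowSums(pres),
    n_samples_per_otu = n_samples[keep]
  ), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d hosts, %d OTUs, %d links (mean OTU degree %.2f)\n",
              length(x$host_nodes), length(x$otu_nodes), nrow(x$links),
              mean(x$otu_degree)))
  invisible(x)
}

#' Cumulative degree distribution
#'
#' Complementary cumulative distribution of node degrees:
#' Pc(k) = fraction of nodes with degree >= k, evaluated at each
#' observed degree.  This is the decreasing form the truncated
#' power-law and exponential fits require; `lower_tail = TRUE` gives the
#' "degree <= k" variant instead.
#'
#' @param degrees integer vector of node degrees.
#' @param lower_tail return P(degree <= k) instead of P(degree >= k).
#' @return data.frame with columns `k` and `pc`.
#' @export
ccdf <- function(degrees, lower_tail = FALSE) {
  if (!length(degrees)) stop("no degrees supplied")
  k <- sort(unique(degrees))
  pc <- if (lower_tail) {
    vapply(k, function(d) mean(degrees <= d), 0)
  } else {
    vapply(k, function(d) mean(degrees >= d), 0)
  }
  data.frame(k = k, pc = pc)
}

#' Fit a truncated power law to a cumulative degree distribution
#'
#' Least-squares fit of Pc(k) = k^-a * exp(-k / b) on the untransformed
#' Pc values, via Levenberg-Marquardt with a small multi-start grid
#' (a in \{0.1, 0.5, 1\}, b in \{mean k, 2 mean k\}).  A fitted cutoff
#' larger than 10 times the maximum observed degree is flagged as
#' having no cutoff support in the data.
#'
#' @param points data.frame from [ccdf()] with columns `k`, `pc`.
#' @return a `degree_fit` list: `side`, `form`, `a`, `b`, `rss`,
#'   `converged`, `no_cutoff_support`.
#' @export
fit_truncated_power_law <- function(points) {
  if (nrow(points) < 4) stop("need at least 4 distinct degrees to fit a truncated power law")
  k <- points$k; pc <- points$pc
  starts <- expand.grid(a = c(0.1, 0.5, 1), b = c(mean(k), 2 * mean(k)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(pc ~ k^(-a) * exp(-k / b),
                        start = list(a = starts$a[i], b = starts$b[i]),
                        lower = c(a = -5, b = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best))
    stop("truncated power-law fit failed to converge from any start")
  structure(list(side = "otu", form = "truncated_power_law",
                 a = unname(best$coef["a"]), b = unname(best$coef["b"]),
                 rss = best$rss, converged = TRUE,
                 no_cutoff_support = unname(best$coef["b"]) > 10 * max(k)),
            class = "degree_fit")
}

#' Fit an exponential to a cumulative degree distribution
#'
#' Least-squares fit of Pc(k) = exp(-k / lambda), the form used for the
#' host side of the network.
#'
#' @param points data.frame from [ccdf()].
#' @return a `degree_fit` list with `lambda`.
#' @export
fit_exponential <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 distinct degrees to fit an exponential")
  k <- points$k; pc <- points$pc
  best <- NULL
  for (l0 in c(mean(k), 2 * mean(k), max(k))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(pc ~ exp(-k / lambda), start = list(lambda = l0),
                        lower = c(lambda = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) stop("exponential fit failed to converge")
  lambda <- unname(best$coef["lambda"])
  # scale beyond 5x the observed range means < 20% decay across the
  # data: the points carry no real information about the scale
  structure(list(side = "host", form = "exponential",
                 lambda = lambda, rss = best$rss, converged = TRUE,
                 no_decay_support = lambda > 5 * max(k)),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  if (x$form == "truncated_power_law")
    cat(sprintf("degree_fit [%s]: Pc(k) = k^-%.4g * exp(-k/%.4g), RSS %.3g\n",
                x$side, x$a, x$b, x$rss))
  else
    cat(sprintf("degree_fit [%s]: Pc(k) = exp(-k/%.4g), RSS %.3g\n",
                x$side, x$lambda, x$rss))
  invisible(x)
}

#' Degree-preserving random bipartite null network
#'
#' Uniform random bipartite graph with the same host count, OTU count
#' and link count as the observed network: links are drawn without
#' replacement from all host x OTU pairs.
#'
#' @param net a `bipartite_network`.
#' @param seed integer seed.
#' @return a `bipartite_network` with randomized links.
#' @export
null_network <- function(net, seed = 1) {
  nh <- length(net$host_nodes); no <- length(net$otu_nodes)
  L <- nrow(net$links)
  pair_idx <- withr::with_seed(seed, sample.int(nh * no, L, replace = FALSE))
  hi <- ((pair_idx - 1) %% nh) + 1
  oi <- ((pair_idx - 1) %/% nh) + 1
  links <- data.frame(host = net$host_nodes[hi], otu = net$otu_nodes[oi],
                      stringsAsFactors = FALSE)
  links <- links[order(links$host, links$otu), , drop = FALSE]
  rownames(links) <- NULL
  od <- table(factor(links$otu, levels = net$otu_nodes))
  hd <- table(factor(links$host, levels = net$host_nodes))
  structure(list(links = links, host_nodes = net$host_nodes,
                 otu_nodes = net$otu_nodes,
                 otu_degree = stats::setNames(as.vector(od), net$otu_nodes),
                 host_degree = stats::setNames(as.vector(hd), net$host_nodes)),
            class = "bipartite_network")
}

#' Classify OTUs as specialists, intermediates or generalists
#'
#' Specialists are OTUs found in strictly fewer than `spec_max` host
#' species, generalists in strictly more than `gen_min`.  The
#' prevalence fraction is the share of samples containing the OTU among
#' all samples of its linked host species (the quantity whose dip at
#' intermediate degree marks opportunists).  Threshold diagnostics
#' report mean degree overall and per class, with their ratios.
#'
#' @param net a `bipartite_network`.
#' @param x the replicate-level [count_table] the network was built from.
#' @param meta metadata with `sample_id` and `host_species`.
#' @param spec_max specialist upper bound on degree (strict `<`).
#' @param gen_min generalist lower bound on degree (strict `>`).
#' @return list with `classification` data.frame (`otu_id`, `degree`,
#'   `class`, `prevalence_fraction`) and `diagnostics`.
#' @export
classify_otus <- function(net, x, meta, spec_max = 5, gen_min = 50) {
  stopifnot_count_table(x)
  sp <- meta$host_species[match(sample_ids(x), meta$sample_id)]
  reps_per_species <- table(sp)
  occ <- x$counts > 0
  prev <- vapply(net$otu_nodes, function(o) {
    hosts <- net$links$host[net$links$otu == o]
    in_hosts <- sp %in% hosts
    denom <- sum(reps_per_species[hosts])
    if (denom == 0) return(NA_real_)
    sum(occ[in_hosts, o]) / denom
  }, 0)
  deg <- net$otu_degree[net$otu_nodes]
  cls <- ifelse(deg < spec_max, "specialist",
                ifelse(deg > gen_min, "generalist", "intermediate"))
  classification <- data.frame(otu_id = net$otu_nodes,
                               degree = as.vector(deg),
                               class = cls,
                               prevalence_fraction = prev,
                               stringsAsFactors = FALSE)
  mean_all <- mean(deg)
  mean_by <- tapply(classification$degree, classification$class, mean)
  diagnostics <- list(
    mean_degree = mean_all,
    mean_degree_by_class = mean_by,
    ratio_overall_to_specialist = unname(mean_all / mean_by["specialist"]),
    ratio_generalist_to_overall = unname(mean_by["generalist"] / mean_all))
  list(classification = classification, diagnostics = diagnostics)
}

#' Smoothing spline of prevalence against degree
#'
#' Cubic smoothing spline of the prevalence fraction versus OTU degree,
#' with the smoothing parameter chosen by generalized cross-validation
#' unless a fixed `spar` is supplied.
#'
#' @param classification data.frame from [classify_otus()].
#' @param smoothing `"cv"` (GCV) or `"fixed"`.
#' @param spar fixed smoothing parameter when `smoothing = "fixed"`.
#' @param n_grid number of grid points spanning the degree range.
#' @return data.frame with `k` (grid) and `fit`.
#' @export
prevalence_spline <- function(classification, smoothing = c("cv", "fixed"),
                              spar = 0.5, n_grid = 200) {
  smoothing <- match.arg(smoothing)
  ok <- is.finite(classification$prevalence_fraction)
  xk <- classification$degree[ok]
  y <- classification$prevalence_fraction[ok]
  fit <- if (smoothing == "cv") {
    stats::smooth.spline(xk, y, cv = FALSE) # GCV
  } else {
    stats::smooth.spline(xk, y, spar = spar)
  }
  grid <- seq(min(xk), max(xk), length.out = n_grid)
  data.frame(k = grid, fit = stats::predict(fit, grid)$y)
}

#' Degree enrichment of core OTUs against the global network
#'
#' For each observed degree d, compares the fraction of all network
#' OTUs with degree >= d against the same fraction within the
#' aggregated core set; `break_k` is the smallest degree (scanning
#' upward) at which the core fraction exceeds the global fraction, the
#' point beyond which cores are enriched in well-connected OTUs.
#'
#' @param net a `bipartite_network`.
#' @param core_otu_ids character vector of core OTU ids (aggregated
#'   over hosts); must be non-empty and present in the network.
#' @return list with `curve` (data.frame `k`, `global_frac`,
#'   `core_frac`), `break_k`, and mean-degree comparison.
#' @export
core_degree_enrichment <- function(net, core_otu_ids) {
  core_otu_ids <- intersect(unique(core_otu_ids), net$otu_nodes)
  if (!length(core_otu_ids)) stop("core OTU set is empty or disjoint from the network")
  deg_all <- net$otu_degree[net$otu_nodes]
  deg_core <- net$otu_degree[core_otu_ids]
  ks <- sort(unique(deg_all))
  curve <- data.frame(
    k = ks,
    global_frac = vapply(ks, function(d) mean(deg_all >= d), 0),
    core_frac = vapply(ks, function(d) mean(deg_core >= d), 0))
  above <- which(curve$core_frac > curve$global_frac)
  list(curve = curve,
       break_k = if (length(above)) curve$k[min(above)] else NA_real_,
       mean_degree_global = mean(deg_all),
       mean_degree_core = mean(deg_core))
}

#' Export a bipartite network
#'
#' @param net a `bipartite_network`.
#' @param path output path; format by extension (`.tsv` edge list or
#'   `.graphml`).
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_data_frame(net$links, directed = FALSE)
    igraph::V(g)$type <- igraph::V(g)$name %in% net$otu_nodes
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$links, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  }
  invisible(path)
}
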