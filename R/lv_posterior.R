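#' Decompose stationary abundance variance
#'
#' For each retained posterior draw, the latent map is linearized at
#' its deterministic equilibrium N* (solving N*_i - sum_j a_ij N*_j =
#' k_i over included links): J_ii = 1 - (r_i/k_i) N*_i and J_ij =
#' (r_i/k_i) a_ij N*_j.  The stationary covariance V of the linearized
#' system solves the discrete Lyapunov equation V = J V J' +
#' diag(sigma^2).  The variance felt by OTU i is then attributed to
#' density dependence (J_ii^2 v_ii), inter-specific interactions
#' (sum_{j != i} J_ij^2 v_jj) and stochasticity (sigma_i^2), and the
#' three are normalized to shares summing to 1.  Draws whose
#' linearization is unstable (spectral radius >= 1) or has no feasible
#' positive equilibrium are skipped; more than `max_skip` skipped is an
#' error.
#'
#' @param post an `lv_posterior`.
#' @param max_draws cap on posterior draws used (evenly spaced).
#' @param max_skip tolerated skip fraction (default 0.5).
#' @return a `variance_shares` list: `shares` (data.frame per OTU with
#'   posterior-mean shares and stationary variance), `skip_fraction`.
#' @export
variance_decomposition <- function(post, max_draws = 500, max_skip = 0.5) {
  stopifnot(inherits(post, "lv_posterior"))
  S <- post$S
  r_all <- do.call(rbind, lapply(post$chains, `[[`, "r"))
  k_all <- do.call(rbind, lapply(post$chains, `[[`, "k"))
  s_all <- do.call(rbind, lapply(post$chains, `[[`, "sigma"))
  a_all <- do.call(rbind, lapply(post$chains, `[[`, "alpha"))
  g_all <- do.call(rbind, lapply(post$chains, `[[`, "g"))
  nd <- nrow(r_all)
  use <- if (nd > max_draws) round(seq(1, nd, length.out = max_draws)) else seq_len(nd)

  acc <- matrix(0, S, 3); vacc <- numeric(S); used <- 0L
  for (it in use) {
    alpha <- matrix(0, S, S)
    alpha[cbind(post$ei, post$ej)] <- a_all[it, ] * g_all[it, ]
    sh <- decompose_one(r_all[it, ], k_all[it, ], alpha, s_all[it, ])
    if (is.null(sh)) next
    used <- used + 1L
    acc <- acc + sh$shares
    vacc <- vacc + sh$v
  }
  skip <- 1 - used / length(use)
  if (skip > max_skip)
    stop(sprintf("variance decomposition skipped %.0f%% of draws (unstable or infeasible)",
                 100 * skip))
  shares <- acc / used
  colnames(shares) <- c("interactions", "density_dependence", "stochasticity")
  structure(list(shares = data.frame(otu_id = post$otu_ids,
                                     stationary_variance = vacc / used,
                                     shares, stringsAsFactors = FALSE),
                 skip_fraction = skip),
            class = "variance_shares")
}

# Shares for one parameter draw; NULL when skipped.
decompose_one <- function(r, k, alpha, sigma) {
  Nstar <- lv_equilibrium(alpha, k)
  if (any(!is.finite(Nstar)) || any(Nstar <= 0)) return(NULL)
  J <- lv_jacobian(r, k, alpha, Nstar)
  if (max(Mod(eigen(J, only.values = TRUE)$values)) >= 1) return(NULL)
  V <- solve_dlyap(J, diag(sigma^2, length(sigma)))
  v <- diag(V)
  S <- length(r)
  dd <- diag(J)^2 * v
  inter <- (J^2 %*% v) - diag(J)^2 * v
  sto <- sigma^2
  tot <- dd + inter + sto
  list(shares = cbind(inter / tot, dd / tot, sto / tot), v = v)
}

# Discrete Lyapunov equation V = J V J' + Q via vectorization.
solve_dlyap <- function(J, Q) {
  S <- nrow(J)
  vecV <- solve(diag(S * S) - kronecker(J, J), as.vector(Q))
  matrix(vecV, S, S)
}

#' Extract the representative interaction network
#'
#' Picks the L directed links with highest posterior inclusion
#' probability, where L = round(posterior mean number of included
#' indicators); ties are broken by |posterior mean coefficient| then
#' lexicographically.  Link sign is the sign of the posterior mean of
#' a_ij conditional on inclusion.  Connectance is L / (S (S - 1)); the
#' distance to the posterior-mean connectance is reported as a
#' validation metric.
#'
#' @param post an `lv_posterior`.
#' @return a `representative_network`: `links` (data.frame `from`,
#'   `to`, `sign`, `inclusion_prob`, `mean_strength`; `from` acts on
#'   `to`), `connectance`, `posterior_mean_connectance`,
#'   `connectance_gap`, `n_links`.
#' @export
representative_network <- function(post) {
  stopifnot(inherits(post, "lv_posterior"))
  S <- post$S
  g_all <- do.call(rbind, lapply(post$chains, `[[`, "g"))
  mean_links <- mean(rowSums(g_all))
  L <- round(mean_links)
  ord <- order(-post$pip, -abs(post$alpha_mean_active),
               post$otu_ids[post$ej], post$otu_ids[post$ei])
  sel <- ord[seq_len(L)]
  links <- data.frame(
    from = post$otu_ids[post$ej[sel]],
    to = post$otu_ids[post$ei[sel]],
    sign = sign(post$alpha_mean_active[sel]),
    inclusion_prob = post$pip[sel],
    mean_strength = post$alpha_mean_active[sel],
    stringsAsFactors = FALSE)
  conn <- L / (S * (S - 1))
  post_conn <- mean_links / (S * (S - 1))
  structure(list(nodes = post$otu_ids, links = links, n_links = L,
                 connectance = conn,
                 posterior_mean_connectance = post_conn,
                 connectance_gap = abs(conn - post_conn)),
            class = "representative_network")
}

#' @export
print.representative_network <- function(x, ...) {
  cat(sprintf("representative_network: %d OTUs, %d links, connectance %.3f (posterior mean %.3f)\n",
              length(x$nodes), x$n_links, x$connectance,
              x$posterior_mean_connectance))
  invisible(x)
}

#' Classify pairwise interaction types
#'
#' For every unordered pair with at least one link, the two directed
#' signs (0 when absent) determine the ecological type: (+,+)
#' mutualism, (-,-) competition, (+,-) exploitation, (+,0)
#' commensalism, (-,0) amensalism, (0,0) none.
#'
#' @param net a `representative_network`.
#' @return list with `pairs` (data.frame `otu_a`, `otu_b`, `sign_ab`,
#'   `sign_ba`, `type`) and `tally` (named counts over all types).
#' @export
classify_interactions <- function(net) {
  nodes <- net$nodes
  sgn <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (l in seq_len(nrow(net$links)))
    sgn[net$links$from[l], net$links$to[l]] <- net$links$sign[l]
  combs <- utils::combn(nodes, 2)
  typ <- function(s1, s2) {
    ss <- sort(c(s1, s2), decreasing = TRUE)
    if (ss[1] > 0 && ss[2] > 0) "mutualism"
    else if (ss[1] < 0) "competition"
    else if (ss[1] > 0 && ss[2] < 0) "exploitation"
    else if (ss[1] > 0) "commensalism"
    else if (ss[2] < 0) "amensalism"
    else "none"
  }
  pairs <- data.frame(otu_a = combs[1, ], otu_b = combs[2, ],
                      stringsAsFactors = FALSE)
  pairs$sign_ab <- sgn[cbind(pairs$otu_a, pairs$otu_b)]
  pairs$sign_ba <- sgn[cbind(pairs$otu_b, pairs$otu_a)]
  pairs$type <- mapply(typ, pairs$sign_ab, pairs$sign_ba)
  lv <- c("mutualism", "competition", "exploitation", "commensalism",
          "amensalism", "none")
  list(pairs = pairs,
       tally = table(factor(pairs$type, levels = lv)))
}

#' Export a representative network
#'
#' Edge list TSV (default) or GraphML by extension.
#'
#' @param net a `representative_network`.
#' @param path output path.
#' @export
write_representative_network <- function(net, path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_data_frame(net$links, directed = TRUE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$links, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  }
  invisible(path)
}
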