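#' Blomberg's K with randomization test
#'
#' K compares the observed ratio of trait variance among tips to the
#' variance expected under Brownian motion on the tree:
#' K = (MSE0/MSE)_obs / (MSE0/MSE)_BM, where the phylogenetic mean is
#' a-hat = (1' V^-1 x) / (1' V^-1 1), MSE0 = sum((x - a-hat)^2)/(n-1),
#' MSE = (x - a-hat)' V^-1 (x - a-hat) / (n - 1), and the Brownian
#' expectation of MSE0/MSE is (tr(V) - n / (1' V^-1 1)) / (n - 1),
#' with V the phylogenetic covariance (shared path lengths).  K = 1
#' under Brownian motion; K < 1 indicates less similarity among
#' relatives than Brownian motion predicts.  The P-value is the rank
#' of the observed MSE among tip-label permutations (small MSE = more
#' signal), with the never-zero convention
#' P = (1 + #\{perm <= obs\}) / (1 + n_perm).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param trait named numeric vector covering all tips.
#' @param n_perm number of tip permutations (default 999).
#' @param seed integer seed.
#' @return a `signal_result` list: `statistic` (K), `p_value`,
#'   `n_permutations`, `seed`.
#' @export
blombergs_k <- function(tree, trait, n_perm = 999, seed = 1) {
  if (is.null(names(trait))) stop("trait vector must be named by tip label")
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait missing for tips: ",
         paste(setdiff(tree$tip.label, names(trait)), collapse = ", "))
  x <- trait[tree$tip.label]
  if (stats::var(x) == 0) stop("zero-variance trait: K undefined")
  V <- ape::vcv.phylo(tree)
  n <- length(x)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  one <- rep(1, n)
  denom_a <- as.numeric(one %*% Vi %*% one)
  k_stat <- function(x) {
    ahat <- as.numeric(one %*% Vi %*% x) / denom_a
    dev <- x - ahat
    mse0 <- sum(dev^2) / (n - 1)
    mse <- as.numeric(dev %*% Vi %*% dev) / (n - 1)
    c(K = (mse0 / mse) / ((sum(diag(V)) - n / denom_a) / (n - 1)),
      mse = mse)
  }
  obs <- k_stat(x)
  perm_mse <- withr::with_seed(seed, vapply(seq_len(n_perm), function(p)
    k_stat(sample(x))[["mse"]], 0))
  # observed MSE small relative to permutations indicates signal
  p <- (1 + sum(perm_mse <= obs[["mse"]])) / (1 + n_perm)
  structure(list(statistic = unname(obs[["K"]]), p_value = p,
                 n_permutations = n_perm, seed = seed,
                 method = "Blomberg's K"),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, P = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

off_diag <- function(m) m[lower.tri(m)]

#' Mantel test between two distance matrices
#'
#' Mantel r is the Pearson correlation of the off-diagonal elements;
#' the null distribution permutes row/column labels of `d1` jointly.
#' P-value convention: (1 + #\{perm >= obs\}) / (1 + n_perm).
#'
#' @param d1,d2 `dist` objects or square symmetric matrices over the
#'   same ids.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a `signal_result` with `statistic` (Mantel r).
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in size")
  n <- nrow(m1)
  pr <- which(lower.tri(m1), arr.ind = TRUE) # permute via pair indexing
  v2 <- m2[pr]
  obs <- stats::cor(m1[pr], v2)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(p) {
    idx <- sample.int(n)
    stats::cor(m1[cbind(idx[pr[, 1]], idx[pr[, 2]])], v2)
  }, 0))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 seed = seed, method = "Mantel"),
            class = "signal_result")
}

#' Partial Mantel test
#'
#' Correlates `d1` and `d2` after removing the linear effect of `d3`
#' from both (correlation of residuals); the permutation null shuffles
#' labels of `d1` and recomputes the partial correlation.
#'
#' @param d1,d2,d3 distance matrices over the same ids; `d3` is the
#'   conditioning matrix.
#' @inheritParams mantel_test
#' @return a `signal_result` with `statistic` (partial Mantel r).
#' @export
partial_mantel <- function(d1, d2, d3, n_perm = 999, seed = 1) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2); m3 <- as.matrix(d3)
  n <- nrow(m1)
  pairs <- which(lower.tri(m1), arr.ind = TRUE)
  v2 <- m2[pairs]; v3 <- m3[pairs]
  res2 <- stats::residuals(stats::lm(v2 ~ v3))
  pcor <- function(v1) stats::cor(stats::residuals(stats::lm(v1 ~ v3)), res2)
  obs <- pcor(m1[pairs])
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(p) {
    idx <- sample.int(n)
    pcor(m1[cbind(idx[pairs[, 1]], idx[pairs[, 2]])])
  }, 0))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 seed = seed, method = "partial Mantel"),
            class = "signal_result")
}

#' Read a host tree in Newick format
#'
#' Thin wrapper over [ape::read.tree()] that validates tip-label
#' uniqueness and non-negative branch lengths.
#'
#' @param path Newick file.
#' @return an `ape::phylo`.
#' @export
read_host_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree: ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in ", path)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths in ", path)
  tree
}

#' Binary host-identity distance matrix
#'
#' Encodes "same host species" as distance 0 and "different species"
#' as 1, the conditioning matrix used when testing phylogeny against
#' composition given host identity.
#'
#' @param species character vector of host species per sample.
#' @param ids optional sample ids for the dimnames.
#' @return a square numeric matrix.
#' @export
host_identity_distance <- function(species, ids = NULL) {
  m <- outer(species, species, FUN = function(a, b) as.numeric(a != b))
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  m
}
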