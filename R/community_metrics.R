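#' Expected richness under rarefaction
#'
#' Hypergeometric expectation of the number of OTUs observed in a random
#' subsample of `n` reads without replacement:
#' E\[S_n\] = sum_i (1 - C(N - N_i, n) / C(N, n)),
#' evaluated through log-gamma arithmetic so large totals do not
#' overflow.
#'
#' @param counts integer vector of per-OTU counts for one sample.
#' @param n subsample size, 0 <= n <= sum(counts).
#' @return expected number of OTUs (numeric scalar).
#' @export
rarefaction_expected <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (n < 0 || n > N) stop("subsample size n must lie in [0, total reads]")
  if (n == 0) return(0)
  # log C(N - N_i, n) - log C(N, n), with C(a, n) = 0 when a < n
  lc <- function(a) ifelse(a >= n, lchoose(a, n), -Inf)
  sum(1 - exp(lc(N - counts) - lchoose(N, n)))
}

#' Chao1 richness estimate
#'
#' S_obs + f1^2 / (2 f2) with singleton count f1 and doubleton count f2;
#' when f2 = 0 the bias-corrected form S_obs + f1 (f1 - 1) / 2 is used.
#'
#' @param counts integer vector of per-OTU counts.
#' @return Chao1 estimate.
#' @export
chao1 <- function(counts) {
  counts <- counts[counts > 0]
  sobs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f1 == 0) return(sobs)
  if (f2 == 0) sobs + f1 * (f1 - 1) / 2 else sobs + f1^2 / (2 * f2)
}

#' ACE richness estimate
#'
#' Abundance-based coverage estimator with the standard split between
#' rare (<= `rare_max` reads, default 10) and abundant OTUs.
#'
#' @param counts integer vector of per-OTU counts.
#' @param rare_max rare/abundant split point.
#' @return ACE estimate.
#' @export
ace <- function(counts, rare_max = 10) {
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_max]
  s_abund <- sum(counts > rare_max)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (n_rare == f1) return(chao1(counts)) # coverage zero; fall back
  c_ace <- 1 - f1 / n_rare
  i <- seq_len(rare_max)
  fi <- vapply(i, function(k) sum(rare == k), 0)
  g2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

#' Shannon diversity index
#'
#' @param counts integer vector of per-OTU counts.
#' @return Shannon index (natural log).
#' @export
shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Inverse Simpson diversity index
#'
#' D = 1 / sum p_i^2; equals the number of OTUs for a perfectly even
#' community and 1 for a single-OTU community.
#'
#' @param counts integer vector of per-OTU counts.
#' @return inverse Simpson index D.
#' @export
inverse_simpson <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  1 / sum(p^2)
}

#' Per-sample diversity table
#'
#' Computes observed richness, Chao1, ACE, Shannon and inverse Simpson
#' for every sample of a count table.
#'
#' @param x a [count_table].
#' @return data.frame with one row per sample.
#' @export
diversity_table <- function(x) {
  stopifnot_count_table(x)
  rows <- lapply(seq_len(nrow(x$counts)), function(i) {
    v <- x$counts[i, ]
    data.frame(sample_id = rownames(x$counts)[i],
               sobs = sum(v > 0),
               chao1 = chao1(v),
               ace = ace(v),
               shannon = shannon(v),
               inv_simpson = inverse_simpson(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bray-Curtis distance matrix
#'
#' BC(x, y) = 1 - 2 sum min(x_i, y_i) / sum (x_i + y_i) after the
#' selected transform.  `proportion` divides each sample by its total
#' (the default for dispersion analyses); `hellinger` takes square roots
#' of proportions.  Distances are delegated to [vegan::vegdist()].
#'
#' @param x a [count_table].
#' @param transform `"none"`, `"proportion"` or `"hellinger"`.
#' @return a `dist` object with sample ids.
#' @export
bray_curtis <- function(x, transform = c("proportion", "none", "hellinger")) {
  stopifnot_count_table(x)
  transform <- match.arg(transform)
  m <- x$counts
  m <- switch(transform,
              none = m,
              proportion = sweep(m, 1, pmax(rowSums(m), 1), "/"),
              hellinger = vegan::decostand(m, "hellinger"))
  vegan::vegdist(m, method = "bray")
}

#' Distance of each sample to its group centroid
#'
#' Multivariate dispersion in the Anderson (2006) sense: samples are
#' embedded by principal coordinates of the (typically Bray-Curtis)
#' distance matrix, axes with negative eigenvalues are kept separately,
#' and the squared distance to the group centroid is the real-axis part
#' minus the imaginary-axis part, floored at zero.  Delegated to
#' [vegan::betadisper()].
#'
#' @param d a `dist` object.
#' @param groups factor or character vector of group labels, aligned
#'   with the labels of `d`.
#' @return data.frame with `sample_id`, `group`, `dist_to_centroid`.
#' @export
dispersion_to_centroid <- function(d, groups) {
  labs <- attr(d, "Labels")
  if (length(groups) != attr(d, "Size"))
    stop("groups must have one entry per sample in the distance matrix")
  groups <- as.factor(groups)
  if (any(table(groups) == 1))
    warning("groups of size 1 have dispersion 0 by construction")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  data.frame(sample_id = if (is.null(labs)) seq_along(groups) else labs,
             group = as.character(groups),
             dist_to_centroid = as.numeric(bd$distances),
             stringsAsFactors = FALSE)
}

#' Write a diversity table as TSV
#'
#' @param div output of [diversity_table()].
#' @param path output path.
#' @export
write_diversity_tsv <- function(div, path) {
  utils::write.table(div, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
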