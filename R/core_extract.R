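#' Select hosts with enough replicates and subsample them
#'
#' Retains host species with at least `min_reps` replicate samples and,
#' where more are available, subsamples exactly `min_reps` of them
#' uniformly at random (reproducibly under `seed`).
#'
#' @param x a [count_table] of host-associated samples.
#' @param meta metadata with `sample_id` and `host_species`.
#' @param min_reps replicate threshold (default 47).
#' @param seed integer seed for the subsampling.
#' @return named list of [count_table]s, one per retained host, each
#'   with exactly `min_reps` samples.
#' @export
select_hosts <- function(x, meta, min_reps = 47, seed = 1) {
  stopifnot_count_table(x)
  sp <- meta$host_species[match(sample_ids(x), meta$sample_id)]
  keep_samples <- !is.na(sp)
  counts_per_host <- table(sp[keep_samples])
  hosts <- names(counts_per_host)[counts_per_host >= min_reps]
  if (!length(hosts)) return(stats::setNames(list(), character(0)))
  out <- lapply(seq_along(hosts), function(i) {
    h <- hosts[i]
    ids <- sort(sample_ids(x)[!is.na(sp) & sp == h])
    if (length(ids) > min_reps)
      ids <- sort(withr::with_seed(derive_seed(seed, i), sample(ids, min_reps)))
    subset_counts(x, samples = ids)
  })
  stats::setNames(out, hosts)
}

#' Extract the core microbiome of one host species
#'
#' Core OTUs must occur (count > 0) in at least `ceiling(prevalence *
#' M)` of the M replicates and carry at least `min_rel_abund` of the
#' table's total reads (mothur `filter.shared(minpercentsamples=85,
#' minpercent=1)` semantics: the abundance floor is a fraction of the
#' grand total).
#'
#' @param x47 a per-host [count_table] (replicates x OTUs), e.g. one
#'   element of [select_hosts()].
#' @param prevalence replicate-occurrence threshold (default 0.85).
#' @param min_rel_abund abundance floor as a fraction of total reads
#'   (default 0.01).
#' @param host_species optional host label carried in the result.
#' @return a `core_set`: `host_species`, `sample_ids`, `otu_ids`,
#'   `counts` (core submatrix), `prevalence`, `rel_abund`.
#' @export
extract_core <- function(x47, prevalence = 0.85, min_rel_abund = 0.01,
                         host_species = NA_character_) {
  stopifnot_count_table(x47)
  M <- nrow(x47$counts)
  need <- ceiling(prevalence * M)
  n_present <- colSums(x47$counts > 0)
  rel <- colSums(x47$counts) / sum(x47$counts)
  pass_prev <- n_present >= need
  pass_ab <- rel >= min_rel_abund
  keep <- pass_prev & pass_ab
  if (!any(keep)) {
    near <- order(-(n_present / need + rel / min_rel_abund))[1:min(5, ncol(x47$counts))]
    stop("empty core for ", host_species, ": no OTU passes prevalence >= ",
         need, "/", M, " and abundance >= ", min_rel_abund,
         "; nearest misses: ",
         paste(sprintf("%s (%d/%d reps, %.3f%%)", otu_ids(x47)[near],
                       n_present[near], M, 100 * rel[near]), collapse = ", "))
  }
  structure(list(host_species = host_species,
                 sample_ids = sample_ids(x47),
                 otu_ids = otu_ids(x47)[keep],
                 counts = subset_counts(x47, otus = which(keep)),
                 prevalence = n_present[keep] / M,
                 rel_abund = rel[keep]),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set [%s]: %d core OTUs over %d replicates\n",
              x$host_species, length(x$otu_ids), length(x$sample_ids)))
  invisible(x)
}

#' Order replicates for the space-for-time substitution
#'
#' The interaction model consumes replicates as a pseudo-series; since
#' spatial replicates carry no intrinsic order, a deterministic policy
#' fixes one.  `sorted_id` (default) sorts sample ids
#' lexicographically; `given` keeps the supplied order; `random`
#' shuffles reproducibly under `seed`.
#'
#' @param core a `core_set` (or a [count_table]).
#' @param policy `"sorted_id"`, `"given"` or `"random"`.
#' @param seed seed for `policy = "random"`.
#' @return integer index into the replicate samples.
#' @export
order_replicates <- function(core, policy = c("sorted_id", "given", "random"),
                             seed = 1) {
  policy <- match.arg(policy)
  ids <- if (inherits(core, "core_set")) core$sample_ids else sample_ids(core)
  switch(policy,
         sorted_id = order(ids),
         given = seq_along(ids),
         random = withr::with_seed(seed, sample(seq_along(ids))))
}
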