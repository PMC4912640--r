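#' Dataset-level count filters
#'
#' These implement the survey-level cleanup applied before any network or
#' diversity analysis: dropping globally rare OTUs, removing organellar
#' sequences, and zeroing seawater-derived OTUs out of host samples.
#' All three are idempotent; the pipeline default order is
#' low-abundance, then taxon, then seawater-like.
#'
#' @name filters
NULL

#' Drop OTUs that are rare across the whole data set
#'
#' An OTU is dropped when its total count divided by the grand total
#' (computed before any dropping) is strictly below `frac`.  The
#' default, 1e-5, corresponds to "less than 0.001% of all sequences".
#'
#' @param x a [count_table].
#' @param frac relative-abundance threshold (proportion, strict `<`).
#' @return a filtered [count_table].
#' @export
filter_low_abundance <- function(x, frac = 1e-5) {
  stopifnot_count_table(x)
  grand <- sum(x$counts)
  if (grand <= 0) stop("grand total must be positive")
  keep <- colSums(x$counts) / grand >= frac
  if (!any(keep)) {
    warning("all OTUs fall below the abundance threshold; returning empty table")
  }
  count_table(x$counts[, keep, drop = FALSE])
}

#' Zero seawater-like OTUs out of sponge samples
#'
#' OTUs whose pooled relative abundance across all seawater samples is
#' strictly above `frac` (default 1e-4, i.e. ">0.01% across all seawater
#' samples") are treated as environmental contaminants picked up by
#' filter feeding: their counts are set to zero in sponge samples, while
#' seawater and sediment samples are left untouched.  "Across all" is
#' read as pooled counts (sum over seawater samples over total seawater
#' reads); `pooling = "per_sample_mean"` uses the mean per-sample
#' proportion instead.
#'
#' @param x a [count_table].
#' @param meta metadata data.frame with `sample_id` and `habitat`.
#' @param frac threshold on seawater relative abundance (strict `>`).
#' @param pooling `"pooled"` or `"per_sample_mean"`.
#' @return a [count_table] of the same shape.
#' @export
remove_seawater_like <- function(x, meta, frac = 1e-4,
                                 pooling = c("pooled", "per_sample_mean")) {
  stopifnot_count_table(x)
  pooling <- match.arg(pooling)
  habitat <- meta$habitat[match(sample_ids(x), meta$sample_id)]
  if (anyNA(habitat)) stop("samples missing from metadata: ",
                           paste(sample_ids(x)[is.na(habitat)], collapse = ", "))
  sw <- habitat == "seawater"
  if (!any(sw)) stop("no seawater samples in metadata; cannot identify seawater-like OTUs")
  swm <- x$counts[sw, , drop = FALSE]
  rel <- if (pooling == "pooled") {
    colSums(swm) / sum(swm)
  } else {
    colMeans(sweep(swm, 1, pmax(rowSums(swm), 1), "/"))
  }
  contaminant <- rel > frac
  sponge <- !(habitat %in% c("seawater", "sediment"))
  m <- x$counts
  m[sponge, contaminant] <- 0
  count_table(m)
}

#' Drop OTUs matching a taxon label
#'
#' Removes OTUs whose lineage string contains `label` as a
#' case-insensitive substring at any rank (default removes
#' chloroplast-assigned OTUs).  OTUs absent from the taxonomy table are
#' kept.
#'
#' @param x a [count_table].
#' @param taxonomy data.frame with `otu_id` and `taxonomy` columns.
#' @param label taxon substring to remove.
#' @return a filtered [count_table].
#' @export
remove_taxon <- function(x, taxonomy, label = "Chloroplast") {
  stopifnot_count_table(x)
  lineage <- taxonomy$taxonomy[match(otu_ids(x), taxonomy$otu_id)]
  hit <- !is.na(lineage) & grepl(label, lineage, ignore.case = TRUE, fixed = FALSE)
  count_table(x$counts[, !hit, drop = FALSE])
}

#' Species-level presence and prevalence matrices
#'
#' Collapses a replicate-level count table to host species: `presence`
#' records whether an OTU occurs (count > 0) in at least one replicate
#' of the species, and `prevalence` the fraction of the species'
#' replicates that contain it.
#'
#' @param x a [count_table] of host-associated samples.
#' @param meta metadata with `sample_id` and `host_species`.
#' @return list with logical `presence` and numeric `prevalence`
#'   matrices (species x OTUs) and `n_replicates` per species.
#' @export
aggregate_presence_by_species <- function(x, meta) {
  stopifnot_count_table(x)
  sp <- meta$host_species[match(sample_ids(x), meta$sample_id)]
  if (anyNA(sp)) stop("samples missing host_species: ",
                      paste(sample_ids(x)[is.na(sp)], collapse = ", "))
  occ <- (x$counts > 0) * 1
  byspecies <- rowsum(occ, group = sp)
  nrep <- as.vector(table(sp)[rownames(byspecies)])
  prevalence <- byspecies / nrep
  list(presence = byspecies > 0,
       prevalence = prevalence,
       n_replicates = stats::setNames(nrep, rownames(byspecies)))
}
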