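#' Read a tabular similarity hit table
#'
#' Reads the standard 12-column tabular alignment format (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, evalue, bitscore) and joins reference
#' cluster labels from a two-column map (`ref_id`, `cluster`; missing
#' refs are outside any cluster).
#'
#' @param path hit-table path (no header).
#' @param cluster_map_path TSV mapping `ref_id` to `cluster`.
#' @return data.frame with `query_id`, `ref_id`, `percent_identity`,
#'   `ref_cluster`, `rank` (within query, by decreasing identity).
#' @export
read_hit_table <- function(path, cluster_map_path = NULL) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("hit table needs at least 3 columns (query, subject, identity)")
  h <- data.frame(query_id = as.character(d[[1]]), ref_id = as.character(d[[2]]),
                  percent_identity = as.numeric(d[[3]]),
                  stringsAsFactors = FALSE)
  h$ref_cluster <- NA_character_
  if (!is.null(cluster_map_path)) {
    cm <- utils::read.delim(cluster_map_path, stringsAsFactors = FALSE)
    if (!all(c("ref_id", "cluster") %in% names(cm)))
      stop("cluster map needs ref_id and cluster columns")
    h$ref_cluster <- cm$cluster[match(h$ref_id, cm$ref_id)]
  }
  h <- h[order(h$query_id, -h$percent_identity), ]
  h$rank <- stats::ave(h$percent_identity, h$query_id,
                       FUN = function(v) seq_along(v))
  rownames(h) <- NULL
  h
}

#' Assign queries to sponge-specific sequence clusters
#'
#' Decision rule on the 10 best hits of each query: if the single most
#' similar reference belongs to a cluster, its identity is strictly
#' above `id_threshold`, and no equally similar reference carries a
#' conflicting label, the query is assigned by `best_hit`.  When the
#' top is tied with conflicting labels (or the best hit has no
#' cluster), a majority rule applies: the query is assigned to a
#' cluster only if at least `majority` of the retained hits carry that
#' label and the best in-cluster identity exceeds `id_threshold`.
#' Otherwise the query stays unassigned (`below_threshold` when
#' identity was the obstacle, `inconsistent` otherwise).
#'
#' @param hits data.frame as from [read_hit_table()] or
#'   [gen_hit_table()].
#' @param id_threshold percent-identity threshold (strict `>`,
#'   default 75).
#' @param majority required fraction of retained hits sharing the
#'   cluster label (`>=`, default 0.60).
#' @param top_n hits retained per query (default 10).
#' @return data.frame with `query_id`, `assigned_cluster` (NA when
#'   unassigned), `rule_fired`.
#' @export
assign_clusters <- function(hits, id_threshold = 75, majority = 0.60,
                            top_n = 10) {
  if (!nrow(hits)) stop("empty hit table")
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100))
    stop("percent identities outside [0, 100]")
  out <- lapply(split(hits, hits$query_id), function(h) {
    h <- h[order(-h$percent_identity), , drop = FALSE]
    h <- utils::head(h, top_n)
    top_id <- h$percent_identity[1]
    top <- h[h$percent_identity == top_id, , drop = FALSE]
    top_clusters <- unique(top$ref_cluster)
    res <- function(cl, rule) data.frame(query_id = h$query_id[1],
                                         assigned_cluster = cl,
                                         rule_fired = rule,
                                         stringsAsFactors = FALSE)
    if (length(top_clusters) == 1 && !is.na(top_clusters)) {
      # unambiguous best hit
      if (top_id > id_threshold) return(res(top_clusters, "best_hit"))
      return(res(NA_character_, "below_threshold"))
    }
    # ties or inconsistent labels among the most similar references:
    # fall back to the majority rule over the retained hits
    labs <- h$ref_cluster[!is.na(h$ref_cluster)]
    if (!length(labs)) return(res(NA_character_, "inconsistent"))
    tab <- sort(table(labs), decreasing = TRUE)
    cand <- names(tab)[1]
    frac <- tab[[1]] / nrow(h)
    best_in <- max(h$percent_identity[!is.na(h$ref_cluster) &
                                        h$ref_cluster == cand])
    if (frac >= majority && best_in > id_threshold)
      return(res(cand, "majority"))
    if (frac >= majority) return(res(NA_character_, "below_threshold"))
    res(NA_character_, "inconsistent")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize cluster assignments over a count table
#'
#' Read-weighted and OTU-weighted fractions of each cluster, overall
#' and per habitat.
#'
#' @param assignments data.frame from [assign_clusters()]; `query_id`
#'   must match OTU ids of `x`.
#' @param x a [count_table].
#' @param meta optional metadata with `sample_id` and `habitat` for a
#'   per-habitat split.
#' @return list with `overall` and (when `meta` given) `by_habitat`
#'   data.frames of `cluster`, `read_fraction`, `otu_fraction`.
#' @export
summarize_assignments <- function(assignments, x, meta = NULL) {
  stopifnot_count_table(x)
  cl <- assignments$assigned_cluster[match(otu_ids(x), assignments$query_id)]
  frac_table <- function(m) {
    tot <- sum(m)
    reads_by <- tapply(colSums(m), cl, sum)
    otus_by <- table(cl[colSums(m) > 0])
    clusters <- sort(unique(cl[!is.na(cl)]))
    data.frame(
      cluster = c(clusters, "unassigned"),
      read_fraction = c(as.numeric(reads_by[clusters]) / tot,
                        1 - sum(as.numeric(reads_by[clusters]), na.rm = TRUE) / tot),
      otu_fraction = c(as.numeric(otus_by[clusters]) / sum(colSums(m) > 0),
                       1 - sum(as.numeric(otus_by[clusters]), na.rm = TRUE) /
                         max(sum(colSums(m) > 0), 1)),
      stringsAsFactors = FALSE)
  }
  out <- list(overall = frac_table(x$counts))
  if (!is.null(meta)) {
    hab <- meta$habitat[match(sample_ids(x), meta$sample_id)]
    out$by_habitat <- lapply(split(seq_len(nrow(x$counts)), hab), function(idx)
      frac_table(x$counts[idx, , drop = FALSE]))
  }
  out
}

#' Write a hit table in 12-column tabular format plus cluster map
#'
#' @param hits data.frame from [gen_hit_table()].
#' @param path output path for the hit table.
#' @param cluster_map_path optional output path for the `ref_id`,
#'   `cluster` map.
#' @export
write_hit_table <- function(hits, path, cluster_map_path = NULL) {
  tab <- data.frame(hits$query_id, hits$ref_id, hits$percent_identity,
                    250L, 0L, 0L, 1L, 250L, 1L, 250L, 0, 400)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  if (!is.null(cluster_map_path)) {
    cm <- unique(data.frame(ref_id = hits$ref_id,
                            cluster = hits$ref_cluster,
                            stringsAsFactors = FALSE))
    cm <- cm[!is.na(cm$cluster), ]
    utils::write.table(cm, cluster_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  }
  invisible(path)
}
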