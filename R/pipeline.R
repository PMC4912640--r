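#' Assemble a pipeline run configuration
#'
#' Either pass a YAML file via `config` or override fields directly;
#' direct arguments take precedence over the file.
#'
#' @param config optional YAML path with the same field names.
#' @param shared,meta,taxonomy input paths (`.shared`/TSV table,
#'   metadata TSV, optional taxonomy TSV).
#' @param out_dir output directory.
#' @param low_abundance_frac,seawater_frac dataset filter thresholds.
#' @param chloroplast_label taxon substring removed via the taxonomy.
#' @param network_min_samples bipartite network occupancy threshold.
#' @param core_min_reps,core_prevalence,core_min_rel_abund core
#'   extraction parameters.
#' @param lv an [lv_config]; `NULL` skips interaction inference.
#' @param seed integer seed recorded in the manifest and used for all
#'   stochastic stages.
#' @return a `run_config` list.
#' @export
run_config <- function(config = NULL, shared = NULL, meta = NULL,
                       taxonomy = NULL, out_dir = "spongenet_out",
                       low_abundance_frac = 1e-5, seawater_frac = 1e-4,
                       chloroplast_label = "Chloroplast",
                       network_min_samples = 25,
                       core_min_reps = 47, core_prevalence = 0.85,
                       core_min_rel_abund = 0.01,
                       lv = lv_config("desk"), seed = 1) {
  cfg <- list(shared = shared, meta = meta, taxonomy = taxonomy,
              out_dir = out_dir,
              low_abundance_frac = low_abundance_frac,
              seawater_frac = seawater_frac,
              chloroplast_label = chloroplast_label,
              network_min_samples = network_min_samples,
              core_min_reps = core_min_reps,
              core_prevalence = core_prevalence,
              core_min_rel_abund = core_min_rel_abund,
              lv = lv, seed = seed)
  if (!is.null(config)) {
    y <- yaml::read_yaml(config)
    for (nm in names(y)) if (is.null(cfg[[nm]]) ||
                             identical(cfg[[nm]], formals(run_config)[[nm]]))
      cfg[[nm]] <- y[[nm]]
  }
  if (cfg$low_abundance_frac < 0 || cfg$low_abundance_frac > 1 ||
      cfg$seawater_frac < 0 || cfg$seawater_frac > 1)
    stop("filter fractions must lie in [0, 1]")
  structure(cfg, class = "run_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: read inputs, dataset filters (low-abundance, taxon,
#' seawater-like), diversity metrics, bipartite network with degree
#' fits and OTU classification, core extraction, sparse Lotka-Volterra
#' inference with variance decomposition and representative networks,
#' and a manifest hashing every artifact together with the
#' configuration snapshot.  A stage failure aborts with the stage name
#' while retaining the partial manifest on disk.
#'
#' @param cfg a [run_config].
#' @return the manifest (named list), invisibly written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$shared) || !file.exists(cfg$shared))
    stop("input count table not readable: ", cfg$shared %||% "<missing>")
  if (is.null(cfg$meta) || !file.exists(cfg$meta))
    stop("metadata file not readable: ", cfg$meta %||% "<missing>")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), artifacts = list())
  artifact <- function(name, path) {
    manifest$artifacts[[name]] <<- list(path = path,
                                        md5 = unname(tools::md5sum(path)))
    save_manifest()
  }
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      save_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  x <- stage("read", {
    if (grepl("\\.shared$", cfg$shared)) read_shared(cfg$shared)
    else read_count_tsv(cfg$shared)
  })
  meta <- stage("read", read_metadata(cfg$meta))

  x <- stage("filter", {
    xf <- filter_low_abundance(x, cfg$low_abundance_frac)
    if (!is.null(cfg$taxonomy) && file.exists(cfg$taxonomy))
      xf <- remove_taxon(xf, read_taxonomy(cfg$taxonomy), cfg$chloroplast_label)
    if (any(meta$habitat == "seawater"))
      xf <- remove_seawater_like(xf, meta, cfg$seawater_frac)
    xf
  })
  p <- file.path(cfg$out_dir, "filtered_counts.tsv")
  write_count_tsv(x, p); artifact("filtered_counts", p)

  div <- stage("metrics", diversity_table(x))
  p <- file.path(cfg$out_dir, "diversity.tsv")
  write_diversity_tsv(div, p); artifact("diversity", p)

  sponge_ids <- meta$sample_id[!meta$habitat %in% c("seawater", "sediment") &
                                 !is.na(meta$host_species)]
  xs <- subset_counts(x, samples = intersect(sample_ids(x), sponge_ids))
  net <- stage("network", build_network(xs, meta, cfg$network_min_samples))
  p <- file.path(cfg$out_dir, "network_edges.tsv")
  write_network(net, p); artifact("network_edges", p)

  fits <- stage("network", {
    # degenerate degree supports (tiny studies) yield no fit, not a failure
    ofit <- tryCatch(fit_truncated_power_law(ccdf(net$otu_degree)),
                     error = function(e) NULL)
    hfit <- tryCatch(fit_exponential(ccdf(net$host_degree)),
                     error = function(e) NULL)
    list(otu = if (!is.null(ofit)) unclass(ofit),
         host = if (!is.null(hfit)) unclass(hfit))
  })
  p <- file.path(cfg$out_dir, "degree_fits.json")
  jsonlite::write_json(fits, p, auto_unbox = TRUE, digits = NA, force = TRUE)
  artifact("degree_fits", p)

  cls <- stage("classify", classify_otus(net, xs, meta))
  p <- file.path(cfg$out_dir, "otu_classification.tsv")
  utils::write.table(cls$classification, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  artifact("otu_classification", p)

  hosts <- stage("cores", select_hosts(xs, meta, cfg$core_min_reps, cfg$seed))
  cores <- stage("cores", {
    out <- list()
    for (h in names(hosts)) {
      cs <- tryCatch(extract_core(hosts[[h]], cfg$core_prevalence,
                                  cfg$core_min_rel_abund, host_species = h),
                     error = function(e) NULL)
      if (!is.null(cs)) out[[h]] <- cs
    }
    out
  })
  core_sizes <- vapply(cores, function(cs) length(cs$otu_ids), 0L)
  p <- file.path(cfg$out_dir, "core_sizes.tsv")
  utils::write.table(data.frame(host_species = names(core_sizes),
                                core_size = as.vector(core_sizes)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  artifact("core_sizes", p)

  if (!is.null(cfg$lv) && length(cores)) {
    lv_out <- stage("core-lv", {
      res <- list()
      for (h in names(cores)) {
        if (length(cores[[h]]$otu_ids) < 2) next
        post <- sample_posterior(cores[[h]], cfg$lv)
        vs <- tryCatch(variance_decomposition(post), error = function(e) NULL)
        rn <- representative_network(post)
        res[[h]] <- list(
          summary = lv_summary(post),
          variance_shares = if (!is.null(vs)) vs$shares,
          connectance = rn$connectance,
          posterior_mean_connectance = rn$posterior_mean_connectance,
          interaction_types = as.list(classify_interactions(rn)$tally))
        pnet <- file.path(cfg$out_dir, paste0("representative_network_",
                                              gsub("\\W+", "_", h), ".tsv"))
        write_representative_network(rn, pnet)
        artifact(paste0("representative_network_", h), pnet)
      }
      res
    })
    p <- file.path(cfg$out_dir, "lv_results.json")
    jsonlite::write_json(lv_out, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    artifact("lv_results", p)
  }

  save_manifest()
  invisible(manifest)
}

#' Write the small synthetic study used by the test suite
#'
#' Six host species with eight replicates each plus seawater
#' background samples, written as `.shared`, metadata, and taxonomy
#' files; deterministic for a given seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return the directory path, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- community_spec(n_hosts = 6, n_otus = 120, replicates_per_host = 8,
                         depth = 2000, n_seawater_samples = 4,
                         n_seawater_otus = 30, gen_min = 4, spec_max = 2,
                         seed = seed)
  com <- gen_bipartite_community(spec)
  write_shared(com$counts, file.path(dir, "community.shared"))
  utils::write.table(com$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  lineages <- ifelse(seq_along(otu_ids(com$counts)) %% 40 == 0,
                     "Bacteria;Cyanobacteria;Chloroplast;unclassified",
                     "Bacteria;Proteobacteria;unclassified")
  utils::write.table(data.frame(otu_id = otu_ids(com$counts),
                                taxonomy = lineages),
                     file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  hosts <- sort(unique(stats::na.omit(com$meta$host_species)))
  tt <- gen_tree_and_traits(length(hosts), model = "BM", seed = seed)
  tt$tree$tip.label <- hosts
  ape::write.tree(tt$tree, file.path(dir, "host_tree.nwk"))
  invisible(dir)
}
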