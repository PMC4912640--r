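#' Read a mothur `.shared` OTU table
#'
#' Parses the mothur shared-file dialect: tab-separated with header
#' `label Group numOtus Otu00001 ...`, one row per sample (`Group`).
#' The `numOtus` field of every row is validated against the actual
#' number of OTU columns.
#'
#' @param path path to a `.shared` file.
#' @return a [count_table].
#' @export
read_shared <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("shared file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 3 || tolower(header[2]) != "group")
    stop("not a mothur shared file (expected 'label<TAB>Group<TAB>numOtus...'): ", path)
  otus <- header[-(1:3)]
  width <- length(header)
  rows <- fields[-1]
  ragged <- which(lengths(rows) != width)
  if (length(ragged))
    stop("ragged row in shared file at line ", ragged[1] + 1L, " of ", path)
  groups <- vapply(rows, `[[`, "", 2L)
  if (anyDuplicated(groups))
    stop("duplicate Group in shared file: ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "))
  numotus <- as.integer(vapply(rows, `[[`, "", 3L))
  if (any(numotus != length(otus)))
    stop("numOtus mismatch at line ",
         which(numotus != length(otus))[1] + 1L,
         ": declared ", numotus[numotus != length(otus)][1],
         ", parsed ", length(otus))
  vals <- vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-(1:3)]))
    if (anyNA(v) || any(v != round(v)))
      stop("non-integer count in shared file row for Group ", r[2])
    v
  }, numeric(length(otus)))
  m <- t(vals)
  dimnames(m) <- list(groups, otus)
  count_table(m)
}

#' Write a count table in mothur `.shared` dialect
#'
#' @param x a [count_table].
#' @param path output path.
#' @param label mothur distance label (first column), default `"0.03"`.
#' @export
write_shared <- function(x, path, label = "0.03") {
  stopifnot_count_table(x)
  m <- x$counts
  header <- c("label", "Group", "numOtus", colnames(m))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(label, rownames(m)[i], ncol(m), format(m[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), body), path, sep = "\n")
  invisible(path)
}

#' Read a plain TSV count table
#'
#' Accepts samples-by-OTUs or OTUs-by-samples layouts; orientation is
#' auto-detected from the header corner cell (`otu_id` means rows are
#' OTUs) or forced with `orientation`.
#'
#' @param path TSV path; first column holds row ids.
#' @param orientation `"auto"`, `"samples_x_otus"` or `"otus_x_samples"`.
#' @return a [count_table].
#' @export
read_count_tsv <- function(path, orientation = c("auto", "samples_x_otus", "otus_x_samples")) {
  orientation <- match.arg(orientation)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  corner <- tolower(names(d)[1])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "auto")
    orientation <- if (grepl("otu", corner)) "otus_x_samples" else "samples_x_otus"
  if (orientation == "otus_x_samples") m <- t(m)
  count_table(m)
}

#' @rdname read_count_tsv
#' @param x a [count_table] to write (samples x OTUs, id column `sample_id`).
#' @export
write_count_tsv <- function(x, path) {
  stopifnot_count_table(x)
  d <- data.frame(sample_id = rownames(x$counts), x$counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with at least `sample_id` and either `host_species`,
#' `habitat`, or both.  Samples without a `habitat` column are assumed
#' to be host-associated (`habitat = "sponge"`).
#'
#' @param path TSV path.
#' @return data.frame with columns `sample_id`, `host_species`, `habitat`.
#' @export
read_metadata <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) stop("metadata needs a sample_id column")
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  if (!"habitat" %in% names(d)) d$habitat <- "sponge"
  if (!"host_species" %in% names(d)) d$host_species <- NA_character_
  d[, c("sample_id", "host_species", "habitat",
        setdiff(names(d), c("sample_id", "host_species", "habitat")))]
}

#' Read an OTU taxonomy table
#'
#' @param path TSV with columns `otu_id` and `taxonomy` (ranked lineage
#'   string, e.g. `"Bacteria;Cyanobacteria;Chloroplast;..."`).
#' @return data.frame, one row per OTU.
#' @export
read_taxonomy <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "taxonomy") %in% names(d)))
    stop("taxonomy table needs otu_id and taxonomy columns")
  if (anyDuplicated(d$otu_id)) stop("taxonomy has duplicate otu_id rows")
  d
}

#' Read a BIOM-format OTU table (optional reader)
#'
#' Thin wrapper over the biomformat package; only used when inputs
#' arrive as BIOM rather than `.shared`/TSV.
#'
#' @param path a BIOM file.
#' @return a [count_table].
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the biomformat package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix") # OTUs x samples in BIOM
  count_table(t(m))
}

#' Write a square distance matrix as TSV
#'
#' @param d a `dist` or square matrix with ids.
#' @param path output path.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as.matrix(d)
  out <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
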