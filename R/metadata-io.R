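#' Validate a sample-metadata table
#'
#' Metadata drives every grouping in the package: replicate pairing, region
#' averaging, donor (batch) assignment and the neocortex / non-neocortex
#' split. Required columns: `sample_id`, `donor`, `region`, `region_class`
#' (`neocortex` or `non_neocortex`), `hemisphere` (`L`/`R`), `replicate`
#' (integer), `batch`.
#'
#' @param meta data.frame of per-sample annotations.
#' @return `meta` (with `replicate` coerced to integer), invisibly usable.
#' @export
validate_sample_metadata <- function(meta) {
  req <- c("sample_id", "donor", "region", "region_class", "hemisphere",
           "replicate", "batch")
  miss <- setdiff(req, colnames(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if (!all(meta$region_class %in% c("neocortex", "non_neocortex")))
    stop("region_class must be 'neocortex' or 'non_neocortex'")
  if (!all(meta$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  # region_class must be a function of region
  tab <- unique(meta[, c("region", "region_class")])
  if (anyDuplicated(tab$region))
    stop("a region maps to both region classes: ",
         paste(tab$region[duplicated(tab$region)], collapse = ", "))
  meta$replicate <- as.integer(meta$replicate)
  meta
}

#' Read sample metadata from TSV
#' @param path tab-delimited file with the columns listed in
#'   [validate_sample_metadata()].
#' @return A validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' Read a probe-to-gene annotation table
#' @param path 2-column TSV (`probe_id`, `gene_id`). Probe ids must be
#'   unique; a gene may own several probes.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_annotation <- function(path) {
  annot <- utils::read.delim(path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
  validate_probe_annotation(annot)
}

validate_probe_annotation <- function(annot) {
  if (!all(c("probe_id", "gene_id") %in% colnames(annot)))
    stop("annotation needs columns probe_id, gene_id")
  if (anyDuplicated(annot$probe_id))
    stop("duplicate probe_id in annotation")
  annot[, c("probe_id", "gene_id")]
}

#' Check that a matrix's samples are all annotated
#'
#' Every sample id used jointly with a metadata table must appear in it
#' exactly once.
#'
#' @param mat an `ExpressionMatrix`.
#' @param meta validated sample metadata.
#' @return invisibly TRUE; error otherwise.
#' @export
check_samples_annotated <- function(mat, meta) {
  miss <- setdiff(colnames(mat$values), meta$sample_id)
  if (length(miss))
    stop("samples missing from metadata: ",
         paste(utils::head(miss, 5), collapse = ", "))
  invisible(TRUE)
}

#' Mean expression per region
#'
#' Averages columns of a matrix within each region of `meta`, optionally
#' restricted to one region class. Used for the "highest average expression
#' across regions" probe designation and the per-gene reproducibility
#' metrics.
#'
#' @param mat an `ExpressionMatrix`.
#' @param meta sample metadata covering `mat`'s samples.
#' @param region_class optional `"neocortex"` or `"non_neocortex"` filter.
#' @return numeric matrix, features x regions.
#' @export
region_mean_matrix <- function(mat, meta, region_class = NULL) {
  check_samples_annotated(mat, meta)
  meta <- meta[meta$sample_id %in% colnames(mat$values), , drop = FALSE]
  if (!is.null(region_class))
    meta <- meta[meta$region_class == region_class, , drop = FALSE]
  if (nrow(meta) == 0) stop("no samples left after region_class filter")
  regions <- sort(unique(meta$region))
  out <- vapply(regions, function(rg) {
    ids <- meta$sample_id[meta$region == rg]
    rowMeans(mat$values[, ids, drop = FALSE])
  }, numeric(nrow(mat$values)))
  if (is.null(dim(out)))  # single feature
    out <- matrix(out, nrow = 1,
                  dimnames = list(rownames(mat$values), regions))
  out
}
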