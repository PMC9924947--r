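#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are removed with a warning;
#' duplicate set names are an error. Empty member lists are allowed.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stopf("GMT parse error at line %d: fewer than 2 fields", i)
    nm <- fields[1]
    if (nm %in% names(sets)) stopf("duplicate gene-set name '%s'", nm)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warnf("gene set '%s': duplicate members removed", nm)
      members <- unique(members)
    }
    sets[[nm]] <- members
    descs[nm] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description (default `"na"`).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("every gene set needs a name")
  if (anyDuplicated(names(sets))) stopf("duplicate gene-set names")
  descriptions <- descriptions %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate an individual-level survival table
#'
#' Expects tab-delimited text with header columns `strain`, `assay`,
#' `replicate`, `animal_id`, `time`, `event`, `control_group`. Times must be
#' positive and events 0/1; offending rows are named in the error.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("strain", "assay", "replicate", "animal_id", "time", "event",
              "control_group")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stopf("survival table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  bad_time <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_time))
    stopf("non-positive survival time at row(s): %s",
          paste(utils::head(bad_time, 5), collapse = ", "))
  bad_event <- which(!df$event %in% c(0, 1))
  if (length(bad_event))
    stopf("event must be 0/1; offending row(s): %s",
          paste(utils::head(bad_event, 5), collapse = ", "))
  unknown <- setdiff(unique(df$control_group), unique(df$strain))
  if (length(unknown))
    stopf("control group(s) with no records: %s",
          paste(unknown, collapse = ", "))
  df
}

#' Write a survival table
#'
#' @param survival survival data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_survival <- function(survival, path) {
  utils::write.table(survival, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix and its sample metadata
#'
#' Counts are tab-delimited with gene ids in the first column and sample ids
#' in the header; metadata must carry `sample`, `strain`, `batch`,
#' `replicate` and cover every count column. Counts must be non-negative
#' integers.
#'
#' @param counts_path count matrix file.
#' @param metadata_path sample metadata file.
#' @return list with `counts` (integer matrix) and `metadata` (data.frame).
#' @export
read_counts <- function(counts_path, metadata_path) {
  raw <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  genes <- raw[[1]]
  if (anyDuplicated(genes)) stopf("duplicate gene ids in count matrix")
  counts <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample ids in count matrix")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  rownames(counts) <- genes
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  needed <- c("sample", "strain", "batch", "replicate")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols))
    stopf("metadata lacks column(s): %s", paste(missing_cols, collapse = ", "))
  orphan <- setdiff(colnames(counts), metadata$sample)
  if (length(orphan))
    stopf("sample(s) present in counts but absent from metadata: %s",
          paste(utils::head(orphan, 5), collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample), ,
                       drop = FALSE]
  list(counts = counts, metadata = metadata)
}

#' Write a count matrix and metadata
#'
#' @param counts gene x sample matrix.
#' @param metadata sample metadata.
#' @param counts_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(counts, metadata, counts_path, metadata_path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}
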