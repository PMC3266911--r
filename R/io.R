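# Tabular I/O. All generic tables are tab-separated UTF-8 with one header
# row; genomic intervals on disk are BED (0-based half-open, headerless).

#' @rdname oncoamp_io
#' @export
write_probes_tsv <- function(probes, path) {
  utils::write.table(probes[, c("probe_id", "chrom", "pos")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname oncoamp_io
#' @export
read_probes_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("probe_id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!is.numeric(df$pos)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$pos))))[1]
    stop(path, ": non-numeric pos at data row ", bad)
  }
  df$probe_id <- as.character(df$probe_id)
  df$chrom <- as.character(df$chrom)
  df
}

#' Tabular and genomic-interval file I/O
#'
#' Readers/writers for the pipeline's on-disk formats: probe annotation TSV
#' (`probe_id`, `chrom`, `pos`), numeric matrices as TSV with an `id` key
#' column (probes or genes x samples), gene models as 4-column BED (0-based
#' half-open), and JSON manifests. Matrix readers validate that every data
#' cell is numeric and report the offending row and column. All round-trip:
#' `read(write(x)) == x`.
#'
#' @param x,m,probes,genes,path,what objects/paths as appropriate.
#' @name oncoamp_io
NULL

#' @rdname oncoamp_io
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname oncoamp_io
#' @export
read_matrix_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = 1)))
  if (names(df)[1] != "id") stop(path, ": first column must be 'id'")
  ids <- df$id
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      num <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]))[1]
      stop(sprintf("%s: non-numeric cell at row %d, column '%s'",
                   path, bad, names(vals)[j]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' @rdname oncoamp_io
#' @export
write_genes_bed <- function(genes, path) {
  bed <- genes[, c("chrom", "start", "end", "name")]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname oncoamp_io
#' @export
read_genes_bed <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  if (ncol(df) < 4) stop(path, ": BED needs 4 columns (chrom start end name)")
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$start))) |
                 is.na(suppressWarnings(as.numeric(df$end))))[1]
    stop(path, ": non-numeric interval at line ", bad)
  }
  if (any(df$end <= df$start))
    stop(path, ": end <= start at line ", which(df$end <= df$start)[1])
  df[, c("name", "chrom", "start", "end")]
}

#' @rdname oncoamp_io
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname oncoamp_io
#' @export
read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' @rdname oncoamp_io
#' @export
write_segments_tsv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    cbind(sample = p$sample_id, p$segments[, c("chrom", "start", "end", "cn",
                                               "b", "label")])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
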