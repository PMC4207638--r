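# On-disk formats.  Internal canonical coordinates are 1-based inclusive
# (the convention of genome browsers and the published tables); BED is
# 0-based half-open and is converted only at the file boundary.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return \code{read_chrom_sizes}: a \code{genome_build}.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  build_genome(spec = df)
}

#' @rdname read_chrom_sizes
#' @param genome a \code{genome_build} to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  write_tsv(as.data.frame(genome), path)
}

#' Read / write a probe map
#' @param path file path (TSV: probe_id, chrom, start, end, category).
#' @return \code{read_probe_map}: a \code{probe_map}.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "category")
  if (!all(need %in% names(pm)))
    stop("probe map is missing column(s): ",
         paste(setdiff(need, names(pm)), collapse = ", "))
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' @rdname read_probe_map
#' @param probe_map a \code{probe_map} to write.
#' @export
write_probe_map <- function(probe_map, path) {
  write_tsv(as.data.frame(probe_map), path)
}

#' Read a per-probe log2-ratio table into a hybridization
#'
#' The table needs \code{probe_id} and \code{log2} columns.  Values are
#' aligned to the probe map by probe id; ids absent from the map are
#' reported with a warning, and map probes absent from the file are marked
#' missing (NA).
#'
#' @param path TSV file path.
#' @param probe_map the \code{probe_map} to align against.
#' @param sample_id,reference_id,tissue,sex,breed metadata for the result.
#' @return a \code{hybridization}.
#' @export
read_log2_table <- function(path, probe_map, sample_id = NULL,
                            reference_id = "REF", tissue = "blood",
                            sex = "F", breed = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty log2 table: ", path)
  if (!all(c("probe_id", "log2") %in% names(df)))
    stop("log2 table needs 'probe_id' and 'log2' columns: ", path)
  bad <- which(!is.na(df$log2) & !is.finite(df$log2))
  if (length(bad))
    stop("non-finite log2 value at line ", bad[1] + 1L, " of ", path)
  unknown <- setdiff(df$probe_id, probe_map$probe_id)
  if (length(unknown))
    warning(length(unknown), " unknown probe id(s) ignored (e.g. ",
            unknown[1], ")")
  v <- df$log2[match(probe_map$probe_id, df$probe_id)]
  hyb <- list(sample_id = sample_id %||%
                sub("\\.tsv$", "", basename(path)),
              reference_id = reference_id, tissue = tissue, sex = sex,
              breed = breed, log2 = v)
  class(hyb) <- "hybridization"
  hyb
}

#' Write a hybridization as a per-probe log2 table
#' @param hyb a \code{hybridization}.
#' @param probe_map the matching \code{probe_map}.
#' @param path file path.
#' @export
write_log2_table <- function(hyb, probe_map, path) {
  write_tsv(data.frame(probe_id = probe_map$probe_id, log2 = hyb$log2),
            path)
}

#' Write intervals as BED
#'
#' Converts internal 1-based inclusive intervals to standard BED (0-based,
#' half-open): start_bed = start - 1, end_bed = end.  Extra columns are
#' appended after the name column.
#'
#' @param intervals data.frame with chrom, start, end.
#' @param path output path.
#' @param name optional name column values (4th BED column).
#' @param extra optional data.frame of extra columns.
#' @export
write_bed <- function(intervals, path, name = NULL, extra = NULL) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = format(intervals$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(intervals$end, scientific = FALSE,
                                 trim = TRUE))
  if (!is.null(name)) bed$name <- name
  if (!is.null(extra)) bed <- cbind(bed, extra)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#' @param path BED file path.
#' @return data.frame chrom, start, end (1-based inclusive), plus name if
#'   present.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) return(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()))
  out <- data.frame(chrom = df[[1]], start = as.numeric(df[[2]]) + 1,
                    end = as.numeric(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- df[[4]]
  out
}

#' Read gene annotation from BED or GFF3
#'
#' GFF3 is 1-based inclusive and is filtered to the requested feature type
#' (default \code{gene}); the gene id is taken from the \code{ID=} (or
#' \code{gene_id=}) attribute, falling back to a positional id.  BED input
#' is converted from 0-based half-open.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"bed"} or \code{"gff3"}.
#' @param feature GFF3 feature type to keep.
#' @return data.frame with columns gene_id, chrom, start, end.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3"),
                                 feature = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  if (format == "bed") {
    b <- read_bed(path)
    return(data.frame(gene_id = b$name %||%
                        paste0("gene", seq_len(nrow(b))),
                      chrom = b$chrom, start = b$start, end = b$end,
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(data.frame(gene_id = character(),
                                        chrom = character(),
                                        start = numeric(), end = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nbad <- which(lengths(fields) < 9)
  if (length(nbad)) stop("malformed GFF3 line ", nbad[1], " in ", path)
  keep <- vapply(fields, function(f) f[3] == feature, logical(1))
  fields <- fields[keep]
  if (!length(fields)) return(data.frame(gene_id = character(),
                                         chrom = character(),
                                         start = numeric(), end = numeric()))
  ids <- vapply(seq_along(fields), function(i) {
    attrs <- fields[[i]][9]
    m <- regmatches(attrs, regexec("(?:^|;)(?:ID|gene_id)=([^;]+)", attrs))[[1]]
    if (length(m) == 2) m[2] else paste0("gene", i)
  }, character(1))
  data.frame(gene_id = ids,
             chrom = vapply(fields, `[`, character(1), 1),
             start = as.numeric(vapply(fields, `[`, character(1), 4)),
             end = as.numeric(vapply(fields, `[`, character(1), 5)),
             stringsAsFactors = FALSE)
}

#' Read / write CNV call tables
#' @param path TSV path (1-based inclusive coordinates).
#' @return \code{read_calls}: a \code{cnv_calls} data.frame.
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' @rdname read_calls
#' @param calls a \code{cnv_calls} data.frame to write.
#' @export
write_calls <- function(calls, path) write_tsv(as.data.frame(calls), path)

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of
#'   \code{\link{run_pipeline}}'s config list.
#' @return a named list.
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)
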