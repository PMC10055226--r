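#' Write hotspot regions (or any stranded intervals) to a BED6 file
#'
#' Coordinates are written 0-based half-open, the BED convention. The `name`
#' and `score` columns are taken from `records` when present (name falls back
#' to `region_<i>`, score to 0).
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `strand`
#'   and optionally `name`, `score` (0-based half-open).
#' @param path Output file path; written atomically.
#' @return Invisibly, `path`.
#' @export
write_sirta_bed <- function(records, path) {
  check_intervals(records, "records", need_strand = TRUE)
  gr <- df_to_gr(records)
  S4Vectors::mcols(gr)$name <-
    records$name %||% paste0("region_", seq_len(nrow(records)))
  S4Vectors::mcols(gr)$score <- records$score %||% rep(0, nrow(records))
  write_atomic(function(tmp) rtracklayer::export(gr, tmp, format = "BED"),
               path)
}

#' Read a BED file into a 0-based half-open interval data.frame
#'
#' @param path Path to a BED (3-6 column) file.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand` and,
#'   when present in the file, `name` and `score`.
#' @export
read_sirta_bed <- function(path) {
  if (!file.exists(path)) stop_validation("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  gr_to_df(gr)
}

#' Read stranded gene intervals from a GFF3 annotation
#'
#' Imports a GFF3 file and returns intervals of the requested feature type
#' (by default `gene`), converted to 0-based half-open coordinates for use
#' with [classify_genic()].
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type(s) to keep (default `"gene"`).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand` and
#'   `gene_id` (the feature ID or Name when available).
#' @export
read_gene_annotations <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop_validation("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  df <- gr_to_df(gr)
  id <- df$ID %||% df$Name %||% paste0("gene_", seq_len(nrow(df)))
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             strand = df$strand, gene_id = id, stringsAsFactors = FALSE)
}
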