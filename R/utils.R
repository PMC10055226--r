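#' @useDynLib sirtascan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods is
#' @importFrom stats pbinom runif sd setNames
#' @importFrom utils head write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Validation errors carry a dedicated class so the CLI can map them to
## exit code 1 (runtime failures map to 2).
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("sirtascan_validation_error",
                                             "error", "condition")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

## Accept a plain character scalar, a DNAString, or a length-1 DNAStringSet;
## return an uppercase character scalar. Soft-masking (lowercase) is ignored.
as_seq_string <- function(x, arg = "seq") {
  if (is(x, "DNAString") || is(x, "DNAStringSet") || is(x, "BString"))
    x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_validation("'", arg, "' must be a single nucleotide string")
  toupper(x)
}

## Coerce a genome to a named DNAStringSet.
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x)))
      names(x) <- paste0("chr", seq_along(x))
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  stop_validation("genome must be a DNAStringSet or named character vector")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Chromosome number from a name like "chrVI", "VI", "chr6" or "6".
roman_to_int <- function(x) {
  out <- suppressWarnings(as.integer(as.roman(x)))
  out
}

chrom_to_number <- function(chrom) {
  x <- sub("^chromosome[ _]?", "", sub("^chr", "", chrom, ignore.case = TRUE),
           ignore.case = TRUE)
  n <- suppressWarnings(as.integer(x))
  rom <- roman_to_int(x)
  ifelse(!is.na(n), n, rom)
}

## Round half up to the nearest unit (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

## Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(master, k) {
  as.integer((as.double(master) %% 1000003L + 9973 * as.double(k) + 1) %%
               2147483646L) + 1L
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop_validation("'seed' must be a single integer")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

## 0-based half-open interval data.frame sanity check.
check_intervals <- function(df, what = "intervals",
                            need_strand = FALSE) {
  req <- c("chrom", "start", "end", if (need_strand) "strand")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_validation(what, " missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$end <= df$start))
    stop_validation(what, " contain empty or inverted ranges")
  df
}

## data.frame (0-based half-open) <-> GRanges (1-based closed) conversion,
## used internally for overlap machinery.
df_to_gr <- function(df, ignore_strand = FALSE) {
  strand <- if (!ignore_strand && "strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  gr
}

gr_to_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  df
}

## Atomic write helper: write to a temp file in the destination directory,
## then rename, so failures never leave partial output.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
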