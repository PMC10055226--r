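#' Genome layout: per-chromosome analysis bounds and landmark intervals
#'
#' A genome layout records, for each chromosome, its length, the analysis
#' bounds obtained after trimming terminal perfect telomeric repeats, the
#' centromere interval, and optional lists of subtelomeric (X/Y' element)
#' and nonessential (distal to the last essential gene) intervals. All
#' coordinates are 0-based half-open.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`,
#'   `analysis_start`, `analysis_end`, `cen_start`, `cen_end` and optionally
#'   `number` (chromosome number; parsed from the name when absent).
#' @param subtelomeres Optional data.frame with columns `chrom`, `start`,
#'   `end` listing subtelomeric X/Y' element intervals.
#' @param nonessential Optional data.frame with columns `chrom`, `start`,
#'   `end` listing regions distal to the last essential gene.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(data.frame(chrom = "chrI", length = 1000,
#'                          analysis_start = 0, analysis_end = 1000,
#'                          cen_start = 500, cen_end = 510))
#' @export
genome_layout <- function(chromosomes, subtelomeres = NULL,
                          nonessential = NULL) {
  req <- c("chrom", "length", "analysis_start", "analysis_end",
           "cen_start", "cen_end")
  miss <- setdiff(req, names(chromosomes))
  if (length(miss))
    stop_validation("layout missing column(s): ", paste(miss, collapse = ", "))
  ch <- chromosomes
  ch$chrom <- as.character(ch$chrom)
  if (anyDuplicated(ch$chrom))
    stop_validation("duplicate chromosome names in layout")
  if (!"number" %in% names(ch)) ch$number <- chrom_to_number(ch$chrom)
  bad <- ch$analysis_start < 0 | ch$analysis_end > ch$length |
    ch$analysis_end <= ch$analysis_start
  if (any(bad))
    stop_validation("empty or out-of-bounds analysis interval for: ",
                    paste(ch$chrom[bad], collapse = ", "))
  bad <- ch$cen_start < ch$analysis_start | ch$cen_end > ch$analysis_end |
    ch$cen_end <= ch$cen_start
  if (any(bad))
    stop_validation("centromere outside analysis bounds for: ",
                    paste(ch$chrom[bad], collapse = ", "))
  chk_iv <- function(iv, what) {
    if (is.null(iv) || !nrow(iv)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    iv <- check_intervals(iv[c("chrom", "start", "end")], what)
    iv$chrom <- as.character(iv$chrom)
    unknown <- setdiff(iv$chrom, ch$chrom)
    if (length(unknown))
      stop_validation(what, " reference unknown chromosome(s): ",
                      paste(unknown, collapse = ", "))
    len <- ch$length[match(iv$chrom, ch$chrom)]
    if (any(iv$start < 0 | iv$end > len))
      stop_validation(what, " outside chromosome bounds")
    iv
  }
  structure(list(chromosomes = ch,
                 subtelomeres = chk_iv(subtelomeres, "subtelomere intervals"),
                 nonessential = chk_iv(nonessential, "nonessential intervals")),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("Genome layout: %d chromosome(s), %d subtelomere interval(s), %d nonessential interval(s)\n",
              nrow(x$chromosomes), nrow(x$subtelomeres), nrow(x$nonessential)))
  print(head(x$chromosomes, 5))
  invisible(x)
}

#' Read a genome layout from a YAML file
#'
#' The file holds a top-level `chromosomes` list; each entry has `chrom`,
#' `length`, `analysis_start`, `analysis_end`, `centromere: [start, end]`,
#' and optional `number`, `subtelomeres` and `nonessential` (lists of
#' `[start, end]` pairs). Coordinates are 0-based half-open unless
#' `one_based = TRUE`, in which case they are interpreted as 1-based
#' inclusive and converted.
#'
#' @param path Path to the YAML layout file.
#' @param one_based Set `TRUE` if the file uses 1-based inclusive coordinates.
#' @return A [genome_layout()] object.
#' @export
read_genome_layout <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop_validation("layout file not found: ", path)
  y <- yaml::read_yaml(path)
  entries <- y$chromosomes %||% stop_validation(
    "layout YAML must contain a 'chromosomes' list")
  adj <- function(s, e) {
    if (one_based) c(s - 1L, e) else c(s, e)
  }
  rows <- lapply(entries, function(e) {
    ce <- adj(e$centromere[[1]], e$centromere[[2]])
    an <- adj(e$analysis_start, e$analysis_end)
    data.frame(chrom = e$chrom, length = e$length,
               analysis_start = an[1], analysis_end = an[2],
               cen_start = ce[1], cen_end = ce[2],
               number = e$number %||% NA_integer_)
  })
  ch <- do.call(rbind, rows)
  if (all(is.na(ch$number))) ch$number <- NULL
  ivs <- function(field) {
    out <- lapply(entries, function(e) {
      v <- e[[field]]
      if (is.null(v) || !length(v)) return(NULL)
      do.call(rbind, lapply(v, function(p) {
        ab <- adj(p[[1]], p[[2]])
        data.frame(chrom = e$chrom, start = ab[1], end = ab[2])
      }))
    })
    out <- do.call(rbind, out)
    out
  }
  genome_layout(ch, subtelomeres = ivs("subtelomeres"),
                nonessential = ivs("nonessential"))
}

## A permissive layout covering each chromosome end to end, used by the
## simulators and by scans of ad-hoc genomes. The centromere is placed at
## the sequence midpoint (2 bp) unless supplied.
default_layout <- function(genome) {
  genome <- as_genome(genome)
  len <- Biostrings::width(genome)
  mid <- pmax(1L, len %/% 2L)
  genome_layout(data.frame(chrom = names(genome), length = len,
                           analysis_start = 0L, analysis_end = len,
                           cen_start = mid - 1L, cen_end = mid + 1L))
}

layout_row <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$chrom)
  if (is.na(i))
    stop_validation("chromosome '", chrom, "' has no layout entry")
  layout$chromosomes[i, ]
}

## Analysis segments of one chromosome: the analysis interval, minus
## subtelomeric intervals when exclude_subtelomeres is TRUE. Returned as a
## data.frame of 0-based half-open [start, end) segments. Implemented by
## adjusting scan bounds (not post-filtering) so windows never straddle an
## excised boundary.
chrom_segments <- function(layout, chrom, exclude_subtelomeres = FALSE) {
  row <- layout_row(layout, chrom)
  segs <- data.frame(start = row$analysis_start, end = row$analysis_end)
  if (!exclude_subtelomeres) return(segs)
  sub <- layout$subtelomeres[layout$subtelomeres$chrom == chrom, , drop = FALSE]
  if (!nrow(sub)) return(segs)
  keep <- IRanges::setdiff(
    IRanges::IRanges(start = segs$start + 1L, end = segs$end),
    IRanges::reduce(IRanges::IRanges(start = sub$start + 1L, end = sub$end)))
  data.frame(start = IRanges::start(keep) - 1L, end = IRanges::end(keep))
}
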