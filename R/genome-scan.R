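#' Scan a genome for telomere-addition hotspot regions
#'
#' Runs the sliding-window tract scorer over both strands of every
#' chromosome, restricted to the layout's analysis bounds (terminal telomeric
#' repeats trimmed) and, optionally, with subtelomeric X/Y' intervals excised
#' by adjusting the scan bounds so that no window straddles an excised
#' boundary. Above-threshold windows are clustered per strand into scored
#' regions (see [cluster_windows()]), which are then annotated with
#' chromosome arm, TG/CA orientation, a location-encoding name, and
#' subtelomere/nonessential membership flags.
#'
#' The minus strand is scanned as the reverse complement and window
#' coordinates are mapped back to the forward strand, so all reported
#' intervals are forward-strand 0-based half-open.
#'
#' Orientation is a pure function of arm and strand: a region whose TG-rich
#' strand matches the strand carrying the 3' TG overhang at the nearest
#' telomere (minus strand on left arms, plus strand on right arms) is in the
#' TG orientation; otherwise it is CA-oriented.
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @param layout A [genome_layout()]; every sequence must have an entry.
#' @param params A [scoring_params()]. The published genome-wide analysis
#'   used `scoring_params(ggtgg_penalty = 1.5)` (window 75, step 1,
#'   threshold 20), which is the default here.
#' @param exclude_subtelomeres Excise the layout's subtelomeric intervals
#'   before scanning (default `FALSE`).
#' @return A data.frame with one row per region and columns `chrom`, `start`,
#'   `end`, `strand`, `score`, `n_windows`, `name`, `arm`, `orientation`,
#'   `in_subtelomere`, `in_nonessential`.
#' @export
scan_genome <- function(genome, layout,
                        params = scoring_params(ggtgg_penalty = 1.5),
                        exclude_subtelomeres = FALSE) {
  genome <- as_genome(genome)
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "scoring_params"))
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop_validation("genome sequences must be named")
  out <- list()
  for (chrom in names(genome)) {
    row <- layout_row(layout, chrom)  # errors if missing
    n <- length(genome[[chrom]])  # DNAString length in nt
    if (row$analysis_end > n)
      stop_validation("analysis bounds for '", chrom,
                      "' exceed sequence length (", n, ")")
    segs <- chrom_segments(layout, chrom, exclude_subtelomeres)
    for (k in seq_len(nrow(segs))) {
      s0 <- segs$start[k]
      s1 <- segs$end[k]
      s <- as.character(Biostrings::subseq(genome[[chrom]], s0 + 1L, s1))
      for (strand in c("+", "-")) {
        scanned <- if (strand == "+") s else revcomp(s)
        win <- scan_sequence(scanned, params, mode = "signal")
        if (strand == "-") {
          L <- nchar(s)
          fwd_start <- L - win$end
          win <- data.frame(start = fwd_start, end = L - win$start,
                            score = win$score)
          win <- win[order(win$start), , drop = FALSE]
        }
        reg <- cluster_windows(win, params$cluster_threshold)
        if (!nrow(reg)) next
        reg$start <- reg$start + s0
        reg$end <- reg$end + s0
        reg <- data.frame(chrom = chrom, reg[c("start", "end")],
                          strand = strand, reg[c("score", "n_windows")])
        out[[length(out) + 1L]] <- reg
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), n_windows = integer(0))
  } else {
    res <- do.call(rbind, out)
    res <- res[order(match(res$chrom, names(genome)), res$start, res$strand), ]
    rownames(res) <- NULL
  }
  annotate_regions(res, layout)
}

## Arm assignment (region midpoint relative to the centromere midpoint),
## TG/CA orientation, naming, and landmark membership flags.
annotate_regions <- function(records, layout) {
  if (!nrow(records)) {
    records$name <- character(0)
    records$arm <- character(0)
    records$orientation <- character(0)
    records$in_subtelomere <- logical(0)
    records$in_nonessential <- logical(0)
    return(records)
  }
  ch <- layout$chromosomes
  i <- match(records$chrom, ch$chrom)
  cen_mid <- (ch$cen_start[i] + ch$cen_end[i]) / 2
  mid <- (records$start + records$end) / 2
  records$arm <- ifelse(mid < cen_mid, "L", "R")
  records$orientation <- ifelse(
    (records$arm == "L" & records$strand == "-") |
      (records$arm == "R" & records$strand == "+"), "TG", "CA")
  records$name <- name_sirta(records, layout)
  records$in_subtelomere <- overlaps_any(records, layout$subtelomeres)
  records$in_nonessential <- overlaps_any(records, layout$nonessential)
  records[c("chrom", "start", "end", "strand", "score", "n_windows",
            "name", "arm", "orientation", "in_subtelomere",
            "in_nonessential")]
}

overlaps_any <- function(records, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, nrow(records)))
  hits <- GenomicRanges::countOverlaps(
    df_to_gr(records, ignore_strand = TRUE),
    df_to_gr(intervals, ignore_strand = TRUE),
    ignore.strand = TRUE)
  hits > 0L
}

#' Name hotspot regions by chromosome, arm, and kilobase position
#'
#' Builds the field's standard name for a region:
#' `"{chromosome number}{arm}{kb}({strand})"`, where `kb` is the region's
#' forward-strand start coordinate in bp divided by 1000 and rounded half-up
#' to the nearest kilobase (the distance from the left telomere), e.g.
#' `"6R210(+)"` or `"9L44(-)"`.
#'
#' @param records data.frame with columns `chrom`, `start`, `strand` and
#'   optionally `arm` (computed from the layout's centromere when absent;
#'   `end` is then also required).
#' @param layout A [genome_layout()] used for chromosome numbers and, if
#'   needed, centromere positions.
#' @return Character vector of names, one per row of `records`.
#' @export
name_sirta <- function(records, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  ch <- layout$chromosomes
  i <- match(records$chrom, ch$chrom)
  if (anyNA(i))
    stop_validation("chromosome '",
                    records$chrom[which(is.na(i))[1]],
                    "' has no layout entry")
  num <- ch$number[i]
  if (anyNA(num))
    stop_validation("chromosome number could not be determined; add a ",
                    "'number' column to the layout")
  arm <- records$arm
  if (is.null(arm)) {
    cen_mid <- (ch$cen_start[i] + ch$cen_end[i]) / 2
    arm <- ifelse((records$start + records$end) / 2 < cen_mid, "L", "R")
  }
  kb <- round_half_up(records$start / 1000)
  sprintf("%d%s%d(%s)", num, arm, kb, records$strand)
}

#' Classify regions as genic or intergenic and assign strand relation
#'
#' A region is genic if it overlaps any gene by at least 1 bp. For genic
#' regions the gene with the largest overlap (ties broken by leftmost gene
#' start) determines the strand relation: when the region's (TG-rich) strand
#' differs from the gene strand, the TG-rich strand is the transcription
#' template (`"template"`); when they agree it is the coding strand
#' (`"coding"`). Intergenic regions are `"not_applicable"`.
#'
#' @param records data.frame of regions (`chrom`, `start`, `end`, `strand`,
#'   0-based half-open).
#' @param genes data.frame of stranded gene intervals (`chrom`, `start`,
#'   `end`, `strand`, 0-based half-open; start codon to stop codon), e.g.
#'   from [read_gene_annotations()]. Malformed rows (missing coordinates or
#'   empty ranges) are skipped with a warning.
#' @return `records` with columns `genic_status` and `gene_strand_relation`
#'   added.
#' @export
classify_genic <- function(records, genes) {
  genes <- as.data.frame(genes)
  req <- c("chrom", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop_validation("genes missing column(s): ", paste(miss, collapse = ", "))
  bad <- is.na(genes$start) | is.na(genes$end) | genes$end <= genes$start |
    !(genes$strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " malformed gene annotation row(s) skipped")
    genes <- genes[!bad, , drop = FALSE]
  }
  records$genic_status <- rep("intergenic", nrow(records))
  records$gene_strand_relation <- rep("not_applicable", nrow(records))
  if (!nrow(records) || !nrow(genes)) return(records)
  qgr <- df_to_gr(records, ignore_strand = TRUE)
  sgr <- df_to_gr(genes, ignore_strand = TRUE)
  hits <- GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = TRUE)
  if (!length(hits)) return(records)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ow <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(qgr)[qh], IRanges::ranges(sgr)[sh]))
  ## largest overlap wins; ties broken by leftmost gene start
  ord <- order(qh, -ow, genes$start[sh])
  best <- !duplicated(qh[ord])
  qi <- qh[ord][best]
  gi <- sh[ord][best]
  records$genic_status[qi] <- "genic"
  records$gene_strand_relation[qi] <-
    ifelse(records$strand[qi] != genes$strand[gi], "template", "coding")
  records
}
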