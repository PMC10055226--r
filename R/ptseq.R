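#' Telomere seed motifs for detecting telomere-addition reads
#'
#' The 8-mer seeds used to recognise newly synthesised yeast telomeric
#' repeats in sequencing reads: `GGGTGTGG` on the TG-rich strand and its
#' reverse complement `CCACACCC` on the CA-rich strand.
#'
#' @return List with elements `plus_seed` and `minus_seed`.
#' @export
telomere_motifs <- function() {
  list(plus_seed = "GGGTGTGG", minus_seed = "CCACACCC")
}

## Longest exact common substring between two sequences, via an exact-match
## local alignment (mismatches and gaps effectively forbidden).
lcs_length <- function(patterns, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1e6,
                                                  baseOnly = FALSE)
  as.numeric(Biostrings::pairwiseAlignment(
    patterns, subject, type = "local", substitutionMatrix = mat,
    gapOpening = 1e6, gapExtension = 1e6, scoreOnly = TRUE))
}

lcs_align <- function(pattern, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1e6,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(pattern, subject, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 1e6, gapExtension = 1e6)
}

as_read_set <- function(reads) {
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is(reads, "QualityScaledDNAStringSet")) reads <- as.character(reads)
  if (!is.character(reads))
    stop_validation("reads must be a character vector or DNAStringSet")
  if (!length(reads)) return(setNames(character(0), character(0)))
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- paste0("read_", seq_along(reads))
  toupper(reads)
}

#' Assign reads to the target or control locus
#'
#' A read is assigned to a locus when it shares a contiguous exact match of
#' at least `min_match` nucleotides with either strand of that locus; a read
#' qualifying for both loci is assigned to the one with the longer match
#' (ties go to the target). Reads matching neither locus are unassigned.
#' This built-in exact-seed assigner serves fixtures and small runs; read
#' sets extracted from an external aligner's SAM/BAM output (see
#' [ptseq_reads_from_bam()]) can be fed to the same downstream logic.
#'
#' @param reads Named character vector or `DNAStringSet` of read sequences.
#' @param target_seq Target locus sequence (the putative hotspot insert,
#'   typically 300 nt, given on its TG-rich strand).
#' @param control_seq Control locus sequence (typically 300 nt within an
#'   essential gene) used for depth normalization.
#' @param min_match Minimum exact contiguous match in nt (default 30).
#' @return List with character-vector elements `target`, `control`,
#'   `unassigned` holding read names, plus `reads` (the normalized read set).
#' @export
assign_reads <- function(reads, target_seq, control_seq, min_match = 30L) {
  reads <- as_read_set(reads)
  target_seq <- as_seq_string(target_seq, "target_seq")
  control_seq <- as_seq_string(control_seq, "control_seq")
  if (!length(reads))
    return(list(target = character(0), control = character(0),
                unassigned = character(0), reads = reads))
  rs <- Biostrings::DNAStringSet(reads)
  lt <- pmax(lcs_length(rs, target_seq),
             lcs_length(rs, revcomp(target_seq)))
  lc <- pmax(lcs_length(rs, control_seq),
             lcs_length(rs, revcomp(control_seq)))
  locus <- ifelse(lt >= min_match & lt >= lc, "target",
                  ifelse(lc >= min_match, "control", "unassigned"))
  list(target = names(reads)[locus == "target"],
       control = names(reads)[locus == "control"],
       unassigned = names(reads)[locus == "unassigned"],
       reads = reads)
}

#' Detect a de novo telomere-addition event in one read
#'
#' Orients the read to the target's TG-rich strand (reverse-complementing it
#' when it matches the CA-rich strand better), locates the longest exact
#' match between read and target, and calls a telomere-addition event when a
#' telomere seed motif occurs in the read beyond the target-matching
#' segment. The junction is the 0-based target coordinate of the last
#' target-matching base (the 3'-most aligned nucleotide on the TG-rich
#' strand, i.e. the latest position at which telomerase may have initiated
#' synthesis); the tail length is the number of read bases past the
#' junction.
#'
#' By default the seed must fall outside the target-matching segment
#' (`require_tail_outside = TRUE`), which avoids counting the hotspot's own
#' TG-rich tract as evidence of telomere addition; setting it `FALSE`
#' reverts to the simpler "read contains the motif anywhere" rule.
#'
#' @param read A single read sequence.
#' @param target_seq Target locus sequence on the TG-rich strand.
#' @param motifs Seed motifs, see [telomere_motifs()].
#' @param require_tail_outside Require the seed outside the target-matching
#'   segment (default `TRUE`).
#' @return `NULL` when no event is detected, otherwise a one-row data.frame
#'   with columns `junction` (0-based), `tail_length`, `orientation`
#'   (`"plus"` or `"minus"`).
#' @export
detect_telomere_addition <- function(read, target_seq,
                                     motifs = telomere_motifs(),
                                     require_tail_outside = TRUE) {
  read <- as_seq_string(read, "read")
  target_seq <- as_seq_string(target_seq, "target_seq")
  if (nchar(read) == 0L) return(NULL)
  lf <- lcs_length(Biostrings::DNAStringSet(read), target_seq)
  rc <- revcomp(read)
  lr <- lcs_length(Biostrings::DNAStringSet(rc), target_seq)
  orientation <- if (lr > lf) "minus" else "plus"
  nr <- if (orientation == "minus") rc else read
  best <- max(lf, lr)
  if (best <= 0) return(NULL)
  aln <- lcs_align(nr, target_seq)
  r2 <- Biostrings::end(Biostrings::pattern(aln))    # 1-based read end
  t2 <- Biostrings::end(Biostrings::subject(aln))    # 1-based target end
  hits <- gregexpr(motifs$plus_seed, nr, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  if (require_tail_outside && !any(hits > r2)) return(NULL)
  tail_length <- nchar(nr) - r2
  if (tail_length < nchar(motifs$plus_seed)) return(NULL)
  data.frame(junction = t2 - 1L, tail_length = tail_length,
             orientation = orientation, stringsAsFactors = FALSE)
}

#' Summarize telomere-addition events against control read depth
#'
#' Normalizes the telomere-read count to the control locus by expressing it
#' as a percentage of control reads, and aggregates events into a junction
#' profile (fraction of telomere reads mapping to each junction
#' coordinate).
#'
#' @param events data.frame of events (columns `junction`, `tail_length`,
#'   `orientation`), e.g. rows from [detect_telomere_addition()]; may have
#'   zero rows.
#' @param n_target_reads Number of reads assigned to the target locus.
#' @param n_control_reads Number of reads assigned to the control locus;
#'   must be positive (normalization is undefined otherwise).
#' @return An object of class `ptseq_summary`: `n_control_reads`,
#'   `n_target_reads`, `n_telomere_reads`, `normalized_pct`
#'   (`100 * telomere / control`) and `junction_profile` (data.frame
#'   `junction`, `n_reads`, `fraction`).
#' @export
summarize_ptseq <- function(events, n_target_reads, n_control_reads) {
  if (is.null(events) || !nrow(events))
    events <- data.frame(junction = integer(0), tail_length = integer(0),
                         orientation = character(0))
  n_control_reads <- as.integer(n_control_reads)
  n_target_reads <- as.integer(n_target_reads)
  if (is.na(n_control_reads) || n_control_reads <= 0L)
    stop_validation("normalization requires a positive control read count")
  n_tel <- nrow(events)
  if (n_tel > n_target_reads)
    stop_validation("more telomere reads than target reads")
  prof <- if (n_tel) {
    tab <- table(events$junction)
    data.frame(junction = as.integer(names(tab)),
               n_reads = as.integer(tab),
               fraction = as.integer(tab) / n_tel)
  } else {
    data.frame(junction = integer(0), n_reads = integer(0),
               fraction = numeric(0))
  }
  structure(list(n_control_reads = n_control_reads,
                 n_target_reads = n_target_reads,
                 n_telomere_reads = n_tel,
                 normalized_pct = 100 * n_tel / n_control_reads,
                 junction_profile = prof),
            class = "ptseq_summary")
}

#' @export
print.ptseq_summary <- function(x, ...) {
  cat("Pooled telomere-addition sequencing summary\n")
  cat(sprintf("  reads: %d control, %d target, %d with telomere addition\n",
              x$n_control_reads, x$n_target_reads, x$n_telomere_reads))
  cat(sprintf("  telomere reads = %.3g%% of control reads\n",
              x$normalized_pct))
  if (!is.null(x$efficiency_pct))
    cat(sprintf("  estimated per-clone efficiency %.1f%% -> %s\n",
                x$efficiency_pct,
                if (isTRUE(x$active)) "active hotspot" else "inactive"))
  if (nrow(x$junction_profile)) {
    cat("  top junctions:\n")
    top <- x$junction_profile[order(-x$junction_profile$fraction), ]
    print(head(top, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Standard curve relating normalized read percentage to clone efficiency
#'
#' Linear calibration `efficiency = slope * normalized_pct + intercept`
#' between the sequencing readout (telomere reads as a percent of control
#' reads) and the percentage of clones that underwent telomere addition.
#' Two published calibrations are available as presets: `"chrVII"`
#' (slope 3.961, intercept -2.039) and `"chrIX"` (slope 3.8022,
#' intercept -0.5505).
#'
#' @param slope Curve slope, or the preset name `"chrVII"` / `"chrIX"`.
#' @param intercept Curve intercept (ignored for presets).
#' @return An object of class `standard_curve`.
#' @examples
#' standard_curve("chrVII")
#' standard_curve(4.0, -1.0)
#' @export
standard_curve <- function(slope = "chrVII", intercept = NULL) {
  if (is.character(slope)) {
    preset <- match.arg(tolower(slope), c("chrvii", "chrix", "vii", "ix"))
    if (preset %in% c("chrvii", "vii")) {
      slope <- 3.961; intercept <- -2.039; name <- "chrVII"
    } else {
      slope <- 3.8022; intercept <- -0.5505; name <- "chrIX"
    }
  } else {
    name <- "custom"
    if (is.null(intercept))
      stop_validation("intercept required for a custom standard curve")
  }
  if (!is.numeric(slope) || slope <= 0)
    stop_validation("standard curve slope must be > 0")
  structure(list(slope = slope, intercept = as.numeric(intercept),
                 name = name), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve (%s): efficiency = %.4g * pct %+.4g\n",
              x$name, x$slope, x$intercept))
  invisible(x)
}

#' Convert a normalized read percentage to estimated clone efficiency
#'
#' Applies the standard curve and clamps the result to `[0, 100]` percent.
#'
#' @param normalized_pct Telomere reads as a percentage of control reads
#'   (must be >= 0).
#' @param curve A [standard_curve()].
#' @return Estimated percentage of clones with de novo telomere addition.
#' @examples
#' apply_standard_curve(10, standard_curve("chrVII"))  # 37.571
#' apply_standard_curve(0, standard_curve("chrVII"))   # clamped to 0
#' @export
apply_standard_curve <- function(normalized_pct, curve = standard_curve()) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(normalized_pct < 0))
    stop_validation("normalized_pct must be >= 0")
  pmin(100, pmax(0, curve$slope * normalized_pct + curve$intercept))
}

#' Classify a sequence as an active telomere-addition hotspot
#'
#' Active means the average efficiency of de novo telomere addition is
#' strictly greater than the threshold (default 6.6%, i.e. more than 2 of 30
#' clones — the level exceeded by chance in only ~6% of random-repair
#' trials).
#'
#' @param efficiency_pct Estimated efficiency in percent (0-100).
#' @param threshold Activity cutoff in percent (default 6.6).
#' @return Logical vector.
#' @examples
#' classify_active(c(80.5, 2.3, 6.6))  # TRUE FALSE FALSE
#' @export
classify_active <- function(efficiency_pct, threshold = 6.6) {
  if (any(efficiency_pct < 0 | efficiency_pct > 100))
    stop_validation("efficiency_pct must be within [0, 100]")
  efficiency_pct > threshold
}

#' Quantify de novo telomere addition from a pooled read set
#'
#' End-to-end PT-seq quantification: assigns reads to the target and control
#' loci ([assign_reads()]), detects telomere-addition events among target
#' reads ([detect_telomere_addition()]), summarizes and normalizes
#' ([summarize_ptseq()]), and — when a standard curve is supplied —
#' calibrates the normalized percentage to per-clone efficiency and
#' classifies activity.
#'
#' @inheritParams assign_reads
#' @inheritParams detect_telomere_addition
#' @param curve Optional [standard_curve()] for efficiency calibration.
#' @param activity_threshold Activity cutoff in percent (default 6.6).
#' @return A `ptseq_summary` (see [summarize_ptseq()]) with additional
#'   elements `events` (per-read event table), and, when a curve is given,
#'   `efficiency_pct` and `active`.
#' @export
ptseq_quantify <- function(reads, target_seq, control_seq, min_match = 30L,
                           motifs = telomere_motifs(),
                           require_tail_outside = TRUE, curve = NULL,
                           activity_threshold = 6.6) {
  asn <- assign_reads(reads, target_seq, control_seq, min_match)
  target_seq <- as_seq_string(target_seq, "target_seq")
  ev <- lapply(asn$target, function(id) {
    e <- detect_telomere_addition(asn$reads[[id]], target_seq, motifs,
                                  require_tail_outside)
    if (!is.null(e)) cbind(read_id = id, e)
  })
  events <- do.call(rbind, ev)
  if (is.null(events))
    events <- data.frame(read_id = character(0), junction = integer(0),
                         tail_length = integer(0), orientation = character(0))
  s <- summarize_ptseq(events, n_target_reads = length(asn$target),
                       n_control_reads = length(asn$control))
  s$events <- events
  if (!is.null(curve)) {
    s$efficiency_pct <- apply_standard_curve(s$normalized_pct, curve)
    s$active <- classify_active(s$efficiency_pct, activity_threshold)
  }
  s
}

#' Extract per-locus read sets from a SAM/BAM alignment
#'
#' For pipelines that align reads with an external local aligner against
#' two 300-bp references (target and control), this reads the alignment
#' file and returns the read sequences whose alignment covers at least
#' `min_match` reference bases of each locus, ready for
#' [detect_telomere_addition()] / [summarize_ptseq()]. SAM input is
#' converted on the fly.
#'
#' @param path Path to a SAM or BAM file whose references are the two loci.
#' @param target_name,control_name Reference names of the two loci.
#' @param min_match Minimum aligned reference width in nt (default 30).
#' @return List with `DNAStringSet` elements `target` and `control`.
#' @export
ptseq_reads_from_bam <- function(path, target_name, control_name,
                                 min_match = 30L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop_validation("Rsamtools and GenomicAlignments are required for ",
                    "SAM/BAM input")
  if (!file.exists(path)) stop_validation("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "cigar", "seq")))[[1]]
  mapped <- !is.na(b$rname) & !is.na(b$cigar)
  refw <- rep(0L, length(b$qname))
  refw[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    b$cigar[mapped])
  pick <- function(ref) {
    sel <- mapped & as.character(b$rname) == ref & refw >= min_match
    out <- b$seq[sel]
    names(out) <- b$qname[sel]
    out
  }
  list(target = pick(target_name), control = pick(control_name))
}
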