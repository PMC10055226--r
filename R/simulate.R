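## Expand a plant pattern like "(TG)15" into an explicit sequence.
expand_pattern <- function(pattern) {
  m <- regmatches(pattern, regexec("^\\(([ACGT]+)\\)([0-9]+)$",
                                   toupper(pattern)))[[1]]
  if (length(m) == 3L) return(strrep(m[2], as.integer(m[3])))
  s <- toupper(pattern)
  if (!grepl("^[ACGT]+$", s))
    stop_validation("plant pattern must be '(UNIT)n' or an explicit ",
                    "A/C/G/T string: ", pattern)
  s
}

#' Simulate a genome with planted telomere-like tracts and known truth
#'
#' Builds a synthetic multi-chromosome genome with tracts of known score
#' planted at known positions, for validating the scanner end to end. Two
#' background modes are available: `"gfree"` draws only A/T — neither strand
#' of such a background contains a G (a plus-strand C would be a minus-strand
#' G), so no tract can open outside a plant and every scan hit must be a
#' plant (zero false positives by construction); `"matched"` draws i.i.d.
#' nucleotides from
#' supplied base frequencies, emulating composition-matched background that
#' can produce chance tracts. Plants are inserted verbatim on the plus
#' strand or reverse-complemented for minus-strand plants.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in nt (recycled across chromosomes).
#' @param plants data.frame with columns `pattern` (e.g. `"(TG)10"` or an
#'   explicit tract string, written as its TG-rich strand), `chrom`
#'   (chromosome index or name), `position` (0-based insertion offset) and
#'   `strand` (`"+"`/`"-"`). Plants must not overlap.
#' @param background `"gfree"` (default) or `"matched"`.
#' @param base_freqs Named vector of A/C/G/T frequencies for `"matched"`
#'   background (default uniform).
#' @param params [scoring_params()] used to compute each plant's expected
#'   score for the truth table.
#' @param seed Integer seed.
#' @return List with elements `genome` (`DNAStringSet`), `truth` (data.frame
#'   `chrom`, `start`, `end`, `strand`, `score` — the planted tract
#'   coordinates and their window scores) and `layout` (a permissive
#'   [genome_layout()] covering the whole of each chromosome).
#' @examples
#' sim <- simulate_planted_genome(1, 5000,
#'   plants = data.frame(pattern = "(TG)10", chrom = 1, position = 1000,
#'                       strand = "+"), seed = 1)
#' @export
simulate_planted_genome <- function(n_chrom = 1L, chrom_len = 100000L,
                                    plants = NULL,
                                    background = c("gfree", "matched"),
                                    base_freqs = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                                    params = scoring_params(),
                                    seed = NULL) {
  background <- match.arg(background)
  n_chrom <- as.integer(n_chrom)
  chrom_len <- rep_len(as.integer(chrom_len), n_chrom)
  set_seed_if(seed)
  chroms <- paste0("chr", as.roman(seq_len(n_chrom)))
  ## Both strands must be G-free for the zero-false-positive guarantee:
  ## a C on the plus strand is a G on the minus strand, so the background
  ## alphabet is A/T only.
  alphabet <- if (background == "gfree") c("A", "T") else names(base_freqs)
  prob <- if (background == "gfree") NULL else base_freqs
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(alphabet, chrom_len[i], replace = TRUE, prob = prob),
          collapse = ""), character(1))
  names(seqs) <- chroms
  truth <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0))
  if (!is.null(plants) && nrow(plants)) {
    plants <- as.data.frame(plants)
    chrom_of <- function(x) if (is.numeric(x)) chroms[x] else as.character(x)
    for (i in seq_len(nrow(plants))) {
      tract <- expand_pattern(plants$pattern[i])
      sc <- score_window(tract, params)
      if (sc <= 0)
        stop_validation("plant ", i, " ('", plants$pattern[i],
                        "') is not a scoreable telomere-like tract")
      chrom <- chrom_of(plants$chrom[i])
      pos <- as.integer(plants$position[i])
      len <- nchar(tract)
      if (is.na(match(chrom, chroms)) || pos < 0 ||
          pos + len > chrom_len[match(chrom, chroms)])
        stop_validation("plant ", i, " does not fit within ", chrom)
      ## the 1 nt insulation flanks (below) must not touch another plant
      clash <- truth$chrom == chrom & pos - 1L < truth$end &
        pos + len + 1L > truth$start
      if (any(clash))
        stop_validation("plants overlap on ", chrom, " at position ", pos)
      strand <- as.character(plants$strand[i] %||% "+")
      ins <- if (strand == "-") revcomp(tract) else tract
      substr(seqs[[chrom]], pos + 1L, pos + len) <- ins
      ## Insulate the tract so a background T (plus plants) or A (minus
      ## plants, i.e. a minus-strand T) cannot extend the planted G/T run
      ## and inflate its score past the truth value.
      buf <- if (strand == "-") "T" else "A"
      cl <- chrom_len[match(chrom, chroms)]
      if (pos > 0L) substr(seqs[[chrom]], pos, pos) <- buf
      if (pos + len < cl)
        substr(seqs[[chrom]], pos + len + 1L, pos + len + 1L) <- buf
      truth <- rbind(truth, data.frame(chrom = chrom, start = pos,
                                       end = pos + len, strand = strand,
                                       score = sc))
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  list(genome = genome, truth = truth, layout = default_layout(genome))
}

## One simulated telomeric tail: a canonical 12-mer head guaranteeing a
## detectable seed, extended with irregular repeats of a single T followed
## by one to three Gs. Degenerate mode draws a G-free tail instead, so no
## seed can occur (a guaranteed-miss control for the detector).
simulate_tail <- function(tail_length, head = "GTGTGGGTGTGG",
                          degenerate = FALSE) {
  if (degenerate) {
    return(paste(sample(c("A", "C", "T"), tail_length, replace = TRUE),
                 collapse = ""))
  }
  if (tail_length < nchar(head))
    stop_validation("tail_length must be >= ", nchar(head),
                    " (the canonical head)")
  tail <- head
  while (nchar(tail) < tail_length)
    tail <- paste0(tail, "T", strrep("G", sample.int(3L, 1L)))
  substr(tail, 1L, tail_length)
}

#' Simulate a pooled telomere-addition read set with known truth
#'
#' Generates event reads — a target prefix ending at a specified junction
#' followed by a simulated telomeric tail — plus control reads drawn as
#' exact substrings of the control locus. The truth table maps every event
#' read to its junction, so precision and recall of the junction caller can
#' be computed without re-deriving anything.
#'
#' Each junction must be exactly recoverable: the generator requires the
#' target base immediately after the junction to differ from the first tail
#' base (G), otherwise the read's match to the target would extend past the
#' intended junction.
#'
#' @param target_seq Target locus sequence (TG-rich strand).
#' @param control_seq Control locus sequence.
#' @param junctions Integer vector of 0-based junction coordinates.
#' @param counts Reads per junction (recycled).
#' @param orientations `"plus"`/`"minus"` per junction (recycled; minus
#'   reads are reverse-complemented whole).
#' @param read_length Read length in nt (default 100).
#' @param tail_length Simulated tail length in nt (default 30).
#' @param n_control Number of control reads (default 1000).
#' @param degenerate_tail Use a G-free (seedless) tail: events become
#'   undetectable, for testing the detector's miss behaviour.
#' @param seed Integer seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `junction`, `orientation`; control reads have
#'   `NA` junction).
#' @export
simulate_ptseq_reads <- function(target_seq, control_seq, junctions,
                                 counts = 1L,
                                 orientations = "plus",
                                 read_length = 100L, tail_length = 30L,
                                 n_control = 1000L,
                                 degenerate_tail = FALSE, seed = NULL) {
  target_seq <- as_seq_string(target_seq, "target_seq")
  control_seq <- as_seq_string(control_seq, "control_seq")
  junctions <- as.integer(junctions)
  counts <- rep_len(as.integer(counts), length(junctions))
  orientations <- rep_len(orientations, length(junctions))
  read_length <- as.integer(read_length)
  prefix_len <- read_length - as.integer(tail_length)
  if (prefix_len < 1L)
    stop_validation("read_length must exceed tail_length")
  tl <- nchar(target_seq)
  if (any(junctions < 0L | junctions >= tl))
    stop_validation("junction out of target bounds [0, ", tl, ")")
  if (any(junctions - prefix_len + 1L < 0L))
    stop_validation("junction too close to the target 5' end for a ",
                    prefix_len, " nt prefix")
  after <- substring(target_seq, junctions + 2L, junctions + 2L)
  if (!degenerate_tail && any(after == "G"))
    stop_validation("junction(s) ",
                    paste(junctions[after == "G"], collapse = ", "),
                    " not exactly recoverable: the target base after the ",
                    "junction is G, matching the tail start")
  set_seed_if(seed)
  reads <- character(0)
  truth <- data.frame(read_id = character(0), junction = integer(0),
                      orientation = character(0))
  for (i in seq_along(junctions)) {
    j <- junctions[i]
    prefix <- substring(target_seq, j - prefix_len + 2L, j + 1L)
    for (k in seq_len(counts[i])) {
      tail <- simulate_tail(tail_length, degenerate = degenerate_tail)
      read <- paste0(prefix, tail)
      if (orientations[i] == "minus") read <- revcomp(read)
      id <- sprintf("event_j%d_%d", j, k)
      reads[[id]] <- read
      truth <- rbind(truth, data.frame(read_id = id, junction = j,
                                       orientation = orientations[i]))
    }
  }
  cl <- nchar(control_seq)
  ctrl_len <- min(read_length, cl)
  if (n_control > 0L) {
    starts <- sample.int(cl - ctrl_len + 1L, n_control, replace = TRUE)
    ctrl <- substring(control_seq, starts, starts + ctrl_len - 1L)
    ids <- sprintf("control_%d", seq_len(n_control))
    reads[ids] <- ctrl
    truth <- rbind(truth, data.frame(read_id = ids, junction = NA_integer_,
                                     orientation = NA_character_))
  }
  list(reads = reads, truth = truth)
}

## Random A/C/G/T sequence helper used by fixtures and the CLI simulator.
random_dna <- function(n, exclude = NULL,
                       alphabet = c("A", "C", "G", "T")) {
  alphabet <- setdiff(alphabet, exclude)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
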