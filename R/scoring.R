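#' Scoring parameters for the telomere-likeness (CATHI) scanner
#'
#' Bundles the tunable parameters of the sliding-window tract scorer. The
#' score of a window is the summed length of its telomere-like G/T tracts
#' minus optional penalties. Defaults follow the published scanner: windows
#' of 75 nt advanced 1 nt at a time, no penalties unless requested, and a
#' clustering threshold of 20 points. The genome-wide analyses in the source
#' study used `ggtgg_penalty = 1.5`.
#'
#' @param window_size Window width in nucleotides (default 75).
#' @param step Window stride in nucleotides (default 1).
#' @param ggtgg_penalty Points deducted per occurrence of the pentanucleotide
#'   `GGTGG` in the window (occurrences may overlap). `GGTGG` never occurs in
#'   yeast telomeric repeats, so it marks divergence from the telomeric
#'   pattern. Default 0 (no penalty); the published genome analysis used 1.5.
#' @param tt_penalty Points deducted per thymine immediately flanking a
#'   candidate tract (either side). Default 0.
#' @param cluster_threshold Minimum window score (points) for a window to
#'   enter region clustering (default 20).
#'
#' @return An object of class `scoring_params`.
#' @examples
#' scoring_params(ggtgg_penalty = 1.5)
#' @export
scoring_params <- function(window_size = 75L, step = 1L,
                           ggtgg_penalty = 0, tt_penalty = 0,
                           cluster_threshold = 20) {
  min_tract_len <- 4L  # fixed by the tract definition
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (is.na(window_size) || window_size < min_tract_len)
    stop_validation("window_size must be >= ", min_tract_len)
  if (is.na(step) || step < 1L)
    stop_validation("step must be >= 1")
  if (!is.numeric(ggtgg_penalty) || ggtgg_penalty < 0)
    stop_validation("ggtgg_penalty must be >= 0")
  if (!is.numeric(tt_penalty) || tt_penalty < 0)
    stop_validation("tt_penalty must be >= 0")
  if (!is.numeric(cluster_threshold) || cluster_threshold < 0)
    stop_validation("cluster_threshold must be >= 0")
  structure(list(window_size = window_size, step = step,
                 min_tract_len = min_tract_len,
                 ggtgg_penalty = as.numeric(ggtgg_penalty),
                 tt_penalty = as.numeric(tt_penalty),
                 cluster_threshold = as.numeric(cluster_threshold)),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("Telomere-likeness scoring parameters\n")
  cat(sprintf("  window %d nt, step %d nt\n", x$window_size, x$step))
  cat(sprintf("  GGTGG penalty %.3g, flanking-T penalty %.3g\n",
              x$ggtgg_penalty, x$tt_penalty))
  cat(sprintf("  cluster threshold %.3g points\n", x$cluster_threshold))
  invisible(x)
}

#' Tokenize a sequence into telomere-like G/T tracts
#'
#' Performs the greedy left-to-right scan that defines candidate telomere-like
#' tracts: a tract opens at each G beginning a run of at least 4 consecutive
#' G/T characters and is truncated (inclusively) at the first T of a TT pair
#' or at the third G of a run of four or more Gs; scanning resumes immediately
#' after the truncation point, so a single G/T run can yield several tracts.
#' Tracts shorter than 4 nt after truncation, or consisting only of Gs, are
#' discarded. Characters other than A/C/G/T (ambiguity codes such as N) break
#' runs; lowercase input is uppercased.
#'
#' @param seq A single nucleotide string (or `DNAString`).
#' @return A data.frame with columns `start`, `end` (0-based half-open
#'   offsets within `seq`) and `length`; zero rows if no tract is found.
#' @examples
#' tokenize_tracts("AAGTGTTGTGGAA")  # two tracts: GTGT and GTGG
#' tokenize_tracts("GGGGG")          # all-G regions are removed
#' @export
tokenize_tracts <- function(seq) {
  s <- as_seq_string(seq)
  if (nchar(s) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  tr <- cpp_tokenize(s)
  data.frame(start = tr$start, end = tr$end, length = tr$end - tr$start)
}

#' Score one window of sequence
#'
#' The window score is the summed length of all candidate tracts (see
#' [tokenize_tracts()]) minus `ggtgg_penalty` times the number of (possibly
#' overlapping) literal `GGTGG` occurrences anywhere in the window, minus
#' `tt_penalty` times the number of Ts immediately flanking candidate tracts.
#' Scores are not floored at zero and may be fractional or negative when
#' penalties apply.
#'
#' @param seq A single nucleotide string of any length (intended use is one
#'   window of `params$window_size` nt).
#' @param params A [scoring_params()] object.
#' @return A single numeric score in points.
#' @examples
#' score_window(strrep("TG", 31), scoring_params(ggtgg_penalty = 1.5))  # 61
#' score_window("AAAGGTGGAAA", scoring_params(ggtgg_penalty = 1.5))    # 3.5
#' @export
score_window <- function(seq, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"))
  s <- as_seq_string(seq)
  cpp_score_window(s, params$ggtgg_penalty, params$tt_penalty)
}

#' Scan a sequence with sliding windows
#'
#' Slides a window of `params$window_size` nt along `seq` with stride
#' `params$step`, scoring each full window (start positions
#' `0, step, ..., len - window_size`). A sequence shorter than the window is
#' scored whole as a single window. In `"score"` mode only the maximum window
#' score is returned (one number per sequence); in `"signal"` mode every
#' window is returned with its start coordinate.
#'
#' @param seq A single nucleotide string (or `DNAString`); must be non-empty.
#' @param params A [scoring_params()] object.
#' @param mode `"score"` (maximum score) or `"signal"` (per-window scores).
#' @return `"score"` mode: a single numeric. `"signal"` mode: a data.frame
#'   with columns `start`, `end` (0-based half-open) and `score`.
#' @examples
#' x <- paste0(strrep("A", 50), strrep("TG", 10), strrep("A", 130))
#' scan_sequence(x, mode = "score")  # 19
#' @export
scan_sequence <- function(seq, params = scoring_params(),
                          mode = c("score", "signal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "scoring_params"))
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (n == 0L) stop_validation("cannot scan an empty sequence")
  scores <- cpp_scan(s, params$window_size, params$step,
                     params$ggtgg_penalty, params$tt_penalty)
  if (mode == "score") return(max(scores))
  if (n < params$window_size) {
    starts <- 0L
    ends <- n
  } else {
    starts <- seq.int(0L, n - params$window_size, by = params$step)
    ends <- starts + params$window_size
  }
  data.frame(start = starts, end = ends, score = scores)
}

#' Merge above-threshold windows into scored regions
#'
#' Windows meeting or exceeding `threshold` whose spans overlap or abut
#' (`end == next start`) are merged into maximal regions. A region starts at
#' the start of its most upstream window and ends at the end of its most
#' downstream window; its score is the maximum score among merged windows.
#' Windows below threshold never appear in the output. Unsorted input is
#' sorted internally.
#'
#' @param windows A data.frame with columns `start`, `end`, `score`
#'   (0-based half-open window spans), from a single chromosome and strand.
#' @param threshold Minimum window score (points); comparison is `>=`.
#' @return A data.frame with columns `start`, `end`, `score` (maximum over
#'   merged windows) and `n_windows`.
#' @examples
#' w <- data.frame(start = c(10, 11, 300), end = c(85, 86, 375),
#'                 score = c(25, 22, 21))
#' cluster_windows(w, threshold = 20)
#' @export
cluster_windows <- function(windows, threshold) {
  stopifnot(is.data.frame(windows),
            all(c("start", "end", "score") %in% names(windows)))
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), n_windows = integer(0))
  if (!nrow(windows)) return(empty)
  keep <- windows[windows$score >= threshold, , drop = FALSE]
  if (!nrow(keep)) return(empty)
  keep <- keep[order(keep$start, keep$end), , drop = FALSE]
  grp <- integer(nrow(keep))
  grp[1] <- 1L
  cur_end <- keep$end[1]
  g <- 1L
  for (i in seq_len(nrow(keep))[-1]) {
    if (keep$start[i] > cur_end) {  # strictly beyond: abutting merges
      g <- g + 1L
      cur_end <- keep$end[i]
    } else {
      cur_end <- max(cur_end, keep$end[i])
    }
    grp[i] <- g
  }
  out <- do.call(rbind, lapply(split(keep, grp), function(d) {
    data.frame(start = min(d$start), end = max(d$end),
               score = max(d$score), n_windows = nrow(d))
  }))
  rownames(out) <- NULL
  out
}
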