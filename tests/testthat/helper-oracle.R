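# Independent brute-force reference for the tract scorer, written as a
# regex/recursion over maximal G/T runs (structurally unlike the package's
# character state machine). Implements the published rules directly:
# tracts start at a G with >= 4 G/T characters remaining in the run, are
# truncated after the first T of a TT pair or after the third G of a >= 4-G
# run (whichever the left-to-right scan meets first), scanning resumes after
# the truncation point, and fragments < 4 nt or without any T are dropped.

oracle_segment <- function(run, off) {
  n_lead_t <- nchar(run) - nchar(sub("^T+", "", run))
  run <- substring(run, n_lead_t + 1L)
  off <- off + n_lead_t
  n <- nchar(run)
  if (n < 4L) return(NULL)
  p_tt <- regexpr("TT", run, fixed = TRUE)[1]
  p_g4 <- regexpr("GGGG", run, fixed = TRUE)[1]
  trig_tt <- if (p_tt > 0) p_tt else Inf        # scanner meets TT at its first T
  trig_g4 <- if (p_g4 > 0) p_g4 + 3 else Inf    # ... and GGGG at its fourth G
  stop_char <- if (is.infinite(trig_tt) && is.infinite(trig_g4)) n
               else if (trig_tt < trig_g4) p_tt else p_g4 + 2L
  tract <- substring(run, 1L, stop_char)
  keep <- nchar(tract) >= 4L && grepl("T", tract, fixed = TRUE)
  rbind(
    if (keep) data.frame(start = off, end = off + stop_char),
    oracle_segment(substring(run, stop_char + 1L), off + stop_char))
}

oracle_tracts <- function(seq) {
  seq <- toupper(seq)
  m <- gregexpr("[GT]+", seq)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0)))
  lens <- attr(m, "match.length")
  out <- do.call(rbind, lapply(seq_along(m), function(i)
    oracle_segment(substring(seq, m[i], m[i] + lens[i] - 1L), m[i] - 1L)))
  if (is.null(out)) data.frame(start = integer(0), end = integer(0)) else out
}

oracle_score <- function(seq, ggtgg_penalty = 0, tt_penalty = 0) {
  seq <- toupper(seq)
  tr <- oracle_tracts(seq)
  base <- sum(tr$end - tr$start)
  n_pent <- {
    g <- gregexpr("(?=GGTGG)", seq, perl = TRUE)[[1]]
    if (g[1] == -1L) 0L else length(g)
  }
  n_flank <- 0L
  if (nrow(tr)) {
    left <- tr$start > 0 & substring(seq, tr$start, tr$start) == "T"
    right <- tr$end < nchar(seq) &
      substring(seq, tr$end + 1L, tr$end + 1L) == "T"
    n_flank <- sum(left) + sum(right)
  }
  base - ggtgg_penalty * n_pent - tt_penalty * n_flank
}

# Random sequence helpers for property tests.
random_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

gt_enriched_seq <- function(n) {
  random_seq(n, prob = c(A = 0.1, C = 0.1, G = 0.4, T = 0.4))
}
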