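#' Shuffle a genome while preserving per-chromosome nucleotide composition
#'
#' Randomly permutes the nucleotides within each chromosome, producing a
#' sequence with identical length and mononucleotide composition but
#' randomized order — the null model for asking how many telomere-like
#' regions a genome of this composition is expected to contain. When a
#' layout is supplied, each chromosome is first restricted to its analysis
#' bounds with subtelomeric intervals excised (the adjusted chromosome), and
#' the shuffle permutes that adjusted sequence.
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @param layout Optional [genome_layout()]; when supplied, shuffling is
#'   applied to the subtelomere-excluded analysis segments of each
#'   chromosome and the returned sequences are those adjusted chromosomes.
#' @param seed Integer seed for reproducibility.
#' @return A `DNAStringSet` of shuffled chromosomes (adjusted ones when a
#'   layout was given), same names as the input.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrI = "ACGTACGTAA"))
#' shuffle_genome(g, seed = 1)
#' @export
shuffle_genome <- function(genome, layout = NULL, seed = NULL) {
  genome <- as_genome(genome)
  set_seed_if(seed)
  out <- vapply(names(genome), function(chrom) {
    s <- as.character(genome[[chrom]])
    if (!is.null(layout)) {
      segs <- chrom_segments(layout, chrom, exclude_subtelomeres = TRUE)
      s <- paste(substring(s, segs$start + 1L, segs$end), collapse = "")
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(ch[sample.int(length(ch))], collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(out)
}

#' Tabulate region scores rounded down to the nearest integer
#'
#' Bins merged-region scores by `floor(score)` — the representation used to
#' compare the observed genome's score spectrum against shuffled genomes.
#'
#' @param x Numeric vector of region scores, or a data.frame with a `score`
#'   column (e.g. from [scan_genome()]).
#' @param min_score Optional lower bound; scores below it are dropped
#'   (the published comparison used 15).
#' @return data.frame with columns `score` (integer bin) and `count`.
#' @examples
#' score_spectrum(c(20.0, 20.5, 21.0))  # bins 20 (x2) and 21 (x1)
#' @export
score_spectrum <- function(x, min_score = NULL) {
  if (is.data.frame(x)) x <- x$score
  if (!is.numeric(x))
    stop_validation("score_spectrum() needs scores or a 'score' column")
  if (!is.null(min_score)) x <- x[x >= min_score]
  if (!length(x))
    return(data.frame(score = integer(0), count = integer(0)))
  tab <- table(floor(x))
  data.frame(score = as.integer(names(tab)), count = as.integer(tab))
}

#' Monte-Carlo model of random repair-event placement
#'
#' Models the null expectation for how many of `n_events` gross chromosomal
#' rearrangement (GCR) events would fall inside a fixed test window if
#' repair were distributed uniformly across the recoverable region. Each
#' trial drops `n_events` points independently and uniformly on
#' `[0, region_len)` and counts those landing inside `[0, target_len)`.
#' Defaults reproduce the assay geometry: 30 GCR events, a 300 bp test
#' insert, and the 21,922 bp interval between the break site and the first
#' essential gene. The exact binomial tail
#' (`1 - pbinom(k - 1, n_events, target_len / region_len)`) is reported
#' alongside as an analytic cross-check.
#'
#' @param n_events Number of events per trial (default 30).
#' @param target_len Test-window length in bp (default 300).
#' @param region_len Recoverable-region length in bp (default 21922).
#' @param iterations Number of Monte-Carlo trials (default 10000).
#' @param seed Integer seed.
#' @return An object of class `gcr_model` with element `tail`: a data.frame
#'   with columns `k`, `p_mc` (empirical P(X >= k)) and `p_binom` (exact
#'   binomial tail).
#' @examples
#' m <- gcr_event_model(iterations = 10000, seed = 1)
#' m$tail[m$tail$k %in% c(2, 3), ]  # ~6.3% and ~0.8%
#' @export
gcr_event_model <- function(n_events = 30L, target_len = 300,
                            region_len = 21922, iterations = 10000L,
                            seed = NULL) {
  n_events <- as.integer(n_events)
  iterations <- as.integer(iterations)
  if (is.na(n_events) || n_events < 0L)
    stop_validation("n_events must be >= 0")
  if (target_len <= 0 || region_len <= 0 || target_len > region_len)
    stop_validation("need 0 < target_len <= region_len")
  if (is.na(iterations) || iterations < 1L)
    stop_validation("iterations must be >= 1")
  set_seed_if(seed)
  counts <- integer(0)
  remaining <- iterations
  while (remaining > 0L) {
    b <- min(remaining, 100000L)
    if (n_events == 0L) {
      counts <- c(counts, integer(b))
    } else {
      inside <- matrix(runif(as.double(b) * n_events, 0, region_len) <
                         target_len, nrow = n_events)
      counts <- c(counts, colSums(inside))
    }
    remaining <- remaining - b
  }
  ks <- seq_len(max(n_events, 1L))
  p_mc <- vapply(ks, function(k) mean(counts >= k), numeric(1))
  p_binom <- 1 - pbinom(ks - 1, n_events, target_len / region_len)
  structure(list(n_events = n_events, target_len = target_len,
                 region_len = region_len, iterations = iterations,
                 seed = seed,
                 tail = data.frame(k = ks, p_mc = p_mc, p_binom = p_binom)),
            class = "gcr_model")
}

#' @export
print.gcr_model <- function(x, ...) {
  cat(sprintf(
    "Random-placement model: %d events, %g bp target in %g bp region, %d trials\n",
    x$n_events, x$target_len, x$region_len, x$iterations))
  show <- x$tail[x$tail$k <= 5, ]
  show$p_mc <- sprintf("%.4f", show$p_mc)
  show$p_binom <- sprintf("%.4f", show$p_binom)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Observed strand run statistics of hotspot regions
#'
#' Orders regions by start coordinate within each chromosome (both strands
#' interleaved) and tabulates the runs of consecutive regions on the same
#' strand: the total number of strand switches (neighbor pairs on opposite
#' strands, summed across chromosomes), the run-length histogram, and the
#' number of singlets (runs of length 1).
#'
#' @param records data.frame with columns `chrom`, `start`, `strand`.
#' @return An object of class `strand_run_stats`: list with `n_switches`,
#'   `run_length_histogram` (data.frame `length`, `count`), `n_singlets`,
#'   `n_records`.
#' @examples
#' r <- data.frame(chrom = "chrI", start = c(10, 20, 30, 40),
#'                 strand = c("+", "-", "+", "-"))
#' strand_switch_observed(r)  # 3 switches, 4 singlets
#' @export
strand_switch_observed <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "start", "strand") %in% names(records)))
  records <- records[order(records$chrom, records$start), , drop = FALSE]
  runs <- unlist(lapply(split(records$strand, records$chrom),
                        function(s) rle(as.character(s))$lengths),
                 use.names = FALSE)
  n_chrom <- length(unique(records$chrom[!is.na(records$chrom)]))
  tab <- if (length(runs)) table(runs) else table(integer(0))
  structure(list(
    n_switches = length(runs) - n_chrom,
    run_length_histogram = data.frame(length = as.integer(names(tab)),
                                      count = as.integer(tab)),
    n_singlets = sum(runs == 1L),
    n_records = nrow(records)),
    class = "strand_run_stats")
}

#' @export
print.strand_run_stats <- function(x, ...) {
  cat(sprintf("Strand runs over %d regions: %d switches, %d singlets\n",
              x$n_records, x$n_switches, x$n_singlets))
  invisible(x)
}

#' Permutation null for the strand distribution of hotspot regions
#'
#' Tests whether regions cluster on the same strand more (or less) than
#' expected by chance. Each iteration permutes the strand labels uniformly
#' within each chromosome — preserving the observed per-chromosome counts of
#' plus- and minus-strand regions — recomputes the statistic (strand
#' switches or singlet runs) per chromosome, and sums across chromosomes.
#' The observed value is compared with the resulting null distribution.
#'
#' @param records data.frame with columns `chrom`, `start`, `strand`.
#' @param iterations Number of permutations (default 10000; at least 100).
#' @param seed Integer seed.
#' @param statistic `"switches"` (strand switches) or `"singlets"` (runs of
#'   length 1).
#' @param alternative Direction of the one-sided empirical p-value:
#'   `"less"` (depletion: fraction of iterations with statistic <= observed),
#'   `"greater"` (excess), or `"auto"` (side of the null mean the observed
#'   value falls on).
#' @return An object of class `null_summary`: observed value, null `mean`
#'   and `sd`, raw empirical `p` (r/n), the `(r+1)/(n+1)` corrected
#'   `p_corrected`, `alternative`, `iterations`, `seed`.
#' @examples
#' r <- data.frame(chrom = "chrI", start = 1:4 * 10,
#'                 strand = c("+", "+", "-", "-"))
#' strand_switch_null(r, iterations = 1000, seed = 1)  # null mean 2.0
#' @export
strand_switch_null <- function(records, iterations = 10000L, seed = NULL,
                               statistic = c("switches", "singlets"),
                               alternative = c("auto", "less", "greater")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 100L)
    stop_validation("iterations must be >= 100")
  obs_stats <- strand_switch_observed(records)
  observed <- if (statistic == "switches") obs_stats$n_switches
              else obs_stats$n_singlets
  records <- records[order(records$chrom, records$start), , drop = FALSE]
  by_chrom <- split(as.character(records$strand), records$chrom)
  stat_fun <- if (statistic == "switches") {
    function(s) sum(s[-1L] != s[-length(s)])
  } else {
    function(s) sum(rle(s)$lengths == 1L)
  }
  set_seed_if(seed)
  null <- vapply(seq_len(iterations), function(i) {
    sum(vapply(by_chrom, function(s) {
      if (length(s) < 2L) return(stat_fun(s))  # 0 switches always
      stat_fun(s[sample.int(length(s))])
    }, numeric(1)))
  }, numeric(1))
  if (alternative == "auto")
    alternative <- if (observed <= mean(null)) "less" else "greater"
  r <- if (alternative == "less") sum(null <= observed)
       else sum(null >= observed)
  structure(list(statistic = statistic, observed = observed,
                 mean = mean(null), sd = sd(null),
                 p = r / iterations,
                 p_corrected = (r + 1) / (iterations + 1),
                 alternative = alternative,
                 iterations = iterations, seed = seed),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("Strand-distribution null (%s), %d iterations\n",
              x$statistic, x$iterations))
  cat(sprintf("  observed %g, expected %.1f +/- %.1f\n",
              x$observed, x$mean, x$sd))
  cat(sprintf("  one-sided empirical p (%s) = %.4g [(r+1)/(n+1) = %.4g]\n",
              x$alternative, x$p, x$p_corrected))
  invisible(x)
}
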