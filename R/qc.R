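#' Barcode sequence quality index
#'
#' Summarises per-base call reliability and read support into one number in
#' `[0, 1]`: the fraction of positions whose quality value reaches the
#' acceptable threshold `q`, weighted by coverage saturation
#' `min(coverage, x) / x` where `x` is the expected coverage,
#'
#' \deqn{B_q = \frac{1}{L} \sum_{i=1}^{L} 1[QV_i \ge q] \,
#'       \frac{\min(c_i, x)}{x}.}
#'
#' With the defaults (`q = 30`, one expected error per thousand bases, and
#' `x = 2`, both sequencing directions represented) a perfect bidirectional
#' high-quality sequence scores 1. The index is monotone non-decreasing in
#' every quality value and every coverage value.
#'
#' @param qualities integer vector of per-base Phred-scale quality values.
#' @param coverage integer vector of per-base read counts (contig size per
#'   position), same length as `qualities`.
#' @param q acceptable quality threshold.
#' @param x expected coverage.
#' @return `B_q` in `[0, 1]`.
#' @export
quality_index <- function(qualities, coverage, q = 30, x = 2) {
  if (length(qualities) == 0L) stop("empty quality vector")
  if (length(coverage) != length(qualities)) {
    stop("qualities and coverage must have the same length")
  }
  if (any(qualities < 0)) stop("negative quality values")
  if (any(coverage < 1)) stop("coverage values must be >= 1")
  mean((qualities >= q) * pmin(coverage, x) / x)
}

#' Linguistic complexity of a sequence
#'
#' Vocabulary-richness measure of sequence repetitiveness. For each sliding
#' window `w` the complexity is the product over pattern sizes `k` of the
#' number of distinct k-mers observed divided by the maximum possible,
#' `min(4^k, |w| - k + 1)`; the per-window values are then aggregated over
#' all windows (arithmetic mean by default). Low values flag repetitive,
#' homopolymer-rich sequence. Ambiguity codes are treated as ordinary
#' distinct symbols.
#'
#' @param sequence nucleotide sequence (single string), length >= `kmax`.
#' @param window window size in bases.
#' @param step step between window starts.
#' @param kmin,kmax minimum and maximum pattern (k-mer) sizes.
#' @param aggregate `"mean"` (default) or `"min"` across windows.
#' @return Complexity in `(0, 1]`.
#' @export
linguistic_complexity <- function(sequence, window = 100, step = 1,
                                  kmin = 3, kmax = 6,
                                  aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  L <- nchar(sequence)
  if (L < kmax) stop("sequence shorter than the maximum pattern size")
  starts <- seq.int(1L, max(1L, L - window + 1L), by = step)
  covered_end <- min(starts[length(starts)] + window - 1L, L)
  nxt <- starts[length(starts)] + step
  if (covered_end < L && (L - nxt + 1L) >= kmax) {
    # trailing shorter window (only reachable for step > 1)
    starts <- c(starts, nxt)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  # k-mer identity per start position, for each k
  kmers <- lapply(kmin:kmax, function(k) {
    n <- L - k + 1L
    m <- vapply(seq_len(k), function(off) chars[off:(off + n - 1L)],
                character(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  })
  lc_w <- vapply(starts, function(s) {
    e <- min(s + window - 1L, L)
    w <- e - s + 1L
    prod(vapply(seq_along(kmers), function(ki) {
      k <- kmin + ki - 1L
      if (w < k) return(1.0)
      u <- length(unique(kmers[[ki]][s:(e - k + 1L)]))
      u / min(4^k, w - k + 1L)
    }, numeric(1)))
  }, numeric(1))
  if (aggregate == "mean") mean(lc_w) else min(lc_w)
}

#' Find homopolymer runs
#'
#' Maximal runs of a single nucleotide at least `min_length` bases long
#' (runs of this length are empirically associated with PCR slippage
#' artifacts). A run is reported once at its full length.
#'
#' @param sequence nucleotide sequence (single string).
#' @param min_length minimum run length to report.
#' @return data.frame with columns `base`, `length`, `start` (1-based),
#'   sorted by `start`; zero rows when none found.
#' @export
find_homopolymers <- function(sequence, min_length = 8) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_length
  data.frame(base = r$values[keep],
             length = r$lengths[keep],
             start = (ends - r$lengths + 1L)[keep])
}

#' Per-record QC table with per-marker summaries
#'
#' Computes the quality index (where per-base qualities and coverage are
#' available), linguistic complexity and homopolymer count for every record
#' of a library, plus per-marker median/IQR summaries.
#'
#' @param lib a [barcode_library()].
#' @param q,x quality-index parameters (see [quality_index()]).
#' @param window,step,kmin,kmax linguistic-complexity parameters
#'   (see [linguistic_complexity()]).
#' @param min_homopolymer minimum homopolymer length (see
#'   [find_homopolymers()]).
#' @return A list with `table` (one row per record: `specimen_id`, `marker`,
#'   `length`, `b_index` — `NA` when qualities are absent — `lc`,
#'   `n_homopolymers`) and `summary` (per marker: median and IQR of
#'   `b_index` and `lc`, total homopolymer-bearing records).
#' @export
qc_table <- function(lib, q = 30, x = 2, window = 100, step = 1,
                     kmin = 3, kmax = 6, min_homopolymer = 8) {
  stopifnot(inherits(lib, "barcode_library"))
  rec <- lib$records
  if (nrow(rec) == 0L) {
    return(list(table = data.frame(specimen_id = character(0),
                                   marker = character(0),
                                   length = integer(0),
                                   b_index = numeric(0), lc = numeric(0),
                                   n_homopolymers = integer(0)),
                summary = data.frame()))
  }
  tab <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    qv <- rec$qualities[[i]]
    cv <- rec$coverage[[i]]
    b <- if (!is.null(qv) && !is.null(cv)) quality_index(qv, cv, q, x)
         else NA_real_
    data.frame(specimen_id = rec$specimen_id[i], marker = rec$marker[i],
               length = nchar(rec$sequence[i]), b_index = b,
               lc = linguistic_complexity(rec$sequence[i], window, step,
                                          kmin, kmax),
               n_homopolymers = nrow(find_homopolymers(rec$sequence[i],
                                                       min_homopolymer)))
  }))
  summ <- do.call(rbind, lapply(split(tab, tab$marker), function(d) {
    data.frame(marker = d$marker[1L],
               n = nrow(d),
               b_median = stats::median(d$b_index, na.rm = TRUE),
               b_q1 = unname(stats::quantile(d$b_index, 0.25, na.rm = TRUE)),
               b_q3 = unname(stats::quantile(d$b_index, 0.75, na.rm = TRUE)),
               lc_median = stats::median(d$lc),
               lc_q1 = unname(stats::quantile(d$lc, 0.25)),
               lc_q3 = unname(stats::quantile(d$lc, 0.75)),
               n_with_homopolymer = sum(d$n_homopolymers > 0))
  }))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}
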