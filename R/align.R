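#' Alignment scoring parameters
#'
#' Scoring for pairwise global alignment. The defaults (match +1,
#' mismatch -1, gap opening -2, gap extension -0.5, terminal gaps free)
#' are appropriate for the near-identical barcode sequences that drive
#' gap and discrimination analysis; free terminal gaps accommodate
#' sequences trimmed to slightly different lengths. A gap of length L
#' costs `|gap_open| + L * |gap_extend|`.
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (negative).
#' @param gap_open gap opening penalty (negative).
#' @param gap_extend per-base gap extension penalty (negative).
#' @param free_end_gaps if `TRUE`, terminal gaps are not penalised
#'   (ends-free global alignment).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -0.5, free_end_gaps = TRUE) {
  stopifnot(match >= 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, free_end_gaps = free_end_gaps),
            class = "align_params")
}

#' Pairwise global alignment
#'
#' Needleman-Wunsch alignment with affine gap costs. Ties are broken
#' deterministically: an aligned (match/mismatch) column is preferred over a
#' gap in `a`, which is preferred over a gap in `b`.
#'
#' @param a,b nucleotide sequences (single strings).
#' @param params an [align_params()] object.
#' @return A list of class `pairwise_alignment` with elements `aligned_a`,
#'   `aligned_b` (equal-length strings over the sequence alphabet plus `-`)
#'   and `score`.
#' @export
pairwise_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  r <- nw_align_cpp(a, b, params$match, params$mismatch, -params$gap_open,
                    -params$gap_extend, params$free_end_gaps)
  structure(r, class = "pairwise_alignment")
}

#' Uncorrected p-distance of a pairwise alignment
#'
#' The number of columns at which both sequences carry different unambiguous
#' nucleotides (A/C/G/T), divided by the total number of alignment columns.
#' Columns containing a gap or an ambiguity code count as aligned positions
#' but never as differences.
#'
#' @param aln a [pairwise_align()] result (or any list with equal-length
#'   `aligned_a`/`aligned_b` strings).
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(aln) {
  cn <- alignment_counts(aln)
  cn[["diffs"]] / cn[["cols"]]
}

# difference / column counts of an alignment
#' @noRd
alignment_counts <- function(aln) {
  a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  if (!length(a)) stop("zero-length alignment")
  acgt <- c("A", "C", "G", "T")
  c(diffs = sum(a %in% acgt & b %in% acgt & a != b), cols = length(a))
}

# per-marker sequences of a library as a named vector, with checks
#' @noRd
marker_sequences <- function(lib, marker, specimens = NULL) {
  rec <- lib$records[lib$records$marker == marker, , drop = FALSE]
  if (is.null(specimens)) specimens <- unique(lib$records$specimen_id)
  missing <- setdiff(specimens, rec$specimen_id)
  if (length(missing)) {
    stop("specimens missing marker ", marker, ": ",
         paste(missing, collapse = ", "))
  }
  stats::setNames(rec$sequence[match(specimens, rec$specimen_id)], specimens)
}

# pairwise difference/column count matrices over a set of sequences,
# deduplicated before alignment
#' @noRd
pair_counts <- function(seqs, params) {
  uniq <- unique(seqs)
  idx <- match(seqs, uniq)
  cn <- pdist_counts_cpp(uniq, params$match, params$mismatch,
                         -params$gap_open, -params$gap_extend,
                         params$free_end_gaps)
  list(diffs = cn$diffs[idx, idx, drop = FALSE],
       cols = cn$cols[idx, idx, drop = FALSE])
}

#' Pairwise p-distance matrix for one marker
#'
#' Every unordered pair of specimens is aligned independently (no multiple
#' sequence alignment) and scored with [p_distance()]. Identical sequences
#' are deduplicated before alignment.
#'
#' @param lib a [barcode_library()]; every specimen must carry `marker`.
#' @param marker marker name.
#' @param params an [align_params()] object.
#' @return A list of class `p_dist_matrix`: `ids`, `species` (parallel to
#'   `ids`), `marker_set`, symmetric matrices `p`, `diffs`, `cols`.
#' @export
distance_matrix <- function(lib, marker, params = align_params()) {
  stopifnot(inherits(lib, "barcode_library"))
  ids <- unique(lib$records$specimen_id)
  seqs <- marker_sequences(lib, marker, ids)
  cn <- pair_counts(seqs, params)
  p <- cn$diffs / cn$cols
  diag(p) <- 0
  dimnames(p) <- dimnames(cn$diffs) <- dimnames(cn$cols) <- list(ids, ids)
  sp <- lib$records$species[match(ids, lib$records$specimen_id)]
  structure(list(ids = ids, species = sp, marker_set = marker, p = p,
                 diffs = cn$diffs, cols = cn$cols),
            class = "p_dist_matrix")
}

#' Pooled multilocus p-distance matrix
#'
#' Markers are used simultaneously: for each specimen pair the nucleotide
#' differences and alignment columns are summed over markers before
#' dividing, which is equivalent to concatenating the per-marker pairwise
#' alignments.
#'
#' @param lib a [barcode_library()]; every specimen must carry all `markers`.
#' @param markers character vector of marker names (default: all).
#' @param params an [align_params()] object.
#' @return A `p_dist_matrix` with `marker_set` set to the marker names.
#' @export
multilocus_distance_matrix <- function(lib, markers = lib$markers,
                                       params = align_params()) {
  stopifnot(inherits(lib, "barcode_library"), length(markers) >= 1)
  ids <- unique(lib$records$specimen_id)
  diffs <- cols <- matrix(0, length(ids), length(ids),
                          dimnames = list(ids, ids))
  for (marker in markers) {
    cn <- pair_counts(marker_sequences(lib, marker, ids), params)
    diffs <- diffs + cn$diffs
    cols <- cols + cn$cols
  }
  p <- diffs / cols
  diag(p) <- 0
  sp <- lib$records$species[match(ids, lib$records$specimen_id)]
  structure(list(ids = ids, species = sp, marker_set = markers, p = p,
                 diffs = diffs, cols = cols),
            class = "p_dist_matrix")
}

#' Pooled multilocus p-distance between two specimens
#'
#' @param lib a [barcode_library()].
#' @param markers marker names to pool.
#' @param specimen_a,specimen_b specimen ids.
#' @param params an [align_params()] object.
#' @return Pooled p-distance (summed differences over summed alignment
#'   columns).
#' @export
multilocus_distance <- function(lib, markers, specimen_a, specimen_b,
                                params = align_params()) {
  stopifnot(inherits(lib, "barcode_library"))
  diffs <- 0; cols <- 0
  for (marker in markers) {
    rec <- lib$records[lib$records$marker == marker, , drop = FALSE]
    for (id in c(specimen_a, specimen_b)) {
      if (!id %in% rec$specimen_id) {
        stop("specimen ", id, " has no record for marker ", marker)
      }
    }
    a <- rec$sequence[match(specimen_a, rec$specimen_id)]
    b <- rec$sequence[match(specimen_b, rec$specimen_id)]
    cn <- nw_counts_cpp(a, b, params$match, params$mismatch,
                        -params$gap_open, -params$gap_extend,
                        params$free_end_gaps)
    diffs <- diffs + cn[1]
    cols <- cols + cn[2]
  }
  unname(diffs / cols)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path FASTA file with equal-length gapped rows.
#' @return Named character vector of aligned rows.
#' @export
read_msa <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  msa <- stats::setNames(toupper(as.character(s)),
                         sub("\\s.*$", "", names(s)))
  if (length(unique(nchar(msa))) > 1) stop("ragged alignment in ", path)
  msa
}

#' Simple indel coding of a multiple sequence alignment
#'
#' Each distinct gap span (identical start and end, in 1-based alignment
#' coordinates, half-open `[start, end)`) becomes one binary character:
#' `1` for rows whose gap matches the span exactly, `0` for rows without a
#' covering gap, and `-` (inapplicable) for rows whose gap strictly contains
#' the span, following the simple-indel-coding rule.
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @return Character matrix (rows = sequences, one column per gap
#'   character, named `g<start>_<end>`); attribute `"spans"` is a
#'   data.frame of the spans. Zero columns when the alignment is gapless.
#' @export
simple_indel_coding <- function(msa) {
  if (length(unique(nchar(msa))) > 1) stop("ragged alignment")
  ids <- names(msa) %||% as.character(seq_along(msa))
  runs <- lapply(msa, function(s) {
    g <- gregexpr("-+", s, perl = TRUE)[[1L]]
    if (g[1L] == -1L) return(data.frame(start = integer(0), end = integer(0)))
    data.frame(start = as.integer(g),
               end = as.integer(g) + attr(g, "match.length"))
  })
  spans <- unique(do.call(rbind, runs))
  if (nrow(spans) == 0L) {
    m <- matrix(character(0), nrow = length(msa), ncol = 0,
                dimnames = list(ids, NULL))
    attr(m, "spans") <- spans
    return(m)
  }
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  rownames(spans) <- NULL
  m <- matrix("0", nrow = length(msa), ncol = nrow(spans),
              dimnames = list(ids, paste0("g", spans$start, "_", spans$end)))
  for (i in seq_along(msa)) {
    r <- runs[[i]]
    for (k in seq_len(nrow(spans))) {
      s <- spans$start[k]; e <- spans$end[k]
      exact <- any(r$start == s & r$end == e)
      contains <- any(r$start <= s & r$end >= e & !(r$start == s & r$end == e))
      m[i, k] <- if (exact) "1" else if (contains) "-" else "0"
    }
  }
  attr(m, "spans") <- spans
  m
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' Convenience builder for tree-based identification when no externally
#' inferred tree is available. Specimens are ordered by id before the
#' neighbor-joining pass so that tied distances resolve deterministically.
#'
#' @param dm a `p_dist_matrix` (from [distance_matrix()] or
#'   [multilocus_distance_matrix()]) or a symmetric numeric matrix with
#'   specimen ids as dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  mat <- if (inherits(dm, "p_dist_matrix")) dm$p else as.matrix(dm)
  if (nrow(mat) < 3) stop("neighbor joining needs at least 3 specimens")
  ord <- order(rownames(mat))
  ape::nj(stats::as.dist(mat[ord, ord]))
}

#' Write a distance matrix to disk
#'
#' @param dm a `p_dist_matrix`.
#' @param path output file.
#' @param format `"csv"` (square, with header) or `"phylip"` (square
#'   lower-precision PHYLIP-style matrix).
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  stopifnot(inherits(dm, "p_dist_matrix"))
  if (format == "csv") {
    utils::write.csv(dm$p, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$ids)), con)
    for (i in seq_along(dm$ids)) {
      writeLines(paste(c(format(dm$ids[i], width = 10),
                         sprintf("%.6f", dm$p[i, ])), collapse = " "), con)
    }
  }
  invisible(path)
}
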