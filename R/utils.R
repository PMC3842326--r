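# internal helpers shared across modules

# IUPAC nucleotide codes (no gap characters)
IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' @noRd
assert_iupac <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence for '", id, "' must be a single non-empty string",
         call. = FALSE)
  }
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, IUPAC_CODES)
  if (length(bad)) {
    stop("sequence for '", id, "' contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Run code with a temporary RNG state; restores the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
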