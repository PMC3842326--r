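#' Construct a barcode library
#'
#' A barcode library is the central container of the package: one record per
#' specimen x marker, each carrying the specimen's species and genus labels,
#' an upper-case IUPAC nucleotide sequence without gap characters, and
#' optionally per-base Phred quality values, per-base read coverage (contig
#' size per position) and a database accession.
#'
#' @param records data.frame with columns `specimen_id`, `species`, `genus`,
#'   `marker`, `sequence`, optional `accession`, and optional list-columns
#'   `qualities` and `coverage` (integer vectors matching sequence length,
#'   or `NULL` where unavailable).
#' @param markers ordered character vector of marker names; defaults to the
#'   order of first appearance in `records`.
#' @return An object of class `barcode_library`.
#' @export
barcode_library <- function(records, markers = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("specimen_id", "species", "genus", "marker", "sequence")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"accession" %in% names(records)) {
    records$accession <- rep(NA_character_, nrow(records))
  }
  if (!"qualities" %in% names(records)) {
    records$qualities <- I(vector("list", nrow(records)))
  }
  if (!"coverage" %in% names(records)) {
    records$coverage <- I(vector("list", nrow(records)))
  }
  rownames(records) <- NULL

  if (nrow(records)) {
    if (any(!nzchar(records$species) | is.na(records$species))) {
      stop("every record must carry a non-empty species label")
    }
    key <- paste(records$specimen_id, records$marker, sep = "\r")
    dup <- key[duplicated(key)]
    if (length(dup)) {
      stop("duplicate (specimen, marker) records: ",
           paste(unique(gsub("\r", " / ", dup)), collapse = "; "))
    }
    for (i in seq_len(nrow(records))) {
      assert_iupac(records$sequence[i], records$specimen_id[i])
      L <- nchar(records$sequence[i])
      qv <- records$qualities[[i]]
      if (!is.null(qv)) {
        if (length(qv) != L) stop("qualities length mismatch for ",
                                  records$specimen_id[i])
        if (any(qv < 0)) stop("negative quality values for ",
                              records$specimen_id[i])
      }
      cv <- records$coverage[[i]]
      if (!is.null(cv)) {
        if (length(cv) != L) stop("coverage length mismatch for ",
                                  records$specimen_id[i])
        if (any(cv < 1)) stop("coverage values must be >= 1 for ",
                              records$specimen_id[i])
      }
    }
  }
  if (is.null(markers)) markers <- unique(records$marker)
  structure(list(records = records, markers = as.character(markers)),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", nrow(x$records), "records,",
      length(unique(x$records$specimen_id)), "specimens,",
      length(unique(x$records$species)), "species,",
      length(x$markers), "markers (",
      paste(x$markers, collapse = ", "), ")\n")
  invisible(x)
}

#' Species index of a library
#'
#' @param lib a [barcode_library()].
#' @return Named list mapping each species to the specimen ids carrying it.
#' @export
species_index <- function(lib) {
  stopifnot(inherits(lib, "barcode_library"))
  sp <- unique(lib$records[, c("specimen_id", "species")])
  split(sp$specimen_id, sp$species)
}

#' Number of specimens per species
#'
#' @param lib a [barcode_library()].
#' @return Named integer vector (the "n" column of a diagnostic-variation
#'   table).
#' @export
n_per_species <- function(lib) {
  vapply(species_index(lib), length, integer(1))
}

#' Read a barcode library from FASTA files plus a metadata table
#'
#' One FASTA file per marker; the first whitespace-delimited token of each
#' header is the specimen id and must be present in the metadata table.
#' Sequences are upper-cased and terminal gap characters stripped; internal
#' gap characters are an error (p-distances are computed on unaligned
#' sequences, alignment happens downstream). Metadata is tab-separated with
#' header columns `specimen_id`, `species`, `genus`, optionally `exclude`
#' (1/TRUE rows are dropped, e.g. specimens without a definitive
#' morphological identification) and per-marker accession columns named
#' `accession_<marker>`.
#'
#' @param fasta_paths named character vector, names are marker names.
#' @param metadata_path path to the TSV metadata table.
#' @return A [barcode_library()]; attribute `"per_marker_counts"` reports the
#'   number of records read per marker, attribute `"excluded"` the specimen
#'   ids dropped through the `exclude` column.
#' @export
read_library <- function(fasta_paths, metadata_path) {
  if (is.null(names(fasta_paths)) || any(!nzchar(names(fasta_paths)))) {
    stop("fasta_paths must be a named vector: names are marker names")
  }
  for (p in c(fasta_paths, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            check.names = FALSE, fileEncoding = "UTF-8")
  needed <- c("specimen_id", "species", "genus")
  if (length(setdiff(needed, names(meta)))) {
    stop("metadata must contain columns: ", paste(needed, collapse = ", "))
  }
  excluded <- character(0)
  if ("exclude" %in% names(meta)) {
    drop <- meta$exclude %in% c(1, "1", TRUE, "TRUE", "true", "yes")
    excluded <- meta$specimen_id[drop]
    meta <- meta[!drop, , drop = FALSE]
  }

  rows <- list()
  counts <- integer(0)
  for (marker in names(fasta_paths)) {
    seqs <- Biostrings::readDNAStringSet(fasta_paths[[marker]])
    ids <- sub("\\s.*$", "", names(seqs))
    s <- toupper(as.character(seqs))
    s <- gsub("^-+|-+$", "", s)
    unknown <- setdiff(ids, meta$specimen_id)
    if (length(unknown)) {
      stop("FASTA ids absent from metadata (marker ", marker, "): ",
           paste(unknown, collapse = ", "))
    }
    if (any(grepl("-", s, fixed = TRUE))) {
      stop("internal gap characters in marker ", marker, " sequences: ",
           paste(ids[grepl("-", s, fixed = TRUE)], collapse = ", "))
    }
    m <- match(ids, meta$specimen_id)
    acc_col <- paste0("accession_", marker)
    acc <- if (acc_col %in% names(meta)) as.character(meta[[acc_col]][m])
           else NA_character_
    rows[[marker]] <- data.frame(
      specimen_id = ids, species = meta$species[m], genus = meta$genus[m],
      marker = marker, sequence = unname(s), accession = acc,
      stringsAsFactors = FALSE)
    counts[[marker]] <- length(ids)
  }
  lib <- barcode_library(do.call(rbind, rows), markers = names(fasta_paths))
  attr(lib, "per_marker_counts") <- counts
  attr(lib, "excluded") <- excluded
  lib
}

#' Write a barcode library to FASTA files plus a metadata table
#'
#' Inverse of [read_library()]: one FASTA per marker (`<marker>.fasta`) and
#' `metadata.tsv`, in a stable order so identical libraries produce
#' byte-identical files.
#'
#' @param lib a [barcode_library()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (named by marker, plus `"metadata"`).
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "barcode_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (marker in lib$markers) {
    rec <- lib$records[lib$records$marker == marker, , drop = FALSE]
    path <- file.path(dir, paste0(marker, ".fasta"))
    con <- file(path, open = "wb")
    writeLines(paste0(">", rec$specimen_id, "\n", rec$sequence), con, sep = "\n")
    close(con)
    paths[[marker]] <- path
  }
  sp <- unique(lib$records[, c("specimen_id", "species", "genus")])
  acc <- lib$records[!is.na(lib$records$accession),
                     c("specimen_id", "marker", "accession")]
  for (marker in lib$markers) {
    col <- paste0("accession_", marker)
    a <- acc[acc$marker == marker, , drop = FALSE]
    sp[[col]] <- a$accession[match(sp$specimen_id, a$specimen_id)]
  }
  mpath <- file.path(dir, "metadata.tsv")
  con <- file(mpath, open = "wb")
  writeLines(paste(colnames(sp), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(sp, as.character), sep = "\t")), con)
  close(con)
  paths[["metadata"]] <- mpath
  invisible(paths)
}

#' Restrict a library to complete samples
#'
#' Keeps exactly the specimens that have one record for every required
#' marker — the analysis unit for cross-marker comparisons (a specimen
#' missing any marker is dropped entirely, so that all markers are scored
#' on the same specimens). Species left with no specimens disappear from
#' the species index.
#'
#' @param lib a [barcode_library()].
#' @param required_markers character vector of marker names; defaults to all
#'   markers of `lib`.
#' @return A [barcode_library()] containing only complete samples.
#' @export
select_complete_samples <- function(lib, required_markers = lib$markers) {
  stopifnot(inherits(lib, "barcode_library"))
  unknown <- setdiff(required_markers, lib$markers)
  if (length(unknown)) {
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  }
  rec <- lib$records
  have <- table(rec$specimen_id[rec$marker %in% required_markers])
  keep_ids <- names(have)[have == length(required_markers)]
  keep <- rec$specimen_id %in% keep_ids
  barcode_library(rec[keep, , drop = FALSE], markers = lib$markers)
}

#' Packaged diagnostic-variation table for Podocarpaceae
#'
#' The published per-species results for the 97 Podocarpaceae species in the
#' complete sample (all three markers recovered): number of individuals `n`,
#' discrimination indicator (`+`/`-`) for matK, rbcL, nrITS2 and the
#' three-marker combination, and the multilocus barcode-gap flag (1/0).
#' Used to exercise the aggregation and statistics paths against printed
#' summary values.
#'
#' @return data.frame of class `results_table` with columns `species`, `n`,
#'   `matK`, `rbcL`, `nrITS2`, `combined`, `gap`.
#' @export
load_results_fixture <- function() {
  path <- system.file("extdata", "podocarpaceae_table1.tsv",
                      package = "barcodeval", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("species", "n", "matK", "rbcL", "nrITS2", "combined",
                  "gap") %in% names(tab)),
            all(tab$n >= 1),
            all(unlist(tab[, c("matK", "rbcL", "nrITS2", "combined")]) %in%
                  c("+", "-")),
            all(tab$gap %in% c(0L, 1L)))
  class(tab) <- c("results_table", class(tab))
  tab
}

#' Read a specimen tree from a Newick file
#'
#' Leaf labels must be specimen ids; when a library is supplied they are
#' checked against it.
#'
#' @param newick_path path to a Newick file (or a Newick string).
#' @param lib optional [barcode_library()] used to validate leaf labels.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(newick_path, lib = NULL) {
  tr <- tryCatch({
    if (file.exists(newick_path)) ape::read.tree(newick_path)
    else ape::read.tree(text = newick_path)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick input: ", newick_path)
  }
  if (!is.null(lib)) {
    ids <- unique(lib$records$specimen_id)
    unmatched <- setdiff(tr$tip.label, ids)
    if (length(unmatched)) {
      stop("tree leaves not found in library: ",
           paste(unmatched, collapse = ", "))
    }
  }
  tr
}
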