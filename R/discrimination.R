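#' Build a reference database from all sequences
#'
#' Deduplicates the sequences of each marker into a genotype registry
#' recording, for every distinct sequence, the specimens and species that
#' carry it. The reference should be built from *all* available sequences,
#' not just complete samples — restricting it to the query set overestimates
#' discrimination success.
#'
#' @param lib_all a [barcode_library()] with every available record.
#' @param markers marker names to index (default: all markers of `lib_all`).
#' @return An object of class `reference_db`: per marker a data.frame with
#'   `sequence`, `count`, and list-columns `species_set`, `specimen_ids`.
#' @export
build_reference <- function(lib_all, markers = lib_all$markers) {
  stopifnot(inherits(lib_all, "barcode_library"))
  if (nrow(lib_all$records) == 0L) stop("empty library")
  registry <- lapply(stats::setNames(markers, markers), function(m) {
    r <- lib_all$records[lib_all$records$marker == m, , drop = FALSE]
    uniq <- unique(r$sequence)
    data.frame(
      sequence = uniq,
      count = as.integer(table(factor(r$sequence, levels = uniq))),
      species_set = I(lapply(uniq, function(s) {
        sort(unique(r$species[r$sequence == s]))
      })),
      specimen_ids = I(lapply(uniq, function(s) {
        r$specimen_id[r$sequence == s]
      })),
      specimen_species = I(lapply(uniq, function(s) {
        r$species[r$sequence == s]
      })),
      stringsAsFactors = FALSE)
  })
  structure(list(markers = markers, registry = registry),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  for (m in x$markers) {
    cat(m, ":", nrow(x$registry[[m]]), "distinct sequence types\n")
  }
  invisible(x)
}

# species sets returned for a set of query sequences against one marker's
# registry, at minimal p-distance with all ties included
#' @noRd
query_sets <- function(ref, queries, marker, params) {
  reg <- ref$registry[[marker]]
  if (is.null(reg) || nrow(reg) == 0L) stop("empty reference for marker ",
                                            marker)
  # distances between all query sequences and all registry sequences,
  # computed over the deduplicated union
  pool <- unique(c(queries, reg$sequence))
  cn <- pdist_counts_cpp(pool, params$match, params$mismatch,
                         -params$gap_open, -params$gap_extend,
                         params$free_end_gaps)
  p <- cn$diffs / cn$cols
  qi <- match(queries, pool)
  ri <- match(reg$sequence, pool)
  lapply(seq_along(queries), function(k) {
    d <- p[qi[k], ri]
    dmin <- min(d)
    hits <- which(d <= dmin + 1e-15)
    list(species = sort(unique(unlist(reg$species_set[hits]))),
         distance = dmin)
  })
}

#' Query a reference database with one sequence
#'
#' Returns the set of species owning at least one reference sequence at
#' minimal p-distance from the query, with all ties included. When the
#' query's own record is part of the reference the minimal distance is zero
#' and the conspecific species is guaranteed to be returned.
#'
#' @param ref a [build_reference()] database.
#' @param sequence query sequence (single string).
#' @param marker marker name.
#' @param params an [align_params()] object.
#' @return A list of class `query_result`: `marker`, `species` (sorted),
#'   `distance` (minimal p-distance achieved).
#' @export
query_reference <- function(ref, sequence, marker, params = align_params()) {
  stopifnot(inherits(ref, "reference_db"))
  if (!marker %in% ref$markers) stop("unknown marker: ", marker)
  r <- query_sets(ref, sequence, marker, params)[[1L]]
  structure(list(marker = marker, species = r$species,
                 distance = r$distance), class = "query_result")
}

#' Combine per-marker query results for one specimen
#'
#' Marker combination uses set intersection of the per-marker returned
#' species sets: a species survives only if it is returned by every marker.
#' This handles references with unequal marker coverage and makes
#' combination monotone — adding a marker can only shrink the returned set.
#' An empty intersection (possible only when the specimen's own records are
#' not all in the reference) is reported with a warning, not dropped.
#'
#' @param results list of [query_reference()] results for one specimen.
#' @return A `query_result` whose `marker` is the combination label,
#'   `species` the intersection, `distance` the largest per-marker minimal
#'   distance.
#' @export
combine_queries <- function(results) {
  stopifnot(length(results) >= 1)
  species <- Reduce(intersect, lapply(results, `[[`, "species"))
  if (length(species) == 0L) {
    warning("empty intersection of per-marker query results")
  }
  structure(list(marker = paste(vapply(results, `[[`, "", "marker"),
                                collapse = "+"),
                 species = sort(species),
                 distance = max(vapply(results, `[[`, 0, "distance"))),
            class = "query_result")
}

# all non-empty subsets of a marker vector, singletons first
#' @noRd
all_marker_sets <- function(markers) {
  unlist(lapply(seq_along(markers), function(k) {
    asplit(utils::combn(markers, k), 2)
  }), recursive = FALSE)
}

#' Reference-database species discrimination
#'
#' Every complete-sample specimen is queried against the reference for each
#' marker; marker combinations intersect the per-marker species sets. A
#' species is scored `+` for a marker set when all queries of all its
#' specimens return exactly that species, and `-` otherwise, in which case
#' the wrongly returned (conflated) species are reported in descending
#' order of how many queries returned them (alphabetical on ties).
#'
#' @param lib_complete the complete-sample [barcode_library()] to evaluate.
#' @param ref a [build_reference()] database built from all sequences.
#' @param marker_sets list of character vectors; default: every non-empty
#'   subset of the reference's markers.
#' @param params an [align_params()] object.
#' @param leave_one_out if `TRUE`, each query specimen's own records are
#'   removed from the reference for its queries (for comparison; the
#'   default keeps them in, matching evaluation against a database built
#'   from all sequences).
#' @param level confidence level for Wilson intervals.
#' @return A list with `rows` (per species x marker set: `indicator`,
#'   list-column `conflated`, `conflated_str`) and `summary` (per marker
#'   set: `k`, `n_species`, `percent`, Wilson `ci_lower`/`ci_upper` on the
#'   percent scale, and `conflated_mean`/`conflated_sd`, the mean and sd of
#'   the number of conflated species among failed species).
#' @export
species_discrimination <- function(lib_complete, ref, marker_sets = NULL,
                                   params = align_params(),
                                   leave_one_out = FALSE, level = 0.95) {
  stopifnot(inherits(lib_complete, "barcode_library"),
            inherits(ref, "reference_db"))
  if (is.null(marker_sets)) marker_sets <- all_marker_sets(ref$markers)
  specimens <- unique(lib_complete$records[, c("specimen_id", "species")])
  zero_sp <- setdiff(unique(lib_complete$records$species),
                     specimens$species)
  if (length(zero_sp)) stop("species with zero complete samples: ",
                            paste(zero_sp, collapse = ", "))

  # per-marker returned species set for every specimen, computed once
  per_marker <- list()
  for (m in unique(unlist(marker_sets))) {
    seqs <- marker_sequences(lib_complete, m, specimens$specimen_id)
    if (leave_one_out) {
      per_marker[[m]] <- lapply(seq_along(seqs), function(k) {
        loo_query(ref, seqs[[k]], m, params, specimens$specimen_id[k])
      })
    } else {
      per_marker[[m]] <- query_sets(ref, unname(seqs), m, params)
    }
  }

  rows <- list()
  summ <- list()
  for (ms in marker_sets) {
    label <- paste(ms, collapse = "+")
    returned <- lapply(seq_len(nrow(specimens)), function(k) {
      Reduce(intersect, lapply(ms, function(m) per_marker[[m]][[k]]$species))
    })
    sp_rows <- list()
    for (sp in sort(unique(specimens$species))) {
      idx <- which(specimens$species == sp)
      ok <- all(vapply(returned[idx], function(r) identical(r, sp),
                       logical(1)))
      wrong <- unlist(returned[idx])
      wrong <- wrong[wrong != sp]
      freq <- table(factor(wrong))
      ord <- if (length(freq)) names(freq)[order(-freq, names(freq))]
             else character(0)
      sp_rows[[sp]] <- data.frame(
        species = sp, marker_set = label, n = length(idx),
        indicator = if (ok) "+" else "-",
        conflated_str = paste(ord, collapse = ", "),
        stringsAsFactors = FALSE)
      sp_rows[[sp]]$conflated <- I(list(ord))
    }
    d <- do.call(rbind, sp_rows)
    rows[[label]] <- d
    k <- sum(d$indicator == "+")
    n <- nrow(d)
    ci <- wilson_ci(k, n, level)
    sizes <- lengths(d$conflated[d$indicator == "-"])
    summ[[label]] <- data.frame(
      marker_set = label, k = k, n_species = n, percent = 100 * k / n,
      ci_lower = 100 * ci$lower, ci_upper = 100 * ci$upper,
      conflated_mean = if (length(sizes)) mean(sizes) else NA_real_,
      conflated_sd = if (length(sizes) > 1) stats::sd(sizes) else NA_real_,
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  list(rows = rows, summary = summ)
}

# leave-one-out variant of a single query: the query specimen's own records
# are removed from the registry before matching
#' @noRd
loo_query <- function(ref, sequence, marker, params, specimen_id) {
  reg <- ref$registry[[marker]]
  # drop the specimen: a genotype carried only by it disappears, and the
  # species sets of shared genotypes are recomputed without it
  keep <- vapply(seq_len(nrow(reg)), function(i) {
    any(!reg$specimen_ids[[i]] %in% specimen_id)
  }, logical(1))
  if (!any(keep)) stop("reference empty after leave-one-out for ",
                       specimen_id)
  sets <- lapply(seq_len(nrow(reg)), function(i) {
    ids <- reg$specimen_ids[[i]]
    sort(unique(reg$specimen_species[[i]][!ids %in% specimen_id]))
  })
  pool <- unique(c(sequence, reg$sequence))
  cn <- pdist_counts_cpp(pool, params$match, params$mismatch,
                         -params$gap_open, -params$gap_extend,
                         params$free_end_gaps)
  p <- cn$diffs / cn$cols
  d <- p[match(sequence, pool), match(reg$sequence, pool)]
  dmin <- min(d[keep])
  hits <- which(keep & d <= dmin + 1e-15)
  list(species = sort(unique(unlist(sets[hits]))), distance = dmin)
}

#' Tree-based identification by the least-inclusive-clade criterion
#'
#' A species is scored `+` when the smallest clade containing all of its
#' samples contains no samples of any other species (i.e. its samples are
#' monophyletic on the supplied tree). The criterion is undefined for
#' species with a single sample, which are returned as `NA`. The tree is
#' used as rooted as supplied.
#'
#' @param tree a `phylo` tree whose tips are specimen ids.
#' @param species_map named character vector mapping specimen id to
#'   species, or a [barcode_library()].
#' @return data.frame with `species`, `n_tips`, `indicator`
#'   (`"+"`, `"-"`, or `NA` for singletons).
#' @export
least_inclusive_clade <- function(tree, species_map) {
  stopifnot(inherits(tree, "phylo"))
  if (inherits(species_map, "barcode_library")) {
    sp <- unique(species_map$records[, c("specimen_id", "species")])
    species_map <- stats::setNames(sp$species, sp$specimen_id)
  }
  unmapped <- setdiff(tree$tip.label, names(species_map))
  if (length(unmapped)) {
    stop("tree leaves without species mapping: ",
         paste(unmapped, collapse = ", "))
  }
  tip_species <- species_map[tree$tip.label]
  out <- lapply(sort(unique(tip_species)), function(sp) {
    tips <- tree$tip.label[tip_species == sp]
    ind <- if (length(tips) < 2) {
      NA_character_
    } else {
      mrca <- ape::getMRCA(tree, tips)
      clade_tips <- ape::extract.clade(tree, mrca)$tip.label
      if (setequal(clade_tips, tips)) "+" else "-"
    }
    data.frame(species = sp, n_tips = length(tips), indicator = ind,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
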