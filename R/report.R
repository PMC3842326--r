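#' Assemble a diagnostic-variation report
#'
#' Combines the discrimination and barcode-gap stage outputs into one
#' per-species table shaped like a published diagnostic-variation table:
#' one row per species with `n`, a `+`/`-` indicator per single marker and
#' for the full combination, the multilocus gap flag (1/0), and the
#' conflated-species list for the combination (ordered by conflation
#' frequency).
#'
#' @param disc a [species_discrimination()] result.
#' @param gap a [gap_frequencies()] result for the same library.
#' @param markers marker order for the indicator columns (default: the
#'   single-marker sets present in `disc`).
#' @return A list of class `barcode_report`: `table` (the per-species
#'   data.frame, species in input order), `discrimination_summary`,
#'   `gap_summary`.
#' @export
make_report <- function(disc, gap, markers = NULL) {
  rows <- disc$rows
  sets <- unique(rows$marker_set)
  if (is.null(markers)) markers <- sets[!grepl("+", sets, fixed = TRUE)]
  combined <- sets[which.max(nchar(sets))]
  multilocus <- unique(gap$per_species$marker_set)
  multilocus <- multilocus[which.max(nchar(multilocus))]

  base <- rows[rows$marker_set == combined, c("species", "n")]
  tab <- base
  for (m in markers) {
    tab[[m]] <- rows$indicator[rows$marker_set == m][
      match(tab$species, rows$species[rows$marker_set == m])]
  }
  tab$combined <- rows$indicator[rows$marker_set == combined][
    match(tab$species, rows$species[rows$marker_set == combined])]
  gp <- gap$per_species[gap$per_species$marker_set == multilocus, ]
  tab$gap <- as.integer(gp$gap[match(tab$species, gp$species)])
  tab$conflated <- rows$conflated_str[rows$marker_set == combined][
    match(tab$species, rows$species[rows$marker_set == combined])]
  rownames(tab) <- NULL
  structure(list(table = tab, discrimination_summary = disc$summary,
                 gap_summary = gap$summary),
            class = "barcode_report")
}

#' Write a report to disk
#'
#' Writes the per-species table (`report_table.csv`), the machine-readable
#' summary (`summary.json`), and figure-data CSVs: intra- versus
#' inter-specific distances per species and marker set
#' (`gap_scatter.csv`), and per-marker-set discrimination percentages with
#' confidence intervals (`discrimination_summary.csv`).
#'
#' @param report a [make_report()] result.
#' @param dir output directory (created if needed).
#' @param gap optionally the full [gap_frequencies()] result, to write the
#'   per-species distance scatter data.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, gap = NULL) {
  stopifnot(inherits(report, "barcode_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "report_table.csv"),
             summary = file.path(dir, "summary.json"),
             discrimination = file.path(dir, "discrimination_summary.csv"))
  utils::write.csv(report$table, paths[["table"]], row.names = FALSE)
  utils::write.csv(report$discrimination_summary, paths[["discrimination"]],
                   row.names = FALSE)
  jsonlite::write_json(
    list(discrimination = report$discrimination_summary,
         gap = report$gap_summary),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  if (!is.null(gap)) {
    paths[["gap_scatter"]] <- file.path(dir, "gap_scatter.csv")
    utils::write.csv(gap$per_species, paths[["gap_scatter"]],
                     row.names = FALSE)
  }
  invisible(paths)
}

#' Summary statistics of a diagnostic-variation table
#'
#' The aggregation path applied to a per-species results table (such as the
#' packaged Podocarpaceae fixture): percent of species discriminated per
#' indicator column with Wilson confidence intervals, percent of species
#' with a multilocus barcode gap, the gap-versus-discrimination concordance
#' with McNemar tests, and the point-biserial correlation between sample
#' size and gap presence.
#'
#' @param tab a `results_table` (see [load_results_fixture()]): columns
#'   `species`, `n`, indicator columns (`+`/`-`), and `gap` (0/1).
#' @param indicator_cols names of the indicator columns.
#' @param level confidence level.
#' @return A list with `n_species`, `discrimination` (per indicator column:
#'   `k`, `percent`, `ci_lower`, `ci_upper` on the percent scale), `gap`
#'   (`k`, `percent`, CI), `concordance`
#'   ([gap_discrimination_concordance()] of gap against the last indicator
#'   column), and `sample_size_vs_gap` ([point_biserial()]).
#' @export
summarize_results <- function(tab,
                              indicator_cols = c("matK", "rbcL", "nrITS2",
                                                 "combined"),
                              level = 0.95) {
  stopifnot(all(c("species", "n", "gap", indicator_cols) %in% names(tab)))
  n <- nrow(tab)
  disc <- do.call(rbind, lapply(indicator_cols, function(col) {
    k <- sum(tab[[col]] == "+")
    ci <- wilson_ci(k, n, level)
    data.frame(indicator = col, k = k, n_species = n,
               percent = 100 * k / n, ci_lower = 100 * ci$lower,
               ci_upper = 100 * ci$upper, stringsAsFactors = FALSE)
  }))
  kg <- sum(tab$gap == 1)
  cig <- wilson_ci(kg, n, level)
  list(n_species = n,
       discrimination = disc,
       gap = data.frame(k = kg, n_species = n, percent = 100 * kg / n,
                        ci_lower = 100 * cig$lower,
                        ci_upper = 100 * cig$upper),
       concordance = gap_discrimination_concordance(
         tab$gap == 1, tab[[indicator_cols[length(indicator_cols)]]]),
       sample_size_vs_gap = point_biserial(tab$gap, tab$n))
}
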