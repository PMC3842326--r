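#' Per-species barcode-gap analysis of a distance matrix
#'
#' For each species, the maximum intraspecific p-distance (0 for species
#' with a single specimen, where no within-species pair exists) is compared
#' to the minimum interspecific p-distance (over all pairs of one member
#' and one non-member). A species has a barcode gap when the minimum
#' interspecific distance strictly exceeds the maximum intraspecific
#' distance; ties score as no gap. Under the singleton convention a species
#' with one specimen has a gap exactly when its nearest heterospecific is
#' at non-zero distance — so singletons can carry either flag.
#'
#' @param dm a `p_dist_matrix` from [distance_matrix()] or
#'   [multilocus_distance_matrix()] (species labels are carried in it).
#' @param species optional character vector to restrict the species scored
#'   (default: every species in `dm`); unknown names are an error.
#' @return data.frame with `species`, `marker_set`, `n`, `max_intra`,
#'   `min_inter`, `gap` (logical).
#' @export
species_gap <- function(dm, species = NULL) {
  stopifnot(inherits(dm, "p_dist_matrix"))
  all_sp <- unique(dm$species)
  if (is.null(species)) species <- sort(all_sp)
  unknown <- setdiff(species, all_sp)
  if (length(unknown)) {
    stop("species absent from distance matrix: ",
         paste(unknown, collapse = ", "))
  }
  out <- lapply(species, function(sp) {
    idx <- which(dm$species == sp)
    max_intra <- if (length(idx) > 1) {
      sub <- dm$p[idx, idx, drop = FALSE]
      max(sub[upper.tri(sub)])
    } else 0
    min_inter <- if (length(idx) < length(dm$ids)) {
      min(dm$p[idx, -idx, drop = FALSE])
    } else Inf
    data.frame(species = sp,
               marker_set = paste(dm$marker_set, collapse = "+"),
               n = length(idx), max_intra = max_intra,
               min_inter = min_inter, gap = min_inter > max_intra,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Barcode-gap frequencies per marker and multilocus
#'
#' Runs [species_gap()] on each single-marker distance matrix and on the
#' pooled multilocus matrix of a complete-sample library, and summarises the
#' percentage of species with a gap, with 95% Wilson confidence intervals
#' (each species counted once as an independent binomial trial).
#'
#' @param lib a complete-sample [barcode_library()].
#' @param markers marker names (default: all markers of `lib`).
#' @param params an [align_params()] object.
#' @param level confidence level for the Wilson intervals.
#' @return A list with `per_species` (stacked [species_gap()] rows for every
#'   marker set) and `summary` (per marker set: `k`, `n_species`,
#'   `percent`, `ci_lower`, `ci_upper` on the percent scale).
#' @export
gap_frequencies <- function(lib, markers = lib$markers,
                            params = align_params(), level = 0.95) {
  stopifnot(inherits(lib, "barcode_library"))
  sets <- c(as.list(markers), list(markers))
  per_species <- do.call(rbind, lapply(sets, function(ms) {
    dm <- if (length(ms) == 1) distance_matrix(lib, ms, params)
          else multilocus_distance_matrix(lib, ms, params)
    species_gap(dm)
  }))
  summary <- do.call(rbind, lapply(split(per_species,
                                         per_species$marker_set), function(d) {
    ci <- wilson_ci(sum(d$gap), nrow(d), level)
    data.frame(marker_set = d$marker_set[1], k = sum(d$gap),
               n_species = nrow(d), percent = 100 * sum(d$gap) / nrow(d),
               ci_lower = 100 * ci$lower, ci_upper = 100 * ci$upper,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_species = per_species, summary = summary)
}

#' Concordance between barcode gaps and discrimination success
#'
#' Cross-tabulates the per-species gap flag against the per-species
#' discrimination indicator and tests the discordant cells with McNemar's
#' test (both the exact binomial and the chi-squared form are reported,
#' since the two can differ materially at small discordant counts).
#'
#' @param gap logical (or 0/1) vector of per-species gap flags.
#' @param discrimination vector of per-species indicators: logical, 0/1, or
#'   `"+"`/`"-"`.
#' @return A list with `table` (2x2 contingency matrix), `b` (gap without
#'   discrimination), `c` (discrimination without gap), `mcnemar_exact` and
#'   `mcnemar_chi2` ([mcnemar_test()] results).
#' @export
gap_discrimination_concordance <- function(gap, discrimination) {
  if (length(gap) != length(discrimination)) {
    stop("gap and discrimination vectors differ in length")
  }
  g <- as.logical(gap)
  d <- if (is.character(discrimination)) discrimination == "+"
       else as.logical(discrimination)
  tab <- matrix(c(sum(g & d), sum(g & !d), sum(!g & d), sum(!g & !d)),
                nrow = 2, byrow = TRUE,
                dimnames = list(gap = c("gap", "no gap"),
                                discrimination = c("+", "-")))
  b <- tab["gap", "-"]
  cc <- tab["no gap", "+"]
  list(table = tab, b = b, c = cc,
       mcnemar_exact = mcnemar_test(b, cc, mode = "exact"),
       mcnemar_chi2 = if (b + cc > 0) mcnemar_test(b, cc, mode = "chi2")
                      else NULL)
}
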