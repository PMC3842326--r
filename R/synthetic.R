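#' Configuration for the synthetic barcode-library generator
#'
#' The defaults emulate a realistic multi-marker conifer barcoding study:
#' marker lengths equal to the study-scale medians for matK (769 bp),
#' rbcL (607 bp) and nrITS2 (425 bp), one to three individuals per species,
#' pairwise interspecific divergence around 1% and intraspecific divergence
#' around 0.2% (uncorrected p-distance scale), and a quality profile in
#' which 93.5% of positions reach QV 30 with mostly bidirectional coverage.
#'
#' @param n_species number of species.
#' @param individuals_per_species inclusive range `c(min, max)` of
#'   individuals drawn per species.
#' @param markers named integer vector: marker name -> sequence length (bp).
#' @param interspecific_divergence target substitutions per site between
#'   species genotypes (each genotype is mutated away from a common
#'   ancestral sequence at half this rate, so pairwise divergence is close
#'   to the target).
#' @param intraspecific_divergence expected substitutions per site between
#'   an individual and its species genotype.
#' @param shared_genotype_pairs list of integer pairs `c(i, j)`: species `j`
#'   is forced to share one full multilocus genotype with species `i` (one
#'   individual of `j` carries an exact copy of `i`'s genotype).
#' @param homopolymer_insertions list of `list(marker =, base =, length =)`:
#'   a homopolymer run of the given base is written into the ancestral
#'   sequence of the marker (overwriting, so all sequence lengths are
#'   preserved and no indels are introduced).
#' @param quality_profile `list(frac_hq =, coverage_probs =)`: fraction of
#'   positions with QV >= 30, and a named probability vector over coverage
#'   values (default over 1/2/3 reads).
#' @param species_per_genus species are assigned to genera in blocks of this
#'   size (labels only; has no effect on sequence generation).
#' @param seed integer seed; a fixed seed makes the generated library
#'   byte-identical across runs.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 10,
                             individuals_per_species = c(1, 3),
                             markers = c(matK = 769, rbcL = 607,
                                         nrITS2 = 425),
                             interspecific_divergence = 0.01,
                             intraspecific_divergence = 0.002,
                             shared_genotype_pairs = list(),
                             homopolymer_insertions = list(),
                             quality_profile = list(
                               frac_hq = 0.935,
                               coverage_probs = c(`1` = 0.1, `2` = 0.8,
                                                  `3` = 0.1)),
                             species_per_genus = 5,
                             seed = 1) {
  stopifnot(n_species >= 1,
            length(individuals_per_species) == 2,
            individuals_per_species[1] >= 1,
            individuals_per_species[2] >= individuals_per_species[1],
            length(markers) >= 1, !is.null(names(markers)),
            all(markers >= 10),
            interspecific_divergence >= 0, interspecific_divergence <= 0.75,
            intraspecific_divergence >= 0, intraspecific_divergence <= 0.75,
            species_per_genus >= 1)
  for (p in shared_genotype_pairs) {
    stopifnot(length(p) == 2, all(p >= 1), all(p <= n_species), p[1] != p[2])
  }
  for (h in homopolymer_insertions) {
    stopifnot(h$marker %in% names(markers), h$length >= 1,
              h$length <= markers[[h$marker]],
              h$base %in% c("A", "C", "G", "T"))
  }
  structure(list(n_species = n_species,
                 individuals_per_species = individuals_per_species,
                 markers = markers,
                 interspecific_divergence = interspecific_divergence,
                 intraspecific_divergence = intraspecific_divergence,
                 shared_genotype_pairs = shared_genotype_pairs,
                 homopolymer_insertions = homopolymer_insertions,
                 quality_profile = quality_profile,
                 species_per_genus = species_per_genus,
                 seed = seed),
            class = "synthetic_config")
}

# mutate `n_sub` uniformly chosen sites to a different uniformly chosen base
#' @noRd
mutate_sites <- function(chars, n_sub) {
  if (n_sub == 0L) return(chars)
  sites <- sample.int(length(chars), n_sub)
  for (s in sites) {
    chars[s] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1L)
  }
  chars
}

#' Generate a synthetic barcode library with known ground truth
#'
#' Species genotypes are derived from a common ancestral sequence per marker
#' by uniform random substitutions (distances downstream are uncorrected
#' p-distances, so no more refined substitution model is needed);
#' individuals are derived from their species genotype the same way at the
#' intraspecific rate. Genotype sharing between configured species pairs is
#' implemented by copying the full marker sequences, which guarantees zero
#' distance. No indels are introduced, so the expected conflation sets and
#' barcode-gap flags in the returned truth are computable exactly from the
#' generated sequences.
#'
#' @param cfg a [synthetic_config()].
#' @return `list(library = barcode_library, truth = synthetic_truth)`. The
#'   truth carries the per-specimen records, per-marker genotype ids, and
#'   the configured sharing structure; feed it to
#'   [expected_discrimination()] and [expected_gap()] for analytic expected
#'   values.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    bases <- c("A", "C", "G", "T")
    markers <- cfg$markers
    n_sp <- cfg$n_species

    roots <- lapply(markers, function(L) sample(bases, L, replace = TRUE))
    for (h in cfg$homopolymer_insertions) {
      L <- markers[[h$marker]]
      start <- sample.int(L - h$length + 1L, 1L)
      roots[[h$marker]][start:(start + h$length - 1L)] <- h$base
    }

    # species genotypes: distinct per marker whenever divergence > 0
    genotypes <- list()
    for (m in names(markers)) {
      L <- markers[[m]]
      n_sub <- if (cfg$interspecific_divergence > 0) {
        max(1L, round(cfg$interspecific_divergence * L / 2))
      } else 0L
      gt <- character(n_sp)
      for (i in seq_len(n_sp)) {
        for (try in seq_len(100L)) {
          cand <- paste(mutate_sites(roots[[m]], n_sub), collapse = "")
          if (n_sub == 0L || !cand %in% gt[seq_len(i - 1L)]) break
          cand <- NA_character_
        }
        if (is.na(cand)) {
          stop("infeasible config: cannot draw ", n_sp,
               " distinct genotypes for marker ", m)
        }
        gt[i] <- cand
      }
      genotypes[[m]] <- gt
    }

    species <- sprintf("Species_%02d", seq_len(n_sp))
    genus <- sprintf("Genus_%02d",
                     ((seq_len(n_sp) - 1L) %/% cfg$species_per_genus) + 1L)
    shared_species <- unique(unlist(cfg$shared_genotype_pairs))

    rows <- list()
    for (i in seq_len(n_sp)) {
      n_ind <- sample(seq(cfg$individuals_per_species[1],
                          cfg$individuals_per_species[2]), 1L)
      for (j in seq_len(n_ind)) {
        id <- sprintf("%s_ind%d", species[i], j)
        seqs <- character(length(markers))
        names(seqs) <- names(markers)
        for (m in names(markers)) {
          base_gt <- genotypes[[m]][i]
          # anchor the first individual of species involved in sharing on
          # the exact species genotype so copied genotypes hit distance 0
          if (j == 1L && i %in% shared_species) {
            seqs[[m]] <- base_gt
          } else {
            chars <- strsplit(base_gt, "", fixed = TRUE)[[1L]]
            n_sub <- stats::rbinom(1L, length(chars),
                                   cfg$intraspecific_divergence)
            seqs[[m]] <- paste(mutate_sites(chars, n_sub), collapse = "")
          }
        }
        rows[[id]] <- data.frame(specimen_id = id, species = species[i],
                                 genus = genus[i], marker = names(markers),
                                 sequence = unname(seqs),
                                 stringsAsFactors = FALSE)
      }
    }
    rec <- do.call(rbind, rows)
    rownames(rec) <- NULL

    # forced multilocus genotype sharing: one individual of the second
    # species carries a full copy of the first species' genotype
    for (p in cfg$shared_genotype_pairs) {
      donor <- p[1]; receiver <- p[2]
      ids <- unique(rec$specimen_id[rec$species == species[receiver]])
      carrier <- ids[length(ids)]
      for (m in names(markers)) {
        rec$sequence[rec$specimen_id == carrier & rec$marker == m] <-
          genotypes[[m]][donor]
      }
    }

    lib <- barcode_library(rec, markers = names(markers))
    gt_ids <- do.call(rbind, lapply(names(markers), function(m) {
      r <- rec[rec$marker == m, , drop = FALSE]
      uniq <- unique(r$sequence)
      data.frame(specimen_id = r$specimen_id, species = r$species,
                 marker = m, genotype_id = match(r$sequence, uniq),
                 stringsAsFactors = FALSE)
    }))
    truth <- structure(list(records = rec, genotype_ids = gt_ids,
                            species = species,
                            shared_genotype_pairs = cfg$shared_genotype_pairs,
                            markers = names(markers), config = cfg),
                       class = "synthetic_truth")
    list(library = lib, truth = truth)
  })
}

#' Attach synthetic per-base qualities and coverage to a library
#'
#' Each position independently reaches QV 30 with probability
#' `quality_profile$frac_hq` (high-quality positions draw QV uniformly from
#' 30-60, the rest from 2-29); per-base coverage is drawn from
#' `quality_profile$coverage_probs`. Deterministic given the config seed.
#'
#' @param lib a [barcode_library()] without qualities.
#' @param cfg a [synthetic_config()].
#' @return The library with `qualities` and `coverage` filled in.
#' @export
inject_quality <- function(lib, cfg) {
  stopifnot(inherits(lib, "barcode_library"),
            inherits(cfg, "synthetic_config"))
  prof <- cfg$quality_profile
  if (prof$frac_hq < 0 || prof$frac_hq > 1 ||
      any(prof$coverage_probs < 0) || any(prof$coverage_probs > 1)) {
    stop("quality profile fractions must lie in [0, 1]")
  }
  cov_vals <- as.integer(names(prof$coverage_probs))
  with_seed(cfg$seed + 1L, {
    rec <- lib$records
    for (i in seq_len(nrow(rec))) {
      L <- nchar(rec$sequence[i])
      hq <- stats::runif(L) < prof$frac_hq
      qv <- integer(L)
      qv[hq] <- sample(30:60, sum(hq), replace = TRUE)
      qv[!hq] <- sample(2:29, sum(!hq), replace = TRUE)
      rec$qualities[[i]] <- qv
      # index-based draw: safe when a single coverage value is configured
      rec$coverage[[i]] <- cov_vals[sample.int(length(cov_vals), L,
                                               replace = TRUE,
                                               prob = prof$coverage_probs)]
    }
    lib$records <- rec
    lib
  })
}

#' Analytic expected discrimination from synthetic truth
#'
#' Independent oracle for reference-database discrimination, computed by
#' exhaustive set logic over the generated genotypes (no alignment): a query
#' returns the species owning a sequence identical to it (the query's own
#' record is in the reference, so the minimal distance is zero); marker
#' combinations intersect the per-marker sets; a species is diagnosable for
#' a marker set when every one of its specimens returns exactly that
#' species.
#'
#' @param truth a `synthetic_truth` from [generate_library()].
#' @param marker_sets list of character vectors of marker names; default:
#'   each single marker plus the full combination.
#' @return data.frame with `species`, `marker_set` (collapsed with `+`),
#'   `indicator` (`+`/`-`), and list-column `conflated` (other species
#'   returned, alphabetical).
#' @export
expected_discrimination <- function(truth, marker_sets = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rec <- truth$records
  if (is.null(marker_sets)) {
    marker_sets <- c(as.list(truth$markers), list(truth$markers))
  }
  # per marker: sequence string -> set of owning species
  owners <- lapply(stats::setNames(truth$markers, truth$markers),
                   function(m) {
    r <- rec[rec$marker == m, , drop = FALSE]
    lapply(split(r$species, r$sequence), unique)
  })
  specimens <- unique(rec[, c("specimen_id", "species")])
  out <- list()
  for (ms in marker_sets) {
    per_spec <- lapply(seq_len(nrow(specimens)), function(k) {
      id <- specimens$specimen_id[k]
      sets <- lapply(ms, function(m) {
        s <- rec$sequence[rec$specimen_id == id & rec$marker == m]
        owners[[m]][[s]]
      })
      Reduce(intersect, sets)
    })
    for (sp in sort(unique(specimens$species))) {
      idx <- which(specimens$species == sp)
      returned <- unique(unlist(per_spec[idx]))
      ok <- all(vapply(per_spec[idx],
                       function(r) identical(sort(r), sp), logical(1)))
      out[[length(out) + 1L]] <- data.frame(
        species = sp, marker_set = paste(ms, collapse = "+"),
        indicator = if (ok) "+" else "-", stringsAsFactors = FALSE)
      out[[length(out)]]$conflated <- I(list(sort(setdiff(returned, sp))))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# hamming-count p-distance pieces for equal-length sequences
#' @noRd
hamming_counts <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  stopifnot(length(ia) == length(ib))
  c(diffs = sum(ia != ib), cols = length(ia))
}

#' Analytic expected barcode-gap flags from synthetic truth
#'
#' Computes, without any alignment (the generator introduces no indels, so
#' p-distance reduces to normalised Hamming distance), each species' maximum
#' intraspecific and minimum interspecific distance, per marker set, and the
#' strict gap flag.
#'
#' @param truth a `synthetic_truth` from [generate_library()].
#' @param marker_sets list of character vectors; default: each single marker
#'   plus the full combination.
#' @return data.frame with `species`, `marker_set`, `max_intra`,
#'   `min_inter`, `gap` (logical).
#' @export
expected_gap <- function(truth, marker_sets = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rec <- truth$records
  if (is.null(marker_sets)) {
    marker_sets <- c(as.list(truth$markers), list(truth$markers))
  }
  specimens <- unique(rec[, c("specimen_id", "species")])
  n <- nrow(specimens)
  out <- list()
  for (ms in marker_sets) {
    seqs <- lapply(ms, function(m) {
      r <- rec[rec$marker == m, , drop = FALSE]
      stats::setNames(r$sequence, r$specimen_id)[specimens$specimen_id]
    })
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        cnt <- rowSums(vapply(seqs, function(s) {
          hamming_counts(s[[i]], s[[j]])
        }, numeric(2)))
        d[i, j] <- d[j, i] <- cnt[["diffs"]] / cnt[["cols"]]
      }
    }
    for (sp in sort(unique(specimens$species))) {
      idx <- which(specimens$species == sp)
      intra <- if (length(idx) > 1) max(d[idx, idx][upper.tri(d[idx, idx])])
               else 0
      inter <- if (length(idx) < n) min(d[idx, -idx, drop = FALSE]) else Inf
      out[[length(out) + 1L]] <- data.frame(
        species = sp, marker_set = paste(ms, collapse = "+"),
        max_intra = intra, min_inter = inter, gap = inter > intra,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
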