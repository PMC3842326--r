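test_that("build_reference registers distinct sequence types", {
  s <- strrep("ACGT", 30)
  lib <- toy_library(list(
    A = list(a1 = c(m1 = s), a2 = c(m1 = s)),
    B = list(b1 = c(m1 = s))))
  ref <- build_reference(lib)
  expect_equal(nrow(ref$registry$m1), 1L)
  expect_equal(ref$registry$m1$count, 3L)
  expect_equal(ref$registry$m1$species_set[[1]], c("A", "B"))
  expect_error(build_reference(barcode_library(
    data.frame(specimen_id = character(0), species = character(0),
               genus = character(0), marker = character(0),
               sequence = character(0)))), "empty")
})

test_that("queries return all species at minimal distance, ties included", {
  s <- strrep("GTCA", 30)
  libs <- toy_library(list(
    A = list(a1 = c(m1 = s)),
    B = list(b1 = c(m1 = sub_at(sub_at(s, 10, "A"), 20, "T")))))
  ref <- build_reference(libs)
  q <- query_reference(ref, s, "m1")
  expect_equal(q$species, "A")
  expect_equal(q$distance, 0)
  # genotype shared between two species
  lib2 <- toy_library(list(A = list(a1 = c(m1 = s)),
                           B = list(b1 = c(m1 = s))))
  q2 <- query_reference(build_reference(lib2), s, "m1")
  expect_equal(q2$species, c("A", "B"))
  # query equidistant (one substitution) from unique genotypes of A and B
  ga <- sub_at(s, 5, "A")   # position 5 is 'G' originally -> 'A'
  gb <- sub_at(s, 5, "C")
  lib3 <- toy_library(list(A = list(a1 = c(m1 = ga)),
                           B = list(b1 = c(m1 = gb))))
  q3 <- query_reference(build_reference(lib3), sub_at(s, 5, "T"), "m1")
  expect_equal(q3$species, c("A", "B"))
  expect_equal(q3$distance, 1 / 120)
  expect_error(query_reference(build_reference(lib3), s, "mX"), "unknown")
})

test_that("combine_queries intersects per-marker species sets", {
  qa <- structure(list(marker = "m1", species = c("A", "B"), distance = 0),
                  class = "query_result")
  qb <- structure(list(marker = "m2", species = c("A", "C"), distance = 0),
                  class = "query_result")
  cmb <- combine_queries(list(qa, qb))
  expect_equal(cmb$species, "A")
  expect_equal(cmb$marker, "m1+m2")
  expect_equal(combine_queries(list(qa, qa))$species, c("A", "B"))
  qc_ <- structure(list(marker = "m3", species = "D", distance = 0),
                   class = "query_result")
  expect_warning(combine_queries(list(qa, qc_)), "empty intersection")
})

test_that("single-marker failures can combine into a diagnosable species", {
  # the focal species shares each marker with a different neighbour, so all
  # single markers fail but the intersection isolates it
  m1 <- strrep("ACGT", 40); m2 <- strrep("GGCA", 40); m3 <- strrep("TTAC", 40)
  u <- function(s, i) sub_at(s, i, if (substr(s, i, i) == "A") "G" else "A")
  lib <- toy_library(list(
    Focal = list(f1 = c(m1 = m1, m2 = m2, m3 = m3)),
    N1 = list(n1 = c(m1 = m1, m2 = u(m2, 11), m3 = u(m3, 12))),
    N2 = list(n2 = c(m1 = u(m1, 13), m2 = m2, m3 = u(m3, 14))),
    N3 = list(n3 = c(m1 = u(m1, 15), m2 = u(m2, 16), m3 = m3))))
  ref <- build_reference(lib)
  disc <- species_discrimination(lib, ref)
  rows <- disc$rows[disc$rows$species == "Focal", ]
  expect_equal(rows$indicator[rows$marker_set == "m1"], "-")
  expect_equal(rows$indicator[rows$marker_set == "m2"], "-")
  expect_equal(rows$indicator[rows$marker_set == "m3"], "-")
  expect_equal(rows$indicator[rows$marker_set == "m1+m2+m3"], "+")
})

test_that("discrimination summary and conflation ordering are correct", {
  s <- strrep("CAGT", 35)
  lib <- toy_library(list(
    A = list(a1 = c(m1 = s), a2 = c(m1 = s)),
    B = list(b1 = c(m1 = s)),
    C = list(c1 = c(m1 = sub_at(s, 9, "T")))))
  ref <- build_reference(lib)
  disc <- species_discrimination(lib, ref, marker_sets = list("m1"))
  rows <- disc$rows
  expect_equal(rows$indicator[rows$species == "C"], "+")
  # A fails twice against B (two specimens), B once against A
  expect_equal(rows$conflated[rows$species == "A"][[1]], "B")
  expect_equal(rows$conflated[rows$species == "B"][[1]], "A")
  expect_equal(disc$summary$k, 1L)
  expect_equal(disc$summary$percent, 100 / 3, tolerance = 1e-12)
  expect_equal(disc$summary$conflated_mean, 1)
})

test_that("all genotypes unique gives 100% discrimination", {
  cfg <- synthetic_config(n_species = 6, intraspecific_divergence = 0,
                          markers = c(m1 = 150, m2 = 120), seed = 17)
  gen <- generate_library(cfg)
  disc <- species_discrimination(gen$library, build_reference(gen$library))
  expect_true(all(disc$rows$indicator == "+"))
  expect_true(all(disc$summary$percent == 100))
})

test_that("leave-one-out mode removes the query's own records", {
  s <- strrep("ATCG", 35)
  # A's two specimens share the genotype; B's singleton is unique
  lib <- toy_library(list(
    A = list(a1 = c(m1 = s), a2 = c(m1 = s)),
    B = list(b1 = c(m1 = sub_at(s, 40, "C")))))
  ref <- build_reference(lib)
  with_self <- species_discrimination(lib, ref, marker_sets = list("m1"))
  loo <- species_discrimination(lib, ref, marker_sets = list("m1"),
                                leave_one_out = TRUE)
  # with self-matching both are clean; under LOO b1's nearest is A
  expect_equal(with_self$rows$indicator, c("+", "+"))
  expect_equal(loo$rows$indicator[loo$rows$species == "A"], "+")
  expect_equal(loo$rows$indicator[loo$rows$species == "B"], "-")
})

test_that("marker synergy is monotone on a mixed synthetic library", {
  cfg <- synthetic_config(n_species = 8, individuals_per_species = c(1, 3),
                          intraspecific_divergence = 0.004,
                          shared_genotype_pairs = list(c(2, 5)),
                          markers = c(m1 = 150, m2 = 120, m3 = 100),
                          seed = 23)
  gen <- generate_library(cfg)
  disc <- species_discrimination(gen$library, build_reference(gen$library))
  ind <- function(sp, set) {
    disc$rows$indicator[disc$rows$species == sp &
                          disc$rows$marker_set == set]
  }
  sets <- list(c("m1"), c("m2"), c("m3"), c("m1", "m2"), c("m1", "m3"),
               c("m2", "m3"), c("m1", "m2", "m3"))
  for (sp in unique(disc$rows$species)) {
    for (s1 in sets) for (s2 in sets) {
      if (all(s1 %in% s2)) {
        lab1 <- paste(s1, collapse = "+"); lab2 <- paste(s2, collapse = "+")
        expect_true(!(ind(sp, lab1) == "+" && ind(sp, lab2) == "-"))
      }
    }
  }
})

test_that("least inclusive clade scores monophyly and singletons", {
  map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  r <- least_inclusive_clade(read_tree("((a1,a2),(b1,b2));"), map)
  expect_equal(r$indicator, c("+", "+"))
  r <- least_inclusive_clade(read_tree("((a1,b1),(a2,b2));"), map)
  expect_equal(r$indicator, c("-", "-"))
  r <- least_inclusive_clade(read_tree("(((a1,a2),b1),b2);"), map)
  expect_equal(r$indicator[r$species == "A"], "+")
  expect_equal(r$indicator[r$species == "B"], "-")
  # singleton species are not applicable
  map2 <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  r <- least_inclusive_clade(read_tree("(((a1,a2),b1),c1);"), map2)
  expect_true(is.na(r$indicator[r$species == "B"]))
  expect_equal(r$indicator[r$species == "A"], "+")
  expect_error(least_inclusive_clade(read_tree("((a1,zz),(a2,b2));"), map),
               "zz")
})

test_that("least inclusive clade agrees with monophyly testing", {
  set.seed(31)
  for (k in 1:10) {
    tips <- paste0("t", 1:8)
    tr <- ape::rtree(8, tip.label = sample(tips))
    map <- setNames(rep(c("A", "B"), each = 4), tips)
    r <- least_inclusive_clade(tr, map)
    for (sp in c("A", "B")) {
      expect_equal(r$indicator[r$species == sp] == "+",
                   ape::is.monophyletic(tr, names(map)[map == sp]))
    }
  }
})
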