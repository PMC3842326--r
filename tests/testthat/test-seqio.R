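test_that("barcode_library enforces record invariants", {
  rec <- data.frame(specimen_id = c("s1", "s1"), species = "Sp a",
                    genus = "G", marker = c("m1", "m2"),
                    sequence = c("ACGT", "ACGTN"), stringsAsFactors = FALSE)
  lib <- barcode_library(rec)
  expect_s3_class(lib, "barcode_library")
  expect_equal(lib$markers, c("m1", "m2"))
  expect_equal(n_per_species(lib), c("Sp a" = 1L))

  expect_error(barcode_library(rbind(rec, rec[1, ])), "duplicate")
  bad <- rec; bad$sequence[1] <- "AC-GT"
  expect_error(barcode_library(bad), "non-IUPAC")
  bad <- rec; bad$species <- ""
  expect_error(barcode_library(bad), "species")
  bad <- rec
  bad$qualities <- I(list(c(30, 30), NULL))
  expect_error(barcode_library(bad), "length mismatch")
})

test_that("read_library resolves FASTA against metadata and reports counts", {
  dir <- withr::local_tempdir()
  writeLines(c(">s1 extra tokens", "acgt", ">s2", "--GGTT--"),
             file.path(dir, "m1.fasta"))
  writeLines(c(">s1", "TTTT", ">s3", "CCCC"), file.path(dir, "m2.fasta"))
  writeLines(c("specimen_id\tspecies\tgenus\taccession_m1",
               "s1\tSp a\tG\tAB1", "s2\tSp b\tG\tAB2", "s3\tSp b\tG\t"),
             file.path(dir, "meta.tsv"))
  lib <- read_library(c(m1 = file.path(dir, "m1.fasta"),
                        m2 = file.path(dir, "m2.fasta")),
                      file.path(dir, "meta.tsv"))
  expect_equal(nrow(lib$records), 4L)
  expect_equal(attr(lib, "per_marker_counts"), c(m1 = 2L, m2 = 2L))
  # upper-cased, terminal gaps stripped
  expect_equal(lib$records$sequence[lib$records$specimen_id == "s1" &
                                      lib$records$marker == "m1"], "ACGT")
  expect_equal(lib$records$sequence[lib$records$specimen_id == "s2" &
                                      lib$records$marker == "m1"], "GGTT")
  expect_equal(lib$records$accession[lib$records$specimen_id == "s2" &
                                       lib$records$marker == "m1"], "AB2")

  writeLines(c(">ghost", "ACGT"), file.path(dir, "m3.fasta"))
  expect_error(read_library(c(m3 = file.path(dir, "m3.fasta")),
                            file.path(dir, "meta.tsv")), "ghost")
  expect_error(read_library(c(mx = file.path(dir, "nope.fasta")),
                            file.path(dir, "meta.tsv")), "not found")
})

test_that("exclude column drops flagged specimens", {
  dir <- withr::local_tempdir()
  writeLines(c(">s1", "ACGT", ">s2", "ACGG"), file.path(dir, "m1.fasta"))
  writeLines(c("specimen_id\tspecies\tgenus\texclude",
               "s1\tSp a\tG\t0", "s2\tSp b\tG\t1"),
             file.path(dir, "meta.tsv"))
  expect_error(read_library(c(m1 = file.path(dir, "m1.fasta")),
                            file.path(dir, "meta.tsv")), "s2")
})

test_that("write_library / read_library round-trips exactly", {
  gen <- generate_library(synthetic_config(n_species = 4, seed = 11,
                                           markers = c(m1 = 60, m2 = 40)))
  dir <- withr::local_tempdir()
  paths <- write_library(gen$library, dir)
  lib2 <- read_library(paths[c("m1", "m2")], paths[["metadata"]])
  cols <- c("specimen_id", "species", "genus", "marker", "sequence")
  norm <- function(lib) {
    r <- lib$records[, cols]
    r <- r[order(r$marker, r$specimen_id), ]
    rownames(r) <- NULL
    r
  }
  expect_equal(norm(lib2), norm(gen$library))
})

test_that("select_complete_samples keeps exactly fully sequenced specimens", {
  lib <- toy_library(list(
    A = list(a1 = c(m1 = "ACGT", m2 = "GGCC"),
             a2 = c(m1 = "ACGT")),
    B = list(b1 = c(m1 = "TTTT", m2 = "AACC"))))
  cs <- select_complete_samples(lib, c("m1", "m2"))
  expect_setequal(unique(cs$records$specimen_id), c("a1", "b1"))
  # species with no remaining specimens disappear from the index
  lib2 <- toy_library(list(A = list(a2 = c(m1 = "ACGT")),
                           B = list(b1 = c(m1 = "TTTT", m2 = "AACC"))))
  cs2 <- select_complete_samples(lib2, c("m1", "m2"))
  expect_equal(names(species_index(cs2)), "B")
  expect_error(select_complete_samples(lib, "mX"), "unknown marker")
})

test_that("select_complete_samples is idempotent and monotone", {
  gen <- generate_library(synthetic_config(n_species = 6, seed = 5,
                                           markers = c(m1 = 50, m2 = 50)))
  lib <- gen$library
  # knock out one marker for some specimens
  drop <- lib$records$specimen_id %in%
    unique(lib$records$specimen_id)[c(2, 5)] & lib$records$marker == "m2"
  partial <- barcode_library(lib$records[!drop, ], markers = lib$markers)
  once <- select_complete_samples(partial)
  twice <- select_complete_samples(once)
  expect_equal(once$records, twice$records)
  # adding a specimen's missing marker back never removes retained specimens
  restored <- barcode_library(lib$records[!drop | lib$records$specimen_id !=
    unique(lib$records$specimen_id)[2], ], markers = lib$markers)
  again <- select_complete_samples(restored)
  expect_true(all(unique(once$records$specimen_id) %in%
                    unique(again$records$specimen_id)))
})

test_that("packaged results fixture has the published structure", {
  tab <- load_results_fixture()
  expect_equal(nrow(tab), 97L)
  expect_equal(sum(tab$n), 159L)
  expect_equal(sum(tab$combined == "+"), 55L)
  expect_equal(sum(tab$gap == 1), 49L)
  r <- tab[tab$species == "Ac. sahniana", ]
  expect_equal(r$n, 3L)
  expect_true(all(r[, c("matK", "rbcL", "nrITS2", "combined")] == "+"))
  expect_equal(r$gap, 1L)
  r <- tab[tab$species == "Af. dawei", ]
  expect_equal(r$n, 1L)
  expect_true(all(r[, c("matK", "rbcL", "nrITS2", "combined")] == "-"))
  expect_equal(r$gap, 0L)
})

test_that("read_tree parses Newick and validates leaves", {
  tr <- read_tree("((a,b),(c,d));")
  expect_equal(ape::Ntip(tr), 4L)
  expect_error(read_tree("((a,b);"), "malformed")
  lib <- toy_library(list(A = list(a = c(m1 = "ACGT")),
                          B = list(b = c(m1 = "AGGT"))))
  expect_error(read_tree("((a,b),(c,d));", lib), "c, d")
  expect_s3_class(read_tree("(a,b);", lib), "phylo")
})
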