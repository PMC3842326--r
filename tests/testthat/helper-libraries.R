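# small hand-built libraries used across test files

# build a barcode_library from a compact spec:
#   specs = list(species_name = list(specimen_id = c(marker = sequence, ...)))
toy_library <- function(specs, genus = "Genus") {
  rows <- list()
  for (sp in names(specs)) {
    for (id in names(specs[[sp]])) {
      seqs <- specs[[sp]][[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = id, species = sp, genus = genus,
        marker = names(seqs), sequence = unname(seqs),
        stringsAsFactors = FALSE)
    }
  }
  barcode_library(do.call(rbind, rows))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# substitute one base at position `pos`
sub_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}
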