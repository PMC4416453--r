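# Independent oracles and shared grids for the property tests.

# brute-force tail of the crown size law: P(N >= n | both founders survive)
# summed directly from the convolution mass P(N = k) = (k-1)(1-beta)^2 beta^(k-2)
brute_crown_tail <- function(n, beta, upto = 20000L) {
  k <- seq.int(n, upto)
  sum((k - 1) * (1 - beta)^2 * beta^(k - 2))
}

# grids shared by the round-trip and continuity properties
grid_n <- c(2.01, 3, 10, 100, 1000)
grid_t <- c(1, 5, 17.4, 47.3)
grid_eps <- c(0, 0.5, 0.9)

# tiny hand-checkable chronogram used across the tree tests
balanced_newick <- "((A:3,B:3):7,(C:5,D:5):5);"

# write a minimal lineage-table TSV for error-path tests
write_lineage_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- paste(c("row_id", "parent_id", "kind", "lineage", "name", "level",
                    "split_type", "age_ma", "crown_age_ma", "stem_age_ma",
                    "n_species", "source_note"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}
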