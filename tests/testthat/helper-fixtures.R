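# Small in-code fixtures shared across test files.

# A tiny deterministic enzyme table with known acquisition sums.
tiny_enzymes <- function() {
  tibble::tibble(
    sample_id = c("a", "b", "c"),
    bg = c(2, 1, 0.5), cbh = c(1, 0, 0.5),
    nag = c(0.5, 1, 1), lap = c(0.5, 0, 1),
    ap = c(3, 1, 2)
  )
}

# Small community: 4 samples x 5 taxa with hand-set counts.
tiny_community <- function() {
  counts <- matrix(
    c(5, 5, 5, 5, 0,
      1, 2, 3, 0, 0,
      3, 2, 1, 0, 0,
      0, 0, 0, 7, 0),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("s", 1:4), paste0("t", 1:5))
  )
  community_table(counts, tibble::tibble(
    taxon_id = paste0("t", 1:5),
    phylum = c("A", "A", "B", "B", "C")
  ))
}

# Small cohort config for fast end-to-end runs.
test_config <- function(seed = 101, n_sxk = 10, n_lxk = 20,
                        community = list(), enzyme = list()) {
  small <- list(
    bacteria = list(otus_per_phylum = 8, read_depth = 800),
    fungi = list(otus_per_phylum = 6, read_depth = 600)
  )
  cohort_config(
    seed = seed, n_sxk = n_sxk, n_lxk = n_lxk,
    community = utils::modifyList(small, community),
    enzyme = enzyme
  )
}
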