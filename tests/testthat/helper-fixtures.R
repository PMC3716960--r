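# Paths to the bundled study fixtures
fixture_counts <- function() scquant_example("two_group_spectral_counts.tsv")
fixture_ids_pos <- function() scquant_example("ros_pos_identifications.tsv")
fixture_ids_neg <- function() scquant_example("ros_neg_identifications.tsv")
fixture_synonyms <- function() scquant_example("accession_synonyms.tsv")
fixture_go_map <- function() scquant_example("synthetic_go_cc_map.tsv")
fixture_go_terms <- function() scquant_example("synthetic_go_terms.tsv")

# Raw fixture read without package readers (independent of the code under test)
raw_fixture <- function() {
  utils::read.delim(fixture_counts(), colClasses = "character")
}

# Small in-memory count table
toy_counts <- function(sc_a, sc_b, accession = paste0("P", seq_along(sc_a))) {
  quant_table(tibble::tibble(accession = accession, sc_a = sc_a, sc_b = sc_b))
}

# Exhaustive hypergeometric upper-tail oracle: probability that a uniform
# n-subset of a population of size N (with K annotated members) contains
# at least k annotated members, by enumeration of all subsets.
enum_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K) # members 1..K are the annotated ones
  mean(hits >= k)
}

# The published differential sets of the bundled study dataset
over_symbols <- c(
  "HIST1H2BA", "MDH2", "HSP90B1", "HSPA5", "GLUL",
  "TGM4", "GPX4", "SPACA4", "OLFM4", "C20orf3"
)
under_symbols <- c("SEMG2", "PRDX6", "CLTC", "EEF2", "ENO1")
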