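test_that("roll-up percentages are shares of annotation assignments", {
  map <- tibble::tibble(
    accession = c("p1", "p2", "p3"),
    go_id = c("T1", "T1", "T2")
  )
  d <- rollup_distribution(c("p1", "p2", "p3"), map)
  expect_equal(d$n_proteins[d$go_id == "T1"], 2L)
  expect_equal(d$percent[d$go_id == "T1"], 100 * 2 / 3)
  expect_equal(d$percent[d$go_id == "T2"], 100 * 1 / 3)
  expect_equal(sum(d$percent, na.rm = TRUE), 100, tolerance = 1e-9)

  expect_equal(nrow(rollup_distribution(character(), map)), 0)

  # unannotated proteins surface in their own bucket, outside the base
  d2 <- rollup_distribution(c("p1", "p4"), map)
  expect_equal(d2$n_proteins[d2$go_id == "unannotated"], 1L)
  expect_true(is.na(d2$percent[d2$go_id == "unannotated"]))
  expect_equal(sum(d2$percent, na.rm = TRUE), 100, tolerance = 1e-9)
})

test_that("the synthetic cellular-component map reproduces its constructed shares", {
  map <- read_annotation_tsv(fixture_go_map())
  terms <- read_term_names(fixture_go_terms())
  d <- rollup_distribution(unique(map$accession), map, term_names = terms)
  expect_equal(nrow(map), 18) # total assignments by construction
  intra <- d[d$term_name == "intracellular", ]
  expect_equal(intra$n_proteins, 4L)
  expect_equal(intra$percent, 100 * 4 / 18) # 22.2%
  expect_equal(sum(d$percent, na.rm = TRUE), 100, tolerance = 1e-9)
})

test_that("roll-up comparison flags terms exclusive to one protein set", {
  map <- tibble::tibble(accession = c("P1", "P2"), go_id = c("Ta", "Tb"))
  cmp <- compare_rollups("P1", "P2", map)
  expect_equal(cmp$status[cmp$go_id == "Ta"], "over_only")
  expect_equal(cmp$status[cmp$go_id == "Tb"], "under_only")
  expect_true(all(compare_rollups(c("P1", "P2"), c("P1", "P2"), map)$status == "shared"))

  # the packaged synthetic map was constructed so endosome, lipid
  # particle and microtubule carry only overexpressed study proteins and
  # the proteinaceous extracellular matrix only underexpressed ones
  d <- read_quant_table(fixture_counts()) |>
    quantify_nsc() |>
    classify_differential()
  over_acc <- d$accession[d$call == "over"]
  under_acc <- d$accession[d$call == "under"]
  go <- read_annotation_tsv(fixture_go_map())
  terms <- read_term_names(fixture_go_terms())
  cmp2 <- compare_rollups(over_acc, under_acc, go, term_names = terms)
  excl_over <- cmp2$term_name[cmp2$status == "over_only"]
  expect_true(all(c("endosome", "lipid particle", "microtubule") %in% excl_over))
  expect_equal(cmp2$term_name[cmp2$status == "under_only"], "proteinaceous extracellular matrix")
})

test_that("hypergeometric enrichment matches the exact tail sum", {
  # population of 20 with 5 annotated; study of 5 with 3 annotated
  map <- tibble::tibble(accession = paste0("g", 1:5), go_id = "T")
  pop <- paste0("g", 1:20)
  study <- c("g1", "g2", "g3", "g6", "g7")
  res <- enrich_terms(study, pop, map, correction = "none")
  expect_equal(res$k, 3L)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)

  # k = 0 never appears (untested terms are dropped); K = N is certain
  all_map <- tibble::tibble(accession = pop, go_id = "T")
  res2 <- enrich_terms(study, pop, all_map)
  expect_equal(res2$p_value, 1)

  expect_error(enrich_terms("zzz", pop, map), class = "scquant_error_validation")
})

test_that("enrichment agrees with exhaustive subset enumeration for small populations", {
  for (N in c(5, 8, 12)) {
    pop <- paste0("m", seq_len(N))
    for (K in c(1, ceiling(N / 2), N - 1)) {
      map <- tibble::tibble(accession = pop[seq_len(K)], go_id = "T")
      for (n in c(2, min(5, N - 1))) {
        study <- pop[seq_len(n)] # first n: k = min(n, K)
        res <- enrich_terms(study, pop, map, correction = "none")
        k <- res$k
        expect_equal(res$p_value, enum_hyper_tail(N, K, n, k), tolerance = 1e-12)
      }
    }
  }
})

test_that("p-values are label-invariant and BH values are rank-monotone", {
  set.seed(9)
  pop <- paste0("prot", 1:30)
  map <- tibble::tibble(
    accession = sample(pop, 60, replace = TRUE),
    go_id = sample(paste0("T", 1:6), 60, replace = TRUE)
  ) |> dplyr::distinct()
  study <- sample(pop, 10)
  res <- enrich_terms(study, pop, map)
  # relabel accessions consistently
  lut <- setNames(paste0("X", seq_along(pop)), pop)
  map2 <- dplyr::mutate(map, accession = unname(lut[accession]))
  res2 <- enrich_terms(unname(lut[study]), unname(lut[pop]), map2)
  expect_equal(res2$p_value, res$p_value)
  expect_true(all(diff(res$q_value) >= -1e-12)) # sorted by p, BH monotone
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("GAF 2.x files parse to an aspect-filtered annotation map", {
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("UniProtKB", "P001", "GENE1", "", "GO:0005737", "PMID:1", "IDA", "", "C",
      "name", "", "protein", "taxon:9606", "20130520", "UniProt", "", "",
      sep = "\t"
    ),
    paste("UniProtKB", "P002", "GENE2", "", "GO:0006096", "PMID:1", "IDA", "", "P",
      "name", "", "protein", "taxon:9606", "20130520", "UniProt", "", "",
      sep = "\t"
    )
  ), gaf)
  all <- read_gaf(gaf)
  expect_equal(nrow(all), 2)
  cc <- read_gaf(gaf, aspect = "C")
  expect_equal(cc$accession, "P001")
  expect_equal(cc$go_id, "GO:0005737")
})
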