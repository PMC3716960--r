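test_that("identification tables parse combined peptide/coverage cells", {
  ids <- read_identification_table(fixture_ids_pos())
  expect_equal(nrow(ids), 68)
  akap4 <- ids[ids$accession == "21493039", ]
  expect_equal(akap4$mw_kda, 94)
  expect_equal(akap4$pi, 6.7)
  expect_equal(akap4$peptide_count, 34L)
  expect_equal(akap4$coverage_pct, 54)
  expect_equal(akap4$mascot_score, 10988)
  h2ba <- ids[ids$accession == "24586679", ]
  expect_equal(h2ba$peptide_count, 1L)
  expect_equal(h2ba$coverage_pct, 11)
  # the other group's table has a no-space peptide cell ("11(24%)")
  neg <- read_identification_table(fixture_ids_neg())
  expect_equal(nrow(neg), 66)
  expect_equal(neg[neg$accession == "4506883", ]$peptide_count, 11L)
  expect_equal(neg[neg$accession == "4506883", ]$coverage_pct, 24)
})

test_that("identification reader validates structure and values", {
  header_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("protein_name\taccession\tmw_kda\tpi\tpeptides\tmascot_score", header_only)
  expect_equal(nrow(read_identification_table(header_only)), 0)

  missing_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_name\taccession\tmw_kda\tpi\tpeptides", "x\t1\t10\t7\t1 (5%)"), missing_col)
  expect_error(read_identification_table(missing_col),
    class = "scquant_error_config", regexp = "mascot_score"
  )

  bad_num <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_name\taccession\tmw_kda\tpi\tpeptides\tmascot_score",
    "x\t1\tten\t7\t1 (5%)\t100"
  ), bad_num)
  expect_error(read_identification_table(bad_num),
    class = "scquant_error_parse", regexp = "row 1"
  )

  # a dialect can remap column names
  renamed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_name\tNCBI\tmw_kda\tpi\tpeptides\tmascot_score",
    "x\t42\t10\t7\t3 (12%)\t100"
  ), renamed)
  ids <- read_identification_table(renamed, dialect = c(accession = "NCBI"))
  expect_equal(ids$accession, "42")
  expect_equal(ids$peptide_count, 3L)
})

test_that("quant table reader recomputes totals and ignores printed derived columns", {
  q <- read_quant_table(fixture_counts())
  expect_s3_class(q, "quant_tbl")
  expect_equal(nrow(q), 74)
  expect_equal(unname(group_totals(q)), c(3434L, 3173L))
  # exclusivity cells in the ratio column are tolerated, counts win
  acta1 <- q[q$gene_symbol == "ACTA1", ]
  expect_equal(acta1$sc_a, 0L)
  expect_equal(acta1$sc_b, 8L)

  toy <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tsc_a\tsc_b", "p\t1\t1", "q\t1\t1"), toy)
  expect_equal(unname(group_totals(read_quant_table(toy))), c(2L, 2L))
})

test_that("quant tables reject duplicate accessions and negative counts", {
  expect_error(
    quant_table(tibble::tibble(accession = c("a", "a"), sc_a = 1:2, sc_b = 1:2)),
    class = "scquant_error_validation", regexp = "Duplicate"
  )
  expect_error(
    quant_table(tibble::tibble(accession = "a", sc_a = -1, sc_b = 0)),
    class = "scquant_error_validation", regexp = "Negative"
  )
})

test_that("write/read round-trip preserves counts and accessions exactly", {
  q <- read_quant_table(fixture_counts())
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(q, tmp)
  q2 <- read_quant_table(tmp)
  expect_identical(q2$accession, q$accession)
  expect_identical(q2$sc_a, q$sc_a)
  expect_identical(q2$sc_b, q$sc_b)
  expect_identical(q2$gene_symbol, q$gene_symbol)
})

test_that("ROS classification uses a strict threshold and is monotone", {
  expect_equal(classify_ros(2236), "ROS+")
  expect_equal(classify_ros(4), "ROS-")
  expect_equal(classify_ros(20), "ROS-") # boundary stays negative
  expect_error(classify_ros(-1), class = "scquant_error_validation")

  readings <- sort(runif(50, 0, 100))
  labels <- classify_ros(readings)
  # once positive, always positive as readings increase
  expect_true(all(diff(labels == "ROS+") >= 0))

  df <- assign_ros_groups(tibble::tibble(sample_id = c("s1", "s2"), ros_rlu = c(5, 50)))
  expect_equal(df$group, c("ROS-", "ROS+"))
})

test_that("group consolidation applies synonym maps and set algebra", {
  res <- consolidate_groups(c("x", "y"), c("y", "z"))
  expect_equal(res$status[match(c("x", "y", "z"), res$accession)], c("a_only", "shared", "b_only"))
  same <- consolidate_groups(c("x", "y"), c("y", "x"))
  expect_true(all(same$status == "shared"))

  cyc <- tibble::tibble(alias = c("a", "b"), canonical = c("b", "a"))
  expect_error(resolve_synonyms("a", cyc), class = "scquant_error_config")

  chain <- tibble::tibble(alias = c("a", "b"), canonical = c("b", "c"))
  expect_equal(resolve_synonyms(c("a", "b", "z"), chain), c("c", "c", "z"))
})

test_that("the two bundled identification tables consolidate onto the quant table", {
  syn <- read_synonym_map(fixture_synonyms())
  pos <- read_identification_table(fixture_ids_pos())
  neg <- read_identification_table(fixture_ids_neg())
  res <- consolidate_groups(neg, pos, synonym_map = syn) # A = ROS-, B = ROS+
  expect_equal(nrow(res), 76)
  quant_acc <- read_quant_table(fixture_counts())$accession
  # the quant table adds one protein reported in neither source table
  expect_setequal(setdiff(quant_acc, res$accession), "4502173")
  # and omits three identification-only proteins
  expect_setequal(
    setdiff(res$accession, quant_acc),
    c("57013276", "57863259", "153791352")
  )
})
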