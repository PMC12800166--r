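test_that("AIRR rows map to records with gene-level calls", {
  path <- write_airr_fixture(data.frame(
    v_call = c("TRBV19*01", "TRBV5-1*02,TRBV5-4*01", "TRBV9"),
    junction_aa = c("CASSIRSSYEQYF", "CASSLGQF", "CASSPF"),
    duplicate_count = c(3, 0, NA),
    productive = c("T", "F", "T"),
    stringsAsFactors = FALSE
  ))
  rec <- read_repertoire(path, "airr")
  expect_equal(rec$v_gene, c("TRBV19", "TRBV5-1", "TRBV9"))
  expect_equal(rec$count, c(3L, 1L, 1L))  # 0 and missing counts become 1
  expect_equal(rec$productive, c(TRUE, FALSE, TRUE))
})

test_that("a header-only file yields an empty record set", {
  path <- write_airr_fixture(data.frame(
    v_call = character(0), junction_aa = character(0),
    duplicate_count = numeric(0), productive = character(0),
    stringsAsFactors = FALSE
  ))
  expect_equal(nrow(read_repertoire(path, "airr")), 0L)
})

test_that("a missing mandatory column is reported by name", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(v_call = "TRBV19", junction_aa = "CASSF", productive = "T"),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_repertoire(path, "airr"), "duplicate_count")
})

test_that("rows with missing V/J/CDR3 are skipped with a warning", {
  path <- write_airr_fixture(data.frame(
    v_call = c("TRBV19*01", ""),
    junction_aa = c("CASSF", "CASSGF"),
    duplicate_count = c(1, 1), productive = c("T", "T"),
    stringsAsFactors = FALSE
  ))
  expect_warning(rec <- read_repertoire(path, "airr"), "skipped")
  expect_equal(nrow(rec), 1L)
})

test_that("the ImmunoSEQ dialect honours a column map", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(
    vMax = c("TCRBV19-01*01", "TCRBV09"),
    jMax = c("TCRBJ02-01*01", "TCRBJ02-01"),
    aminoAcid = c("CASSIRSSYEQYF", "CASS*F"),
    templates = c(5, 2),
    frame_type = c("In", "Stop"),
    stringsAsFactors = FALSE
  ), path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_repertoire(path, "immunoseq", colmap = immunoseq_colmap(
    v_gene = "vMax", j_gene = "jMax", cdr3_aa = "aminoAcid",
    count = "templates", productive = "frame_type"))
  expect_equal(rec$count, c(5L, 2L))
  expect_equal(rec$productive, c(TRUE, FALSE))

  # the same map via an on-disk key: value file
  cmf <- tempfile()
  writeLines(c("v_gene: vMax", "j_gene: jMax", "cdr3_aa: aminoAcid",
               "count: templates", "productive: frame_type"), cmf)
  expect_equal(read_repertoire(path, "immunoseq", colmap = cmf), rec)
})

test_that("productivity filtering removes stops, non-canonicals and flags", {
  rec <- rearrangement_records(
    v_call = rep("TRBV19", 5), j_call = rep("TRBJ2-1", 5),
    cdr3_aa = c("CASS*EQYF", "CASSEQYF", "CASSEQYF", "CASSXQYF", ""),
    productive = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  kept <- filter_productive(rec)
  expect_equal(kept$cdr3_aa, "CASSEQYF")
  expect_true(all(kept$productive))
})

test_that("collapsing merges synonymous rearrangements and sums counts", {
  rec <- rearrangement_records(
    v_call = c("TRBV19", "TRBV19", "TRBV19"),
    j_call = c("TRBJ2-1", "TRBJ2-1", "TRBJ2-7"),
    cdr3_aa = c("CASSIRSSYEQYF", "CASSIRSSYEQYF", "CASSIRSSYEQYF"),
    count = c(2, 5, 1), productive = TRUE)
  rep <- collapse_repertoire(rec, "s1")
  expect_equal(rep$depth, 2L)
  merged <- rep$clonotypes[rep$clonotypes$j_gene == "TRBJ2-1", ]
  expect_equal(merged$expansion, 7L)
  # conservation: total expansion equals total input count
  expect_equal(sum(rep$clonotypes$expansion), sum(rec$count))
  # row-order invariance
  rep2 <- collapse_repertoire(rec[c(3, 1, 2), ], "s1")
  expect_equal(rep2$clonotypes, rep$clonotypes)
  # binary mode records presence only
  repb <- collapse_repertoire(rec, "s1", expansion_mode = "binary")
  expect_equal(repb$clonotypes$expansion, c(1L, 1L))
})

test_that("collapsing zero records flags an empty repertoire", {
  rec <- rearrangement_records(character(0), character(0), character(0))
  expect_warning(rep <- collapse_repertoire(rec, "empty"), "depth 0")
  expect_equal(rep$depth, 0L)
})

test_that("depth never exceeds the number of input records", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    rec <- rearrangement_records(
      v_call = sample(c("TRBV19", "TRBV9"), n, TRUE),
      j_call = "TRBJ2-1",
      cdr3_aa = sample(c("CASSAF", "CASSGF", "CASSLF"), n, TRUE),
      count = sample(1:5, n, TRUE), productive = TRUE)
    expect_lte(collapse_repertoire(rec)$depth, n)
  }
})

test_that("AIRR writing round-trips through the reader", {
  rep <- make_repertoire("rt", "TRBV19", "TRBJ2-1",
                         c("CASSAF", "CASSGF"), expansion = c(4L, 2L))
  path <- tempfile(fileext = ".tsv")
  write_repertoire_airr(rep, path)
  back <- collapse_repertoire(filter_productive(read_repertoire(path, "airr")),
                              "rt")
  expect_equal(back$clonotypes, rep$clonotypes)
})
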