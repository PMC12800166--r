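cl <- function(v, j, cdr3) list(v_gene = v, j_gene = j, cdr3_aa = cdr3)

test_that("similarity edges require same V/J and CDR3 Hamming <= 1", {
  expect_true(similarity_edge(cl("TRBV19", "TRBJ2-1", "CASSLG"),
                              cl("TRBV19", "TRBJ2-1", "CASSFG")))
  expect_true(similarity_edge(cl("TRBV19", "TRBJ2-1", "CASSLG"),
                              cl("TRBV19", "TRBJ2-1", "CASSLG")))
  # unequal CDR3 lengths: Hamming undefined, no edge
  expect_false(similarity_edge(cl("TRBV19", "TRBJ2-1", "CASSLGPDTQYF"),
                               cl("TRBV19", "TRBJ2-1", "CASSLGPPDTQYF")))
  # same CDR3, different V gene
  expect_false(similarity_edge(cl("TRBV19", "TRBJ2-1", "CASSLG"),
                               cl("TRBV9", "TRBJ2-1", "CASSLG")))
  expect_false(similarity_edge(cl("TRBV19", "TRBJ2-1", "CASSLG"),
                               cl("TRBV19", "TRBJ2-7", "CASSLG")))
  # two substitutions
  expect_false(similarity_edge(cl("TRBV19", "TRBJ2-1", "CASSLG"),
                               cl("TRBV19", "TRBJ2-1", "CATTLG")))
  # symmetry
  a <- cl("TRBV19", "TRBJ2-1", "CASSAG"); b <- cl("TRBV19", "TRBJ2-1", "CASSAF")
  expect_equal(similarity_edge(a, b), similarity_edge(b, a))
})

test_that("a clique of similar clonotypes plus its unit is one component", {
  asg <- data.frame(
    v_gene = "TRBV19", j_gene = "TRBJ2-1",
    cdr3_aa = c("CASSLGF", "CASSLGY", "CASSLGW"),
    unit = "A*02:01", stringsAsFactors = FALSE)
  g <- build_clonotype_graph(asg)
  expect_equal(max(g$components), 1L)
  expect_length(g$components, 4L)
  expect_setequal(unique(g$edges$type), c("similarity", "restriction"))
})

test_that("without edges every node is its own component", {
  asg <- data.frame(
    v_gene = c("TRBV19", "TRBV9"), j_gene = "TRBJ2-1",
    cdr3_aa = c("CASSAAAAF", "CASSWWWWF"),
    unit = c("A*02:01", "B*08:01"), stringsAsFactors = FALSE)
  g <- build_clonotype_graph(asg)
  sim <- g$edges[g$edges$type == "similarity", ]
  expect_equal(nrow(sim), 0L)
  expect_equal(max(g$components), 2L)  # each clonotype-unit pair
})

test_that("bucketed edge finding equals the brute-force pairwise scan", {
  set.seed(53)
  n <- 200
  base <- c("CASSLGQDTQYF", "CASSPGQGAYEQYF", "CASSFSTCSANYGYTF")
  cdr3 <- vapply(seq_len(n), function(i) {
    s <- strsplit(sample(base, 1), "")[[1]]
    k <- sample(0:2, 1)
    if (k > 0) {
      pos <- sample(seq_along(s), k)
      s[pos] <- sample(aa_alphabet(), k, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  asg <- data.frame(
    v_gene = sample(c("TRBV19", "TRBV9"), n, TRUE),
    j_gene = sample(c("TRBJ2-1", "TRBJ2-7"), n, TRUE),
    cdr3_aa = cdr3, unit = "A*02:01", stringsAsFactors = FALSE)
  asg <- asg[!duplicated(clonotype_key(asg$v_gene, asg$j_gene, asg$cdr3_aa)), ]
  g <- build_clonotype_graph(asg)
  got <- g$edges[g$edges$type == "similarity", c("from", "to")]
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b))
  brute <- character(0)
  m <- nrow(asg)
  key <- clonotype_key(asg$v_gene, asg$j_gene, asg$cdr3_aa)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (similarity_edge(asg[i, ], asg[j, ])) {
      brute <- c(brute, canon(key[i], key[j]))
    }
  }
  expect_setequal(canon(got$from, got$to), brute)
  expect_gt(length(brute), 0)          # the case is non-trivial
  expect_false(any(got$from == got$to))  # no self-loops
})

test_that("annotation joins on CDR3 and deduplicates labels", {
  clono <- data.frame(v_gene = c("TRBV19", "TRBV9"), j_gene = "TRBJ2-1",
                      cdr3_aa = c("CASSIRSSYEQYF", "CASSNOVELF"),
                      stringsAsFactors = FALSE)
  tab <- data.frame(cdr3 = c("CASSIRSSYEQYF", "CASSIRSSYEQYF", "CASSIRSSYEQYF"),
                    antigen.species = c("CMV", "CMV", "EBV"),
                    stringsAsFactors = FALSE)
  ann <- annotate_clonotypes(clono, tab)
  expect_equal(ann$antigen, c("CMV;EBV", NA))
  # empty table annotates nothing
  ann0 <- annotate_clonotypes(clono, tab[0, ])
  expect_true(all(is.na(ann0$antigen)))
  # missing CDR3 column is a format error
  expect_error(annotate_clonotypes(clono, data.frame(x = 1)), "CDR3")
})

test_that("strict V/J annotation requires gene agreement", {
  clono <- data.frame(v_gene = "TRBV19", j_gene = "TRBJ2-1",
                      cdr3_aa = "CASSIRSSYEQYF", stringsAsFactors = FALSE)
  tab <- data.frame(v_gene = "TRBV9", j_gene = "TRBJ2-1",
                    cdr3_aa = "CASSIRSSYEQYF", antigen = "EBV",
                    stringsAsFactors = FALSE)
  expect_true(is.na(annotate_clonotypes(clono, tab, by = "vj_cdr3")$antigen))
  expect_equal(annotate_clonotypes(clono, tab, by = "cdr3")$antigen, "EBV")
})

test_that("edge lists export as from/to/type TSV", {
  asg <- data.frame(v_gene = "TRBV19", j_gene = "TRBJ2-1",
                    cdr3_aa = c("CASSLGF", "CASSLGY"),
                    unit = "A*02:01", stringsAsFactors = FALSE)
  g <- build_clonotype_graph(asg)
  path <- tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(names(back), c("from", "to", "type"))
  expect_equal(nrow(back), nrow(g$edges))
})
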