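# A cohort where one clonotype perfectly tracks carriership of A*02:01.
weight_cohort <- function(n = 40, expansion_in_carriers = 5L) {
  reps <- lapply(seq_len(n), function(i) {
    carrier <- i <= n / 2
    cdr3 <- c("CASSTRACKF"[carrier], sprintf("CASSP%02dF", i), "CASSCOMMONF")
    make_repertoire(sprintf("s%02d", i), "TRBV19", "TRBJ2-1",
                    cdr3[!is.na(cdr3)],
                    expansion = c(expansion_in_carriers[carrier],
                                  1L, 2L)[!is.na(cdr3)])
  })
  allot <- lapply(seq_len(n), function(i) {
    hla_allotype(sprintf("s%02d", i),
                 if (i <= n / 2) "A*02:01" else character(0), "A")
  })
  hla_cohort(reps, allot)
}

test_that("a perfectly informative clonotype earns a positive weight", {
  co <- weight_cohort()
  w <- fit_clonotype_weight(co, "TRBV19", "TRBJ2-1", "CASSTRACKF", "A*02:01")
  expect_gt(w$weight, 0)
  expect_gt(w$coefficients["expansion"], 0)
})

test_that("a clonotype with identical expansion everywhere gets weight 0", {
  co <- weight_cohort()
  w <- fit_clonotype_weight(co, "TRBV19", "TRBJ2-1", "CASSCOMMONF", "A*02:01")
  expect_identical(w$weight, 0)
  expect_identical(unname(w$scale["expansion"]), 0)
})

test_that("recovered weights rank with planted effect sizes", {
  # 50 clonotypes spanning a penetrance gradient in carriers of one unit,
  # on top of a carriership-independent background that dominates depth
  set.seed(77)
  n <- 160
  carrier <- rep(c(TRUE, FALSE), each = n / 2)
  pen <- seq(0.1, 0.95, length.out = 50)
  bg_pool <- unique(vapply(1:2000, function(i) {
    paste0("CASS", paste(sample(aa_alphabet(), 8, TRUE), collapse = ""), "F")
  }, character(1)))
  reps <- lapply(seq_len(n), function(i) {
    present <- runif(50) < (if (carrier[i]) pen else rep(0.02, 50))
    # per-sample assay depth swamps the planted clonotypes' depth footprint
    bg <- bg_pool[runif(length(bg_pool)) < runif(1, 0.3, 0.7)]
    cdr3 <- c(sprintf("CASSW%02dF", which(present)), bg,
              sprintf("CASSPRIV%03dF", i))
    make_repertoire(sprintf("s%03d", i), "TRBV19", "TRBJ2-1", cdr3)
  })
  allot <- lapply(seq_len(n), function(i) {
    hla_allotype(sprintf("s%03d", i),
                 if (carrier[i]) "A*02:01" else character(0), "A")
  })
  co <- hla_cohort(reps, allot)
  w <- vapply(seq_len(50), function(k) {
    fit_clonotype_weight(co, "TRBV19", "TRBJ2-1", sprintf("CASSW%02dF", k),
                         "A*02:01")$weight
  }, numeric(1))
  expect_gte(cor(w, pen, method = "spearman"), 0.8)
})

test_that("weighted expansion follows the quoted arithmetic", {
  A <- data.frame(v_gene = "TRBV19", j_gene = "TRBJ2-1",
                  cdr3_aa = c("CASSAF", "CASSGF", "CASSLF"),
                  weight = c(0.5, 0.2, 1.0), stringsAsFactors = FALSE)
  rep <- make_repertoire("s", "TRBV19", "TRBJ2-1", c("CASSAF", "CASSGF"),
                         expansion = c(2L, 3L))
  expect_equal(weighted_expansion(rep, A), 0.5 * 2 + 0.2 * 3 + 1.0 * 0)
  # no shared clonotypes -> 0
  other <- make_repertoire("t", "TRBV9", "TRBJ2-1", "CASSAF")
  expect_equal(weighted_expansion(other, A), 0)
  # linearity: doubling expansions doubles the sum
  rep2 <- make_repertoire("s", "TRBV19", "TRBJ2-1", c("CASSAF", "CASSGF"),
                          expansion = c(4L, 6L))
  expect_equal(weighted_expansion(rep2, A), 2 * weighted_expansion(rep, A))
  # invariant to clonotype ordering within A
  expect_equal(weighted_expansion(rep, A[c(3, 1, 2), ]),
               weighted_expansion(rep, A))
})

test_that("a separable weighted sum trains to balanced accuracy 1", {
  co <- weight_cohort()
  A <- data.frame(v_gene = "TRBV19", j_gene = "TRBJ2-1",
                  cdr3_aa = "CASSTRACKF", weight = 1, stringsAsFactors = FALSE)
  model <- fit_allele_classifier(co, "A*02:01", A)
  imp <- impute_cohort(co, list(model))
  ev <- evaluate_imputation(co, imp)
  expect_equal(ev$balanced_accuracy, 1)
})

test_that("shuffled labels yield chance-level held-out accuracy", {
  set.seed(13)
  bas <- replicate(20, {
    sim <- simulate_cohort(simulation_config(
      n_samples = 80, units = data.frame(unit = "A*02:01", frequency = 0.5),
      n_clonotypes_per_unit = 10, n_background = 150, n_private = 10),
      seed = sample.int(1e6, 1))
    co <- sim$cohort
    # break the repertoire-allotype pairing
    perm <- sample(co$samples)
    shuffled <- hla_cohort(co$repertoires,
                           stats::setNames(lapply(seq_along(perm), function(i) {
                             a <- co$allotypes[[perm[i]]]
                             hla_allotype(co$samples[i], a$units, a$typed_loci)
                           }), co$samples))
    sp <- split_cohort(shuffled, 0.75, seed = 1)
    A <- sim$truth[, c("v_gene", "j_gene", "cdr3_aa")]
    A$weight <- 1
    fitted <- tryCatch(fit_allele_classifier(sp$train, "A*02:01", A),
                       error = function(e) NULL)
    if (is.null(fitted)) return(NA_real_)
    ev <- evaluate_imputation(sp$validation,
                              impute_cohort(sp$validation, list(fitted)))
    if (nrow(ev)) ev$balanced_accuracy else NA_real_
  })
  expect_lt(abs(mean(bas, na.rm = TRUE) - 0.5), 0.15)
})

test_that("single-class training labels fail naming the unit", {
  co <- weight_cohort()
  allot <- lapply(co$samples, function(s) hla_allotype(s, "A*02:01", "A"))
  co2 <- hla_cohort(co$repertoires, allot)
  A <- data.frame(v_gene = "TRBV19", j_gene = "TRBJ2-1",
                  cdr3_aa = "CASSTRACKF", weight = 1, stringsAsFactors = FALSE)
  expect_error(fit_allele_classifier(co2, "A*02:01", A), "A\\*02:01")
})

test_that("imputation calls are inclusive at the 0.5 threshold", {
  model <- structure(
    list(unit = "A*02:01", locus = "A",
         A = data.frame(v_gene = "TRBV19", j_gene = "TRBJ2-1",
                        cdr3_aa = "CASSAF", weight = 1,
                        stringsAsFactors = FALSE),
         coefficients = c(intercept = 0, weighted_expansion = 0, depth = 0),
         center = c(weighted_expansion = 0, depth = 0),
         scale = c(weighted_expansion = 1, depth = 1),
         train_frequency = 0.5, n_train = 10L),
    class = "allele_model")
  rep <- make_repertoire("s", "TRBV9", "TRBJ2-1", "CASSGF")
  out <- impute_repertoire(rep, list(model))
  expect_equal(out$probability, 0.5)  # all-zero coefficients -> exactly 0.5
  expect_true(out$called)
})

test_that("probability is monotone in a positively weighted expansion", {
  co <- weight_cohort()
  A <- data.frame(v_gene = "TRBV19", j_gene = "TRBJ2-1",
                  cdr3_aa = "CASSTRACKF", weight = 1, stringsAsFactors = FALSE)
  model <- fit_allele_classifier(co, "A*02:01", A)
  expect_gt(model$coefficients["weighted_expansion"], 0)
  probs <- vapply(c(1L, 3L, 6L, 12L), function(e) {
    r <- make_repertoire("x", "TRBV19", "TRBJ2-1",
                         c("CASSTRACKF", "CASSOTHERF"), expansion = c(e, 1L))
    impute_repertoire(r, list(model))$probability
  }, numeric(1))
  expect_true(all(diff(probs) >= 0))
})

test_that("an empty repertoire scores at the model baseline", {
  co <- weight_cohort()
  A <- data.frame(v_gene = "TRBV19", j_gene = "TRBJ2-1",
                  cdr3_aa = "CASSTRACKF", weight = 1, stringsAsFactors = FALSE)
  model <- fit_allele_classifier(co, "A*02:01", A)
  empty <- suppressWarnings(collapse_repertoire(
    rearrangement_records(character(0), character(0), character(0)), "e"))
  out <- impute_repertoire(empty, list(model))
  z <- (c(0, 0) - model$center) / model$scale
  expected <- plogis(sum(model$coefficients * c(1, z)))
  expect_equal(out$probability, unname(expected))
})

test_that("model bundles round-trip losslessly through JSON", {
  sim <- simulate_cohort(simulation_config(
    n_samples = 60, units = data.frame(unit = c("A*02:01", "B*08:01"),
                                       frequency = c(0.5, 0.3)),
    n_clonotypes_per_unit = 5, n_background = 100, n_private = 5), seed = 31)
  fit <- hla_fit(sim$cohort)
  path <- tempfile(fileext = ".json")
  save_models(fit, path)
  back <- load_models(path)
  expect_setequal(names(back), names(fit$models))
  r <- sim$cohort$repertoires[[1]]
  expect_identical(impute_repertoire(r, back)$probability,
                   impute_repertoire(r, fit)$probability)
})

test_that("bundle loading rejects bad versions and truncated files", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = 99, models = list()), path,
                       auto_unbox = TRUE)
  expect_error(load_models(path), "version")
  trunc <- tempfile(fileext = ".json")
  writeLines('{"schema_version": 1, "models": [', trunc)
  expect_error(load_models(trunc))
  # an empty model list is a valid bundle
  empty <- tempfile(fileext = ".json")
  save_models(list(), empty)
  expect_length(load_models(empty), 0L)
})
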