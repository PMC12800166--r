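# Per-clonotype association weights and the per-allele carriership
# classifier.
#
# Each resolved clonotype c associated with unit a gets a weight |beta1|
# from a logistic regression of carriership on the column-wise Z-scored
# features [C(c, R_i), sqrt(C(R_i))]. An allele's weighted clonotype set
# A = {(a_j, c_j)} then feeds a two-feature carriership classifier over
# [sum_j |a_j| * C(c_j, R_i), C(R_i)].

.zscore_col <- function(x) {
  mu <- mean(x)
  sdv <- stats::sd(x)
  if (!is.finite(sdv) || sdv == 0) {
    list(z = rep(0, length(x)), center = mu, scale = 0)
  } else {
    list(z = (x - mu) / sdv, center = mu, scale = sdv)
  }
}

# Core weight fit on precomputed vectors: expansion e, depth, carriership y.
.fit_weight_core <- function(e, depth, y, ridge = 1e-6) {
  ze <- .zscore_col(e)
  zd <- .zscore_col(sqrt(depth))
  fit <- ridge_logistic(cbind(expansion = ze$z, sqrt_depth = zd$z), y,
                        ridge = ridge)
  beta1 <- unname(fit$coefficients["expansion"])
  weight <- if (ze$scale == 0) 0 else abs(beta1)
  list(weight = weight, coefficients = fit$coefficients,
       center = c(expansion = ze$center, sqrt_depth = zd$center),
       scale = c(expansion = ze$scale, sqrt_depth = zd$scale))
}

#' Fit the association weight of one clonotype
#'
#' Logistic regression of carriership of `unit` on the Z-scored features
#' [expansion C(c, R), sqrt depth sqrt(C(R))]; the clonotype's weight is the
#' absolute value of the expansion coefficient beta1. A zero-variance
#' expansion column (clonotype equally expanded everywhere) yields weight 0.
#'
#' @param cohort training `hla_cohort`.
#' @param v_gene,j_gene,cdr3_aa the clonotype triple.
#' @param unit the HLA unit the clonotype is resolved to.
#' @return a `clonotype_weight` list: the triple, `unit`, `weight`,
#'   `center`/`scale` Z-score statistics and the full `coefficients`.
#' @export
fit_clonotype_weight <- function(cohort, v_gene, j_gene, cdr3_aa, unit) {
  cv <- carriership_vector(cohort, unit)
  ids <- names(cv$carrier)
  key <- clonotype_key(v_gene, j_gene, cdr3_aa)
  e <- vapply(cohort$repertoires[ids], function(r) {
    k <- clonotype_key(r$clonotypes$v_gene, r$clonotypes$j_gene,
                       r$clonotypes$cdr3_aa)
    m <- match(key, k)
    if (is.na(m)) 0 else as.numeric(r$clonotypes$expansion[m])
  }, numeric(1))
  depth <- vapply(cohort$repertoires[ids], `[[`, numeric(1), "depth")
  core <- .fit_weight_core(e, depth, as.numeric(cv$carrier))
  structure(c(list(v_gene = v_gene, j_gene = j_gene, cdr3_aa = cdr3_aa,
                   unit = unit), core),
            class = "clonotype_weight")
}

#' Weighted expansion of an allele's clonotype set in one repertoire
#'
#' Computes sum_j |a_j| * C(c_j, R): each clonotype of the set contributes
#' its expansion in the repertoire times the magnitude of its association
#' weight; clonotypes absent from the repertoire contribute 0.
#'
#' @param repertoire a `repertoire` object.
#' @param A data.frame with columns `v_gene`, `j_gene`, `cdr3_aa`, `weight`.
#' @return non-negative scalar.
#' @export
weighted_expansion <- function(repertoire, A) {
  if (!nrow(A)) stop("the clonotype set A is empty")
  rk <- clonotype_key(repertoire$clonotypes$v_gene,
                      repertoire$clonotypes$j_gene,
                      repertoire$clonotypes$cdr3_aa)
  m <- match(clonotype_key(A$v_gene, A$j_gene, A$cdr3_aa), rk)
  e <- ifelse(is.na(m), 0, repertoire$clonotypes$expansion[m])
  sum(abs(A$weight) * e)
}

#' Fit the carriership classifier of one HLA unit
#'
#' Standard (ridge-stabilised) logistic regression predicting carriership
#' of `unit` from [weighted expansion of A, repertoire depth C(R)]. Both
#' features are Z-scored with training statistics stored in the model
#' (disable with `scale_features = FALSE`).
#'
#' @param cohort training `hla_cohort`.
#' @param unit HLA unit name.
#' @param A weighted clonotype set: data.frame `v_gene`, `j_gene`,
#'   `cdr3_aa`, `weight`.
#' @param scale_features Z-score the two features (default TRUE).
#' @return an `allele_model`: `unit`, `locus`, `A` (sorted), `coefficients`
#'   (intercept, weighted_expansion, depth), `center`, `scale`,
#'   `train_frequency`, `n_train`.
#' @export
fit_allele_classifier <- function(cohort, unit, A, scale_features = TRUE) {
  stopifnot(nrow(A) >= 1L)
  cv <- carriership_vector(cohort, unit)
  ids <- names(cv$carrier)
  y <- as.numeric(cv$carrier)
  if (length(unique(y)) < 2L) {
    stop("unit ", unit, " has a single carriership class in training data")
  }
  ws <- vapply(cohort$repertoires[ids], weighted_expansion, numeric(1), A = A)
  depth <- vapply(cohort$repertoires[ids], `[[`, numeric(1), "depth")
  .build_allele_model(unit, A, ws, depth, y, scale_features,
                      train_frequency = cv$frequency, n_train = length(y))
}

.build_allele_model <- function(unit, A, ws, depth, y, scale_features,
                                train_frequency, n_train) {
  if (scale_features) {
    zw <- .zscore_col(ws)
    zd <- .zscore_col(depth)
    X <- cbind(weighted_expansion = zw$z, depth = zd$z)
    center <- c(weighted_expansion = zw$center, depth = zd$center)
    scale <- c(weighted_expansion = zw$scale, depth = zd$scale)
  } else {
    X <- cbind(weighted_expansion = ws, depth = depth)
    center <- c(weighted_expansion = 0, depth = 0)
    scale <- c(weighted_expansion = 1, depth = 1)
  }
  fit <- ridge_logistic(X, y)
  ord <- order(clonotype_key(A$v_gene, A$j_gene, A$cdr3_aa))
  A <- A[ord, c("v_gene", "j_gene", "cdr3_aa", "weight"), drop = FALSE]
  rownames(A) <- NULL
  structure(
    list(unit = unit, locus = hla_unit_locus(unit), A = A,
         coefficients = stats::setNames(
           unname(fit$coefficients),
           c("intercept", "weighted_expansion", "depth")),
         center = center, scale = scale,
         train_frequency = train_frequency, n_train = as.integer(n_train)),
    class = "allele_model"
  )
}

#' @export
print.allele_model <- function(x, ...) {
  cat("<allele_model>", x$unit, "|", nrow(x$A), "clonotypes",
      "| training carriership frequency",
      format(x$train_frequency, digits = 3), "\n")
  invisible(x)
}

# Carriership probability of one repertoire under one allele model.
.score_repertoire <- function(repertoire, model) {
  x <- c(weighted_expansion = weighted_expansion(repertoire, model$A),
         depth = repertoire$depth)
  sc <- ifelse(model$scale == 0, 1, model$scale)
  z <- (x - model$center) / sc
  co <- model$coefficients
  unname(plogis(co["intercept"] + co["weighted_expansion"] *
                  z["weighted_expansion"] + co["depth"] * z["depth"]))
}

#' Impute HLA carriership from a single repertoire
#'
#' Scores the repertoire under every allele model and calls the units whose
#' carriership probability reaches the threshold (inclusive: a probability
#' of exactly 0.5 is called).
#'
#' @param repertoire a `repertoire` object.
#' @param models an `hla_model_set` (see [hla_fit()]) or list of
#'   `allele_model` objects.
#' @param threshold carriership-probability call threshold (default 0.5).
#' @return data.frame with `sample_id`, `unit`, `probability`, `called`.
#' @export
impute_repertoire <- function(repertoire, models, threshold = 0.5) {
  mlist <- if (inherits(models, "hla_model_set")) models$models else models
  if (!length(mlist)) stop("no allele models supplied")
  probs <- vapply(mlist, .score_repertoire, numeric(1),
                  repertoire = repertoire)
  units <- vapply(mlist, `[[`, character(1), "unit")
  data.frame(sample_id = repertoire$sample_id, unit = unname(units),
             probability = unname(probs),
             called = unname(probs >= threshold),
             stringsAsFactors = FALSE)
}

#' Impute HLA carriership for many repertoires
#'
#' @param x an `hla_cohort` or a named list of `repertoire` objects.
#' @inheritParams impute_repertoire
#' @return long data.frame: one row per (sample, unit).
#' @export
impute_cohort <- function(x, models, threshold = 0.5) {
  reps <- if (inherits(x, "hla_cohort")) x$repertoires else x
  out <- lapply(reps, impute_repertoire, models = models,
                threshold = threshold)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
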