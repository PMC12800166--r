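# Resolving clonotypes associated with multiple HLA units.
#
# Because HLA alleles travel on strongly linked haplotypes, the Fisher scan
# can associate one clonotype with several units. For each such clonotype,
# an L1-regularised logistic regression predicts the clonotype's presence
# from the candidate units' carriership indicators plus sqrt repertoire
# depth; sweeping the penalty until exactly one carriership weight survives
# names the restricting unit, and clonotypes that never reach that state
# are labelled "unsolvable" and dropped downstream.

#' The penalty schedule for association resolution
#'
#' Ten log-spaced values from 0.01 to 10, tried in increasing order.
#'
#' @param n number of values.
#' @param from,to range of the schedule.
#' @return numeric vector of penalties.
#' @export
lambda_schedule <- function(n = 10L, from = 0.01, to = 10) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Build the disambiguation problem for one promiscuous clonotype
#'
#' @param cohort an `hla_cohort`.
#' @param v_gene,j_gene,cdr3_aa the clonotype triple.
#' @param units candidate HLA units (length >= 2) the clonotype is
#'   associated with.
#' @return list with `Y` (presence per sample), `X` (carriership indicator
#'   columns, one per candidate unit, plus a final `sqrt_depth` column),
#'   `units`, and `samples`. Samples untyped at any candidate locus are
#'   excluded.
#' @export
build_disambiguation_problem <- function(cohort, v_gene, j_gene, cdr3_aa,
                                         units) {
  stopifnot(length(units) >= 2L)
  loci <- unique(hla_unit_locus(units))
  typed <- vapply(cohort$allotypes,
                  function(a) all(loci %in% a$typed_loci), logical(1))
  ids <- cohort$samples[typed]
  key <- clonotype_key(v_gene, j_gene, cdr3_aa)
  Y <- vapply(cohort$repertoires[ids], function(r) {
    key %in% clonotype_key(r$clonotypes$v_gene, r$clonotypes$j_gene,
                           r$clonotypes$cdr3_aa)
  }, logical(1))
  X <- vapply(units, function(u) {
    as.numeric(vapply(cohort$allotypes[ids],
                      function(a) u %in% a$units, logical(1)))
  }, numeric(length(ids)))
  depth <- vapply(cohort$repertoires[ids], `[[`, numeric(1), "depth")
  X <- cbind(X, sqrt_depth = sqrt(depth))
  colnames(X) <- c(units, "sqrt_depth")
  list(Y = as.numeric(Y), X = X, units = units, samples = ids)
}

#' Resolve one multi-associated clonotype to a single HLA unit
#'
#' Runs the L1 logistic fit for each penalty in the schedule (1000 epochs
#' per run, restarted from scratch); after each run, if exactly one
#' carriership weight has magnitude at or above `sparsity_tol` (1e-4), the
#' clonotype is assigned to that unit. If no penalty in the schedule
#' achieves this, the clonotype is labelled `"unsolvable"` - its association
#' is locked inside a haplotype this cohort cannot split.
#'
#' @param problem a problem from [build_disambiguation_problem()].
#' @param lambdas penalty schedule; default [lambda_schedule()].
#' @param epochs epochs per penalty (default 1000).
#' @param sparsity_tol weight-magnitude threshold (default 1e-4).
#' @param lr optional fixed step size passed to [fit_l1_logistic()].
#' @return list with `status` (`"resolved"` or `"unsolvable"`), `unit`
#'   (`NA` when unsolvable), `lambda` used, and the final `W`, `b`.
#' @export
resolve_clonotype <- function(problem, lambdas = lambda_schedule(),
                              epochs = 1000L, sparsity_tol = 1e-4,
                              lr = NULL) {
  n_units <- length(problem$units)
  pen <- seq_len(n_units)
  fit <- NULL
  for (lam in lambdas) {
    fit <- fit_l1_logistic(problem$X, problem$Y, lambda = lam,
                           epochs = epochs, lr = lr, penalized = pen)
    nz <- which(abs(fit$W[pen]) >= sparsity_tol)
    if (length(nz) == 1L) {
      return(list(status = "resolved", unit = problem$units[nz],
                  lambda = lam, W = fit$W, b = fit$b))
    }
  }
  list(status = "unsolvable", unit = NA_character_,
       lambda = NA_real_, W = fit$W, b = fit$b)
}

#' Resolve all promiscuous associations from a Fisher scan
#'
#' Groups association records by clonotype. Clonotypes associated with a
#' single unit (L(c) = 1) bypass resolution; clonotypes with L(c) >= 2 go
#' through [resolve_clonotype()]. Each input record receives a status:
#' `resolved_single`, `resolved_multi_kept` (the record whose unit won),
#' `resolved_multi_dropped`, or `unsolvable`.
#'
#' @param cohort the training `hla_cohort`.
#' @param associations data.frame from [discover_associations()].
#' @inheritParams resolve_clonotype
#' @return list with `records` (the input plus `status`), `clonotypes`
#'   (one row per clonotype: triple, `n_candidates`, `status`,
#'   `assigned_unit`, `lambda`), and `assignments` (clonotype-unit pairs
#'   kept for model fitting).
#' @export
resolve_associations <- function(cohort, associations,
                                 lambdas = lambda_schedule(),
                                 epochs = 1000L, sparsity_tol = 1e-4,
                                 lr = NULL) {
  key <- clonotype_key(associations$v_gene, associations$j_gene,
                       associations$cdr3_aa)
  ukeys <- sort(unique(key))
  status <- character(nrow(associations))
  clono <- vector("list", length(ukeys))
  for (i in seq_along(ukeys)) {
    rows <- which(key == ukeys[i])
    units <- sort(associations$unit[rows])
    tri <- associations[rows[1L], c("v_gene", "j_gene", "cdr3_aa")]
    if (length(units) == 1L) {
      status[rows] <- "resolved_single"
      clono[[i]] <- data.frame(tri, n_candidates = 1L,
                               status = "resolved_single",
                               assigned_unit = units, lambda = NA_real_,
                               stringsAsFactors = FALSE)
    } else {
      problem <- build_disambiguation_problem(
        cohort, tri$v_gene, tri$j_gene, tri$cdr3_aa, units)
      res <- resolve_clonotype(problem, lambdas = lambdas, epochs = epochs,
                               sparsity_tol = sparsity_tol, lr = lr)
      if (res$status == "resolved") {
        status[rows] <- ifelse(associations$unit[rows] == res$unit,
                               "resolved_multi_kept",
                               "resolved_multi_dropped")
        st <- "resolved_multi"
      } else {
        status[rows] <- "unsolvable"
        st <- "unsolvable"
      }
      clono[[i]] <- data.frame(tri, n_candidates = length(units),
                               status = st, assigned_unit = res$unit,
                               lambda = res$lambda, stringsAsFactors = FALSE)
    }
  }
  records <- associations
  records$status <- status
  clonotypes <- do.call(rbind, clono)
  rownames(clonotypes) <- NULL
  keep <- !is.na(clonotypes$assigned_unit)
  assignments <- clonotypes[keep, c("v_gene", "j_gene", "cdr3_aa",
                                    "assigned_unit"), drop = FALSE]
  names(assignments)[4L] <- "unit"
  rownames(assignments) <- NULL
  list(records = records, clonotypes = clonotypes, assignments = assignments)
}

#' Partition resolved clonotypes by how their association was settled
#'
#' @param resolution output of [resolve_associations()] (or its
#'   `clonotypes` element).
#' @return list of three character vectors of clonotype keys:
#'   `single`, `multi_resolved`, `unsolvable`; their lengths sum to the
#'   number of distinct clonotypes with candidate associations.
#' @export
partition_by_resolution <- function(resolution) {
  cl <- if (is.data.frame(resolution)) resolution else resolution$clonotypes
  if (is.null(cl) || !nrow(cl)) {
    return(list(single = character(0), multi_resolved = character(0),
                unsolvable = character(0)))
  }
  keys <- clonotype_key(cl$v_gene, cl$j_gene, cl$cdr3_aa)
  list(single = keys[cl$status == "resolved_single"],
       multi_resolved = keys[cl$status == "resolved_multi"],
       unsolvable = keys[cl$status == "unsolvable"])
}
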