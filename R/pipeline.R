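# End-to-end model training: Fisher scan -> LD resolution -> clonotype
# weights -> per-allele carriership classifiers.

#' Train HLA imputation models from a paired cohort
#'
#' Runs the full training pipeline on a cohort of paired repertoires and
#' HLA allotypes:
#' 1. [discover_associations()] finds public clonotypes enriched in
#'    carriers of each HLA unit (one-sided Fisher, fixed `p_cutoff`).
#' 2. [resolve_associations()] settles clonotypes associated with several
#'    units via the L1-regularised logistic sweep; unsolvable clonotypes
#'    are dropped.
#' 3. Each assigned clonotype gets an association weight
#'    ([fit_clonotype_weight()]); multi-associated clonotypes are re-fit
#'    the same way as single ones.
#' 4. For each unit with training carriership frequency above
#'    `min_train_freq`, a carriership classifier is fitted on
#'    [weighted expansion, depth] ([fit_allele_classifier()]).
#'
#' @param cohort training `hla_cohort`.
#' @param p_cutoff Fisher association cutoff (fixed default 1e-4).
#' @param publicity minimum clonotype incidence (default 2).
#' @param min_carriers minimum carriers for a unit to be scanned.
#' @param min_train_freq units at or below this training carriership
#'   frequency get no model (default 0.01).
#' @param lambdas,epochs,sparsity_tol,lr resolution parameters; see
#'   [resolve_clonotype()].
#' @param scale_features Z-score the classifier features (default TRUE).
#' @param verbose print stage progress.
#' @return an `hla_model_set`: list with `models` (named list of
#'   `allele_model`s, sorted by unit), `weights` (per-clonotype weight
#'   table), `resolution` (see [resolve_associations()]), `associations`
#'   (the Fisher scan output) and `params`.
#' @export
hla_fit <- function(cohort, p_cutoff = 1e-4, publicity = 2L,
                    min_carriers = 2L, min_train_freq = 0.01,
                    lambdas = lambda_schedule(), epochs = 1000L,
                    sparsity_tol = 1e-4, lr = NULL, scale_features = TRUE,
                    verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("scanning for clonotype-HLA associations ...")
  assoc <- discover_associations(cohort, p_cutoff = p_cutoff,
                                 publicity = publicity,
                                 min_carriers = min_carriers)
  say("  ", nrow(assoc), " candidate records")
  res <- resolve_associations(cohort, assoc, lambdas = lambdas,
                              epochs = epochs, sparsity_tol = sparsity_tol,
                              lr = lr)
  asg <- res$assignments
  say("  ", nrow(asg), " clonotypes assigned to a single unit")

  samples <- cohort$samples
  n <- length(samples)
  depth <- vapply(cohort$repertoires, `[[`, numeric(1), "depth")
  # unit bookkeeping: carriership over typed samples, frequency filter
  units <- sort(unique(asg$unit))
  carr <- lapply(units, function(u) carriership_vector(cohort, u))
  names(carr) <- units
  freqs <- vapply(carr, `[[`, numeric(1), "frequency")
  units <- units[freqs > min_train_freq]
  asg <- asg[asg$unit %in% units, , drop = FALSE]

  # sparse expansion vectors for every assigned clonotype
  idx <- presence_index(cohort)
  akey <- clonotype_key(asg$v_gene, asg$j_gene, asg$cdr3_aa)
  kid <- match(akey, idx$keys)
  rows_by_key <- split(seq_len(nrow(idx$long)), idx$long$key_id)
  expansion_vec <- function(id) {
    e <- numeric(n)
    r <- rows_by_key[[as.character(id)]]
    e[idx$long$sample_id[r]] <- idx$long$expansion[r]
    e
  }

  say("fitting ", nrow(asg), " clonotype weights ...")
  weights <- numeric(nrow(asg))
  for (i in seq_len(nrow(asg))) {
    cv <- carr[[asg$unit[i]]]
    ids <- match(names(cv$carrier), samples)
    e <- expansion_vec(kid[i])
    weights[i] <- .fit_weight_core(e[ids], depth[ids],
                                   as.numeric(cv$carrier))$weight
  }
  weight_tab <- data.frame(asg, weight = weights, stringsAsFactors = FALSE)

  say("fitting ", length(units), " allele classifiers ...")
  models <- list()
  for (u in units) {
    rows <- which(weight_tab$unit == u)
    A <- weight_tab[rows, c("v_gene", "j_gene", "cdr3_aa", "weight"),
                    drop = FALSE]
    cv <- carr[[u]]
    y <- as.numeric(cv$carrier)
    if (length(unique(y)) < 2L) {
      warning("skipping unit ", u, ": single carriership class in training")
      next
    }
    ids <- match(names(cv$carrier), samples)
    ws <- numeric(n)
    for (i in rows) {
      ws <- ws + abs(weight_tab$weight[i]) * expansion_vec(kid[i])
    }
    models[[u]] <- .build_allele_model(
      u, A, ws[ids], depth[ids], y, scale_features,
      train_frequency = cv$frequency, n_train = length(y))
  }
  models <- models[order(names(models))]
  structure(
    list(models = models, weights = weight_tab, resolution = res,
         associations = assoc,
         params = list(p_cutoff = p_cutoff, publicity = publicity,
                       min_carriers = min_carriers,
                       min_train_freq = min_train_freq,
                       lambdas = lambdas, epochs = epochs,
                       sparsity_tol = sparsity_tol,
                       scale_features = scale_features,
                       n_train_samples = n)),
    class = "hla_model_set"
  )
}

#' @export
print.hla_model_set <- function(x, ...) {
  part <- partition_by_resolution(x$resolution)
  cat("<hla_model_set>", length(x$models), "allele models |",
      nrow(x$weights), "weighted clonotypes |",
      length(part$unsolvable), "unsolvable clonotypes dropped\n")
  invisible(x)
}
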