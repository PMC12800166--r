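# Model-bundle serialisation: a versioned JSON document embedding, for each
# allele model, the clonotype triples and weights, the Z-score statistics
# and the classifier coefficients. Serialisation is deterministic (fixed
# ordering, no timestamps) so identical model sets produce byte-identical
# bundles.

.bundle_version <- 1L

#' Save allele models to a JSON bundle
#'
#' @param models an `hla_model_set` from [hla_fit()] or a list of
#'   `allele_model` objects; an empty list writes a valid empty bundle.
#' @param path output path.
#' @export
save_models <- function(models, path) {
  mlist <- if (inherits(models, "hla_model_set")) models$models else models
  mlist <- mlist[order(vapply(mlist, `[[`, character(1), "unit"))]
  blocks <- lapply(mlist, function(m) {
    list(unit = m$unit, locus = m$locus,
         train_frequency = m$train_frequency, n_train = m$n_train,
         coefficients = as.list(m$coefficients),
         center = as.list(m$center), scale = as.list(m$scale),
         clonotypes = m$A)
  })
  doc <- list(schema_version = .bundle_version, models = unname(blocks))
  # 17 significant digits: doubles round-trip exactly through the bundle
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load allele models from a JSON bundle
#'
#' Round-trips losslessly with [save_models()]: scoring any repertoire with
#' the reloaded models gives identical probabilities.
#'
#' @param path bundle path.
#' @return named list of `allele_model` objects (possibly empty).
#' @export
load_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- doc$schema_version
  if (is.null(ver) || ver != .bundle_version) {
    stop("unsupported model bundle version: ", ver %||% "<missing>",
         " (expected ", .bundle_version, ")")
  }
  mlist <- lapply(doc$models, function(blk) {
    A <- do.call(rbind, lapply(blk$clonotypes, function(cl) {
      data.frame(v_gene = cl$v_gene, j_gene = cl$j_gene,
                 cdr3_aa = cl$cdr3_aa, weight = as.numeric(cl$weight),
                 stringsAsFactors = FALSE)
    }))
    structure(
      list(unit = blk$unit, locus = blk$locus, A = A,
           coefficients = unlist(blk$coefficients),
           center = unlist(blk$center), scale = unlist(blk$scale),
           train_frequency = as.numeric(blk$train_frequency),
           n_train = as.integer(blk$n_train)),
      class = "allele_model")
  })
  names(mlist) <- vapply(mlist, `[[`, character(1), "unit")
  mlist
}
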