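# The paired repertoire-allotype cohort and the HLA functional units that
# carriership is defined over.
#
# Carriership is tracked per "HLA unit": class-I alleles (A/B/C) and DRB1
# alleles are units by themselves; HLA-DQ and HLA-DP act through alpha-beta
# heterodimers, so their units name both chains, e.g.
# "DQA1*01:02-DQB1*06:02". Phase (cis vs trans) is unknown at this level, so
# all alpha x beta pairings of a sample's alleles are treated as candidate
# carried complexes.

.single_loci <- c("A", "B", "C", "DRB1")
.pair_loci <- list(DQ = c("DQA1", "DQB1"), DP = c("DPA1", "DPB1"))

.allele_regex <- "^[A-Z0-9]+\\*[0-9]{2,3}:[0-9]{2,3}[A-Z]?$"

#' Locus of an HLA unit
#'
#' @param unit character vector of unit names, e.g. `"A*02:01"` or
#'   `"DQA1*01:02-DQB1*06:02"`.
#' @return character vector over `{A, B, C, DRB1, DQ, DP}`.
#' @export
hla_unit_locus <- function(unit) {
  gene <- sub("\\*.*$", "", unit)
  out <- gene
  out[gene %in% c("DQA1", "DQB1")] <- "DQ"
  out[gene %in% c("DPA1", "DPB1")] <- "DP"
  unknown <- !out %in% c(.single_loci, "DQ", "DP")
  if (any(unknown)) stop("unrecognised HLA unit(s): ",
                         paste(unique(unit[unknown]), collapse = ", "))
  out
}

#' Enumerate candidate DQ/DP heterodimer units
#'
#' All alpha x beta pairings of a sample's alleles are returned as candidate
#' carried complexes; without phased haplotypes, cis and trans dimers cannot
#' be distinguished. With 1-2 distinct alleles per chain the output has
#' 1, 2 or 4 units.
#'
#' @param alpha_alleles,beta_alleles character vectors of alpha- and
#'   beta-chain alleles at four-digit resolution (e.g. `"DQA1*01:02"`).
#' @return character vector of unit names `"<alpha>-<beta>"`, sorted.
#' @export
enumerate_complexes <- function(alpha_alleles, beta_alleles) {
  alpha_alleles <- sort(unique(alpha_alleles[!is.na(alpha_alleles)]))
  beta_alleles <- sort(unique(beta_alleles[!is.na(beta_alleles)]))
  if (!length(alpha_alleles) || !length(beta_alleles)) return(character(0))
  sort(as.vector(outer(alpha_alleles, beta_alleles, paste, sep = "-")))
}

#' Construct an HLA allotype
#'
#' @param sample_id sample identifier.
#' @param units character vector of carried HLA units.
#' @param typed_loci loci with genotype information for this sample;
#'   defaults to the loci represented in `units`.
#' @return an `hla_allotype` object.
#' @export
hla_allotype <- function(sample_id, units,
                         typed_loci = unique(hla_unit_locus(units))) {
  structure(
    list(sample_id = as.character(sample_id),
         units = sort(unique(units)),
         typed_loci = sort(unique(typed_loci))),
    class = "hla_allotype"
  )
}

#' Read an allotype table
#'
#' Expects a TSV with a `sample_id` column plus per-locus allele columns
#' `A.1`, `A.2`, ..., `DPB1.1`, `DPB1.2` (empty cell = missing allele).
#' Class-I and DRB1 alleles become units directly (homozygotes collapse to a
#' single carried unit); DQ and DP units are built with
#' [enumerate_complexes()]. A locus counts as typed for a sample when at
#' least one allele (both chains, for DQ/DP) is present.
#'
#' @param path TSV path.
#' @param loci optional character vector of loci (`A`, `B`, `C`, `DRB1`,
#'   `DQ`, `DP`) that must be present in the file; a requested locus whose
#'   allele columns are absent raises an error naming the locus. By default
#'   whatever columns exist are used.
#' @return named list of [hla_allotype()] objects keyed by sample id.
#' @export
read_allotypes <- function(path, loci = NULL) {
  if (!file.exists(path)) stop("allotype file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  if (!"sample_id" %in% names(tab)) stop("missing mandatory column: sample_id")
  if (!is.null(loci)) {
    for (locus in loci) {
      chains <- if (locus %in% names(.pair_loci)) .pair_loci[[locus]]
                else locus
      for (chain in chains) {
        if (!any(paste0(chain, c(".1", ".2")) %in% names(tab))) {
          stop("allotype table lacks columns for locus ", locus,
               " (expected ", chain, ".1/", chain, ".2)")
        }
      }
    }
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ",
         tab$sample_id[duplicated(tab$sample_id)][1L])
  }
  get_alleles <- function(locus, row) {
    cols <- paste0(locus, c(".1", ".2"))
    cols <- cols[cols %in% names(tab)]
    vals <- unlist(tab[row, cols], use.names = FALSE)
    vals <- vals[!is.na(vals) & nzchar(trimws(vals))]
    vals <- trimws(vals)
    bad <- !grepl(.allele_regex, vals)
    if (any(bad)) {
      stop("malformed allele string '", vals[bad][1L], "' at row ", row)
    }
    unique(vals)
  }
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    units <- character(0)
    typed <- character(0)
    for (locus in .single_loci) {
      al <- get_alleles(locus, i)
      if (length(al)) {
        units <- c(units, al)
        typed <- c(typed, locus)
      }
    }
    for (locus in names(.pair_loci)) {
      alpha <- get_alleles(.pair_loci[[locus]][1L], i)
      beta <- get_alleles(.pair_loci[[locus]][2L], i)
      if (length(alpha) && length(beta)) {
        units <- c(units, enumerate_complexes(alpha, beta))
        typed <- c(typed, locus)
      }
    }
    out[[i]] <- hla_allotype(tab$sample_id[i], units, typed)
  }
  names(out) <- tab$sample_id
  out
}

#' Write an allotype table
#'
#' Inverse of [read_allotypes()] for single-chain loci; DQ/DP units are
#' decomposed back into their chain alleles.
#'
#' @param allotypes named list of [hla_allotype()] objects.
#' @param path output TSV path.
#' @export
write_allotypes <- function(allotypes, path) {
  chains <- c(.single_loci, unlist(.pair_loci, use.names = FALSE))
  rows <- lapply(allotypes, function(a) {
    row <- list(sample_id = a$sample_id)
    for (chain in chains) {
      al <- unique(unlist(lapply(a$units, function(u) {
        parts <- strsplit(u, "-", fixed = TRUE)[[1L]]
        parts[startsWith(parts, paste0(chain, "*"))]
      })))
      al <- sort(al)
      row[[paste0(chain, ".1")]] <- if (length(al) >= 1L) al[1L] else ""
      row[[paste0(chain, ".2")]] <-
        if (length(al) >= 2L) al[2L] else if (length(al) == 1L) al[1L] else ""
    }
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a paired repertoire-allotype cohort
#'
#' @param repertoires named list of `repertoire` objects.
#' @param allotypes named list of [hla_allotype()] objects with exactly the
#'   same sample ids.
#' @return an `hla_cohort` object.
#' @export
hla_cohort <- function(repertoires, allotypes) {
  if (is.null(names(repertoires))) {
    names(repertoires) <- vapply(repertoires, `[[`, character(1), "sample_id")
  }
  if (is.null(names(allotypes))) {
    names(allotypes) <- vapply(allotypes, `[[`, character(1), "sample_id")
  }
  ids <- sort(names(repertoires))
  if (!setequal(ids, names(allotypes))) {
    stop("repertoire and allotype sample ids do not match")
  }
  if (length(ids) < 2L) stop("a cohort needs at least 2 samples")
  structure(
    list(repertoires = repertoires[ids], allotypes = allotypes[ids],
         samples = ids),
    class = "hla_cohort"
  )
}

#' @export
print.hla_cohort <- function(x, ...) {
  depths <- vapply(x$repertoires, `[[`, numeric(1), "depth")
  cat("<hla_cohort>", length(x$samples), "samples |",
      length(unique(unlist(lapply(x$allotypes, `[[`, "units")))),
      "distinct HLA units | median depth", stats::median(depths), "\n")
  invisible(x)
}

#' All HLA units observed in a cohort
#' @param cohort an `hla_cohort`.
#' @return sorted character vector of unit names.
#' @export
cohort_units <- function(cohort) {
  sort(unique(unlist(lapply(cohort$allotypes, `[[`, "units"))))
}

#' Carriership vector of an HLA unit over a cohort
#'
#' Samples are binned into carriers and non-carriers of `unit`. Samples
#' whose allotype lacks genotype information at the unit's locus are
#' excluded (dropped from the vector), and the carriership frequency is
#' carriers / N over the typed samples.
#'
#' @param cohort an `hla_cohort`.
#' @param unit HLA unit name.
#' @return list with `carrier` (named logical over typed samples),
#'   `frequency`, and `n_typed`.
#' @export
carriership_vector <- function(cohort, unit) {
  locus <- hla_unit_locus(unit)
  typed <- vapply(cohort$allotypes, function(a) locus %in% a$typed_loci,
                  logical(1))
  carrier <- vapply(cohort$allotypes[typed],
                    function(a) unit %in% a$units, logical(1))
  list(carrier = carrier,
       frequency = if (length(carrier)) mean(carrier) else 0,
       n_typed = length(carrier))
}

#' Split a cohort into training and validation subsets
#'
#' Simple random split, reproducible under `seed`; every sample lands in
#' exactly one of the two subsets.
#'
#' @param cohort an `hla_cohort`.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `validation` cohorts.
#' @export
split_cohort <- function(cohort, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- length(cohort$samples)
  n_train <- round(n * fraction)
  if (n_train < 2L || n - n_train < 1L) {
    stop("split would leave fewer than 2 training or 1 validation samples")
  }
  train_ids <- with_seed(seed, sort(sample(cohort$samples, n_train)))
  val_ids <- setdiff(cohort$samples, train_ids)
  list(
    train = hla_cohort(cohort$repertoires[train_ids],
                       cohort$allotypes[train_ids]),
    validation = hla_cohort(cohort$repertoires[val_ids],
                            cohort$allotypes[val_ids])
  )
}
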