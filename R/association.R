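# Public-clonotype identification and the carrier/non-carrier Fisher scan.
#
# For each HLA unit, samples are binned into carriers and non-carriers and
# the presence of each public clonotype is compared between the two groups
# with a one-sided (enrichment in carriers) exact test on the 2x2 table.
# The scan runs over a sparse presence index (clonotype -> sample indices),
# so its cost is proportional to the total number of presence entries, not
# clonotypes x samples.

#' Sparse presence/expansion index of a cohort
#'
#' @param cohort an `hla_cohort`.
#' @return list with `samples`, `keys` (sorted clonotype keys), and `long`, a
#'   data.frame with one row per (clonotype, sample) presence entry holding
#'   `key_id`, `sample_id` (integer indices) and `expansion`.
#' @keywords internal
#' @export
presence_index <- function(cohort) {
  reps <- cohort$repertoires
  nper <- vapply(reps, `[[`, numeric(1), "depth")
  key <- unlist(lapply(reps, function(r) {
    clonotype_key(r$clonotypes$v_gene, r$clonotypes$j_gene,
                  r$clonotypes$cdr3_aa)
  }), use.names = FALSE)
  expansion <- unlist(lapply(reps, function(r) r$clonotypes$expansion),
                      use.names = FALSE)
  sample_id <- rep(seq_along(reps), times = nper)
  keys <- sort(unique(key))
  list(samples = cohort$samples, keys = keys,
       long = data.frame(key_id = match(key, keys), sample_id = sample_id,
                         expansion = expansion))
}

#' Identify public clonotypes
#'
#' A public clonotype is one detected in at least `publicity` individuals
#' (default two or more).
#'
#' @param cohort an `hla_cohort`.
#' @param publicity minimum incidence (number of samples with the clonotype).
#' @return data.frame with `v_gene`, `j_gene`, `cdr3_aa`, `incidence`.
#' @export
identify_public_clonotypes <- function(cohort, publicity = 2L) {
  idx <- presence_index(cohort)
  inc <- tabulate(idx$long$key_id, nbins = length(idx$keys))
  keep <- inc >= publicity
  out <- split_clonotype_key(idx$keys[keep])
  out$incidence <- inc[keep]
  out
}

#' Build the carrier-by-presence 2x2 contingency table
#'
#' Cells count individuals that have the allele and the clonotype, have the
#' allele but not the clonotype, have the clonotype but not the allele, and
#' have neither.
#'
#' @param presence,carrier equal-length binary (0/1 or logical) vectors over
#'   the same samples.
#' @return named integer vector `n_carrier_with`, `n_carrier_without`,
#'   `n_noncarrier_with`, `n_noncarrier_without`.
#' @export
build_contingency_table <- function(presence, carrier) {
  if (length(presence) != length(carrier)) {
    stop("presence and carrier vectors differ in length")
  }
  p <- as.logical(presence)
  k <- as.logical(carrier)
  c(n_carrier_with = sum(p & k),
    n_carrier_without = sum(!p & k),
    n_noncarrier_with = sum(p & !k),
    n_noncarrier_without = sum(!p & !k))
}

# Vectorised log-space hypergeometric upper tail P(X >= x) with X the
# carrier-with-clonotype cell under fixed margins: K carriers, M
# non-carriers, n samples with the clonotype.
.hyper_upper_tail <- function(x, K, M, n) {
  m <- max(length(x), length(K), length(M), length(n))
  x <- rep_len(x, m); K <- rep_len(K, m)
  M <- rep_len(M, m); n <- rep_len(n, m)
  vapply(seq_len(m), function(i) {
    if (K[i] == 0L || n[i] == 0L || x[i] <= 0L) return(1)
    hi <- min(K[i], n[i])
    if (x[i] > hi) return(0)
    kk <- x[i]:hi
    lt <- lchoose(K[i], kk) + lchoose(M[i], n[i] - kk) -
      lchoose(K[i] + M[i], n[i])
    mx <- max(lt)
    min(1, exp(mx + log(sum(exp(lt - mx)))))
  }, numeric(1))
}

#' One-sided Fisher exact test for clonotype enrichment in carriers
#'
#' Tests enrichment of a clonotype among allele carriers: the p-value is the
#' hypergeometric upper tail P(X >= n_carrier_with) under fixed table
#' margins, accumulated in log space for numerical stability at cohort sizes
#' in the thousands. Degenerate margins (a zero row or column sum) give
#' p = 1.
#'
#' @param table either a 2x2 matrix / length-4 vector ordered as
#'   (n_carrier_with, n_carrier_without, n_noncarrier_with,
#'   n_noncarrier_without), or the `n_carrier_with` vector when the other
#'   three cell vectors are supplied.
#' @param n_carrier_without,n_noncarrier_with,n_noncarrier_without optional
#'   cell vectors for vectorised use.
#' @return p-value(s) in (0, 1].
#' @export
fisher_one_sided <- function(table, n_carrier_without = NULL,
                             n_noncarrier_with = NULL,
                             n_noncarrier_without = NULL) {
  if (is.null(n_carrier_without)) {
    cells <- as.integer(table)
    if (length(cells) != 4L || any(is.na(cells)) || any(cells < 0L)) {
      stop("a 2x2 table needs four non-negative cells")
    }
    n11 <- cells[1L]; n12 <- cells[2L]; n21 <- cells[3L]; n22 <- cells[4L]
  } else {
    n11 <- as.integer(table)
    n12 <- as.integer(n_carrier_without)
    n21 <- as.integer(n_noncarrier_with)
    n22 <- as.integer(n_noncarrier_without)
    if (any(c(n11, n12, n21, n22) < 0L)) stop("negative cell counts")
  }
  .hyper_upper_tail(n11, K = n11 + n12, M = n21 + n22, n = n11 + n21)
}

#' Scan a cohort for clonotype-HLA associations
#'
#' For every public clonotype and every HLA unit with at least
#' `min_carriers` carriers (and carriership frequency above
#' `min_carrier_freq`, if set), builds the carrier/non-carrier 2x2 table and
#' keeps pairs whose one-sided Fisher p-value falls below `p_cutoff`.
#' Samples untyped at a unit's locus are excluded from that unit's tests.
#'
#' @param cohort an `hla_cohort`.
#' @param p_cutoff association p-value cutoff; the fixed default is 1e-4.
#' @param publicity minimum clonotype incidence (default 2 individuals).
#' @param min_carriers minimum carriers for a unit to be tested (default 2).
#' @param min_carrier_freq optional minimum carriership frequency at scan
#'   time (default 0: test all units, filter downstream).
#' @return data.frame with the clonotype triple, `unit`, `locus`, the four
#'   table cells and `p_value`, ordered by unit then clonotype key.
#' @export
discover_associations <- function(cohort, p_cutoff = 1e-4, publicity = 2L,
                                  min_carriers = 2L, min_carrier_freq = 0) {
  idx <- presence_index(cohort)
  n_keys <- length(idx$keys)
  inc <- tabulate(idx$long$key_id, nbins = n_keys)
  pub_ids <- which(inc >= publicity)
  empty <- data.frame(v_gene = character(0), j_gene = character(0),
                      cdr3_aa = character(0), unit = character(0),
                      locus = character(0), n_carrier_with = integer(0),
                      n_carrier_without = integer(0),
                      n_noncarrier_with = integer(0),
                      n_noncarrier_without = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  if (!length(pub_ids)) return(empty)
  pos <- integer(n_keys)
  pos[pub_ids] <- seq_along(pub_ids)
  keep <- pos[idx$long$key_id] > 0L
  lp_key <- pos[idx$long$key_id[keep]]
  lp_sample <- idx$long$sample_id[keep]
  n_pub <- length(pub_ids)
  n_samples <- length(idx$samples)

  units <- cohort_units(cohort)
  res <- vector("list", length(units))
  for (ui in seq_along(units)) {
    unit <- units[ui]
    locus <- hla_unit_locus(unit)
    typed <- vapply(cohort$allotypes,
                    function(a) locus %in% a$typed_loci, logical(1))
    carrier_full <- logical(n_samples)
    carrier_full[typed] <- vapply(cohort$allotypes[typed],
                                  function(a) unit %in% a$units, logical(1))
    K <- sum(carrier_full)
    n_typed <- sum(typed)
    if (K < min_carriers || n_typed == 0L) next
    if (K / n_typed < min_carrier_freq) next
    typed_l <- typed[lp_sample]
    n_with <- tabulate(lp_key[typed_l], nbins = n_pub)
    n11 <- tabulate(lp_key[carrier_full[lp_sample]], nbins = n_pub)
    p <- .hyper_upper_tail(n11, K = K, M = n_typed - K, n = n_with)
    hit <- which(p < p_cutoff)
    if (!length(hit)) next
    triple <- split_clonotype_key(idx$keys[pub_ids[hit]])
    triple$unit <- unit
    triple$locus <- locus
    triple$n_carrier_with <- n11[hit]
    triple$n_carrier_without <- K - n11[hit]
    triple$n_noncarrier_with <- n_with[hit] - n11[hit]
    triple$n_noncarrier_without <- (n_typed - K) - (n_with[hit] - n11[hit])
    triple$p_value <- p[hit]
    res[[ui]] <- triple
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$unit,
                   clonotype_key(out$v_gene, out$j_gene, out$cdr3_aa)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
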