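# Synthetic paired repertoire+allotype cohorts with planted structure.
#
# The generator emulates what the association framework assumes about real
# cohorts: a pool of public background clonotypes shared at random, private
# clonotypes unique to each sample, allele-restricted clonotypes whose
# detection probability is elevated in carriers of their unit, carriership
# frequencies per HLA unit with optional pairwise haplotype linkage, and
# per-sample depth variation between assays.

.default_units <- function() {
  data.frame(
    unit = c("A*02:01", "A*01:01", "B*08:01", "B*07:02", "C*07:01",
             "DRB1*15:01"),
    frequency = c(0.50, 0.41, 0.32, 0.23, 0.14, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic cohort
#'
#' Defaults describe a mid-sized single-population cohort: 300 samples, six
#' HLA units spanning carriership frequencies 0.05-0.5, 30 planted
#' clonotypes per unit detected with probability 0.8 in carriers versus
#' 0.02 in non-carriers, a pool of 2000 public background clonotypes each
#' present in ~10% of samples, 50 private clonotypes per sample, geometric
#' expansion counts with mean 2, and +/-30% per-sample depth variation.
#'
#' @param n_samples cohort size.
#' @param units data.frame with `unit`, `frequency` columns.
#' @param n_clonotypes_per_unit planted clonotypes per unit.
#' @param penetrance detection probability of a planted clonotype in
#'   carriers of its unit.
#' @param background_prevalence detection probability in non-carriers.
#' @param n_background size of the public background pool.
#' @param background_incidence per-sample inclusion probability of each
#'   background clonotype.
#' @param n_private private (non-public) clonotypes per sample.
#' @param expansion_mean mean of the geometric expansion count of a present
#'   clonotype (>= 1).
#' @param depth_variation half-width of the uniform per-sample depth factor;
#'   all detection probabilities are scaled by the sample's factor.
#' @param ld optional data.frame `unit1`, `unit2`, `r` requesting a
#'   haplotype-level correlation `r` between two configured units; each
#'   unit may appear in at most one pair.
#' @param cdr3_length_range CDR3 amino-acid length range.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 300L,
                              units = .default_units(),
                              n_clonotypes_per_unit = 30L,
                              penetrance = 0.8,
                              background_prevalence = 0.02,
                              n_background = 2000L,
                              background_incidence = 0.10,
                              n_private = 50L,
                              expansion_mean = 2,
                              depth_variation = 0.3,
                              ld = NULL,
                              cdr3_length_range = c(12L, 16L)) {
  stopifnot(n_samples >= 2L, nrow(units) >= 1L,
            all(units$frequency > 0 & units$frequency < 1),
            !anyDuplicated(units$unit),
            penetrance >= 0, penetrance <= 1,
            background_prevalence >= 0, background_prevalence <= 1,
            background_incidence > 0, background_incidence <= 1,
            expansion_mean >= 1, depth_variation >= 0, depth_variation < 1,
            cdr3_length_range[1L] >= 9L,
            cdr3_length_range[2L] >= cdr3_length_range[1L])
  invisible(hla_unit_locus(units$unit))
  if (!is.null(ld)) {
    stopifnot(all(c("unit1", "unit2", "r") %in% names(ld)))
    involved <- c(ld$unit1, ld$unit2)
    if (anyDuplicated(involved)) {
      stop("each unit may appear in at most one LD pair")
    }
    if (!all(involved %in% units$unit)) {
      stop("LD pairs must reference configured units")
    }
    for (i in seq_len(nrow(ld))) {
      .haplotype_probs(units$frequency[units$unit == ld$unit1[i]],
                       units$frequency[units$unit == ld$unit2[i]],
                       ld$r[i])
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), units = units,
         n_clonotypes_per_unit = as.integer(n_clonotypes_per_unit),
         penetrance = penetrance,
         background_prevalence = background_prevalence,
         n_background = as.integer(n_background),
         background_incidence = background_incidence,
         n_private = as.integer(n_private),
         expansion_mean = expansion_mean,
         depth_variation = depth_variation, ld = ld,
         cdr3_length_range = as.integer(cdr3_length_range)),
    class = "simulation_config"
  )
}

# Two-locus haplotype category probabilities (AB, Ab, aB, ab) achieving
# carrier frequencies fA, fB and haplotype correlation r; errors when the
# requested joint frequency is infeasible.
.haplotype_probs <- function(fA, fB, r) {
  pA <- 1 - sqrt(1 - fA)
  pB <- 1 - sqrt(1 - fB)
  pAB <- pA * pB + r * sqrt(pA * (1 - pA) * pB * (1 - pB))
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  if (pAB < lo - 1e-12 || pAB > hi + 1e-12) {
    stop("infeasible LD target: r = ", r, " with carrier frequencies ",
         fA, " and ", fB)
  }
  pAB <- min(max(pAB, lo), hi)
  c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
}

.random_cdr3 <- function(n, len_range) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  aa <- aa_alphabet()
  vapply(lens, function(l) {
    paste0("CASS", paste(sample(aa, l - 8L, replace = TRUE), collapse = ""),
           "EQYF")
  }, character(1))
}

.v_catalogue <- paste0("TRBV", c("2", "4-1", "5-1", "6-2", "7-9", "9",
                                 "11-2", "12-5", "19", "20-1", "27", "28"))
.j_catalogue <- paste0("TRBJ", c("1-1", "1-2", "1-5", "2-1", "2-3", "2-5",
                                 "2-7"))

# n distinct clonotype triples drawn from the V/J catalogue.
.random_clonotypes <- function(n, len_range) {
  out <- data.frame(v_gene = character(0), j_gene = character(0),
                    cdr3_aa = character(0), stringsAsFactors = FALSE)
  seen <- character(0)
  while (nrow(out) < n) {
    m <- n - nrow(out)
    cand <- data.frame(
      v_gene = sample(.v_catalogue, m, replace = TRUE),
      j_gene = sample(.j_catalogue, m, replace = TRUE),
      cdr3_aa = .random_cdr3(m, len_range),
      stringsAsFactors = FALSE
    )
    k <- clonotype_key(cand$v_gene, cand$j_gene, cand$cdr3_aa)
    keep <- !duplicated(k) & !(k %in% seen)
    out <- rbind(out, cand[keep, , drop = FALSE])
    seen <- c(seen, k[keep])
  }
  rownames(out) <- NULL
  out
}

#' Simulate a paired repertoire+allotype cohort with planted associations
#'
#' Carriership is sampled per unit at the configured frequencies (via a
#' two-haplotype model for LD pairs); carriers of a unit contain each of
#' its planted clonotypes with probability penetrance x depth factor,
#' non-carriers with the background prevalence; expansion counts of present
#' clonotypes are geometric. Fully reproducible under `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `cohort` (an `hla_cohort`), `truth` (data.frame
#'   mapping each planted clonotype to its unit), and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  n <- cfg$n_samples
  units <- cfg$units$unit
  freqs <- cfg$units$frequency
  n_units <- length(units)

  # carriership matrix, haplotype-sampled for LD pairs
  carrier <- matrix(FALSE, n, n_units, dimnames = list(NULL, units))
  done <- character(0)
  if (!is.null(cfg$ld)) {
    for (i in seq_len(nrow(cfg$ld))) {
      u1 <- cfg$ld$unit1[i]; u2 <- cfg$ld$unit2[i]
      probs <- .haplotype_probs(freqs[match(u1, units)],
                                freqs[match(u2, units)], cfg$ld$r[i])
      h1 <- sample.int(4L, n, replace = TRUE, prob = probs)
      h2 <- sample.int(4L, n, replace = TRUE, prob = probs)
      carrier[, u1] <- h1 <= 2L | h2 <= 2L       # haplotypes AB, Ab
      carrier[, u2] <- h1 %in% c(1L, 3L) | h2 %in% c(1L, 3L)  # AB, aB
      done <- c(done, u1, u2)
    }
  }
  for (j in seq_len(n_units)) {
    if (units[j] %in% done) next
    carrier[, j] <- stats::runif(n) < freqs[j]
  }

  # clonotype catalogues: planted first, then background, then private
  n_planted <- n_units * cfg$n_clonotypes_per_unit
  n_total <- n_planted + cfg$n_background + n * cfg$n_private
  pool <- .random_clonotypes(n_total, cfg$cdr3_length_range)
  planted <- pool[seq_len(n_planted), , drop = FALSE]
  planted$unit <- rep(units, each = cfg$n_clonotypes_per_unit)
  background <- pool[n_planted + seq_len(cfg$n_background), , drop = FALSE]
  private <- pool[n_planted + cfg$n_background + seq_len(n * cfg$n_private),
                  , drop = FALSE]

  g <- stats::runif(n, 1 - cfg$depth_variation, 1 + cfg$depth_variation)
  rgeom_exp <- function(m) {
    if (cfg$expansion_mean <= 1) rep(1L, m)
    else stats::rgeom(m, prob = 1 / cfg$expansion_mean) + 1L
  }
  unit_of_planted <- match(planted$unit, units)

  reps <- vector("list", n)
  for (i in seq_len(n)) {
    p_bg <- min(1, cfg$background_incidence * g[i])
    bg_in <- stats::runif(cfg$n_background) < p_bg
    pen <- ifelse(carrier[i, unit_of_planted], cfg$penetrance,
                  cfg$background_prevalence)
    pl_in <- stats::runif(n_planted) < pmin(1, pen * g[i])
    priv <- private[(i - 1L) * cfg$n_private + seq_len(cfg$n_private), ,
                    drop = FALSE]
    cl <- rbind(planted[pl_in, c("v_gene", "j_gene", "cdr3_aa"),
                        drop = FALSE],
                background[bg_in, , drop = FALSE], priv)
    cl$expansion <- rgeom_exp(nrow(cl))
    reps[[i]] <- new_repertoire(sprintf("S%04d", i), cl)
  }
  names(reps) <- vapply(reps, `[[`, character(1), "sample_id")

  typed <- sort(unique(hla_unit_locus(units)))
  allot <- lapply(seq_len(n), function(i) {
    hla_allotype(reps[[i]]$sample_id, units[carrier[i, ]], typed)
  })
  names(allot) <- names(reps)

  truth <- planted
  truth$penetrance <- cfg$penetrance
  list(cohort = hla_cohort(reps, allot), truth = truth, config = cfg)
}

#' Downsample a repertoire by binomial thinning
#'
#' Each clonotype's expansion is thinned binomially with retention
#' probability `fraction`; clonotypes losing all their templates drop out
#' and the depth is recomputed. Emulates shallower repertoire profiling.
#'
#' @param repertoire a `repertoire` object.
#' @param fraction retention probability in (0, 1]; 1 returns the input
#'   unchanged.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return the thinned `repertoire`.
#' @export
downsample_repertoire <- function(repertoire, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(repertoire)
  thin <- function() {
    cl <- repertoire$clonotypes
    kept <- stats::rbinom(nrow(cl), size = cl$expansion, prob = fraction)
    cl$expansion <- kept
    cl <- cl[kept > 0L, , drop = FALSE]
    new_repertoire(repertoire$sample_id, cl)
  }
  if (is.null(seed)) thin() else with_seed(seed, thin())
}

#' Write a cohort to disk as AIRR + allotype TSVs
#'
#' One AIRR Rearrangement TSV per sample under `dir/repertoires/` plus
#' `dir/allotypes.tsv`, so simulated cohorts exercise the real readers.
#'
#' @param cohort an `hla_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  rep_dir <- file.path(dir, "repertoires")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in cohort$samples) {
    write_repertoire_airr(cohort$repertoires[[id]],
                          file.path(rep_dir, paste0(id, ".tsv")))
  }
  write_allotypes(cohort$allotypes, file.path(dir, "allotypes.tsv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param expansion_mode passed to [collapse_repertoire()].
#' @return an `hla_cohort`.
#' @export
read_cohort <- function(dir, expansion_mode = "count") {
  allot <- read_allotypes(file.path(dir, "allotypes.tsv"))
  files <- sort(list.files(file.path(dir, "repertoires"),
                           pattern = "\\.tsv$", full.names = TRUE))
  reps <- lapply(files, function(f) {
    id <- sub("\\.tsv$", "", basename(f))
    collapse_repertoire(filter_productive(read_repertoire(f, "airr")),
                        sample_id = id, expansion_mode = expansion_mode)
  })
  names(reps) <- vapply(reps, `[[`, character(1), "sample_id")
  hla_cohort(reps, allot)
}
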