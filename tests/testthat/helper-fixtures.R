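# In-code fixtures shared across tests.

# A repertoire built directly from clonotype triples.
make_repertoire <- function(id, v, j, cdr3, expansion = NULL) {
  n <- length(cdr3)
  new_repertoire(id, data.frame(
    v_gene = rep_len(v, n), j_gene = rep_len(j, n), cdr3_aa = cdr3,
    expansion = expansion %||% rep(1L, n), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny hand-built cohort: 4 samples, one class-I unit, one shared
# clonotype enriched in carriers.
tiny_cohort <- function() {
  reps <- list(
    make_repertoire("s1", "TRBV19", "TRBJ2-1", c("CASSIRSSYEQYF", "CASSAAAAF")),
    make_repertoire("s2", "TRBV19", "TRBJ2-1", c("CASSIRSSYEQYF", "CASSBBBBF")),
    make_repertoire("s3", "TRBV19", "TRBJ2-1", "CASSCCCCF"),
    make_repertoire("s4", "TRBV19", "TRBJ2-1", "CASSDDDDF")
  )
  allot <- list(
    hla_allotype("s1", "A*02:01", "A"),
    hla_allotype("s2", "A*02:01", "A"),
    hla_allotype("s3", character(0), "A"),
    hla_allotype("s4", character(0), "A")
  )
  hla_cohort(reps, allot)
}

# Write a minimal AIRR Rearrangement TSV; rows is a data.frame with
# v_call, junction_aa, productive, duplicate_count (j_call optional).
write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  if (is.null(rows$j_call)) rows$j_call <- rep("TRBJ2-1*01", nrow(rows))
  utils::write.table(rows[, c("v_call", "j_call", "junction_aa",
                              "duplicate_count", "productive")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent brute-force oracle for the one-sided exact test: the
# hypergeometric upper-tail mass summed term by term with dhyper.
brute_force_upper_tail <- function(n11, n12, n21, n22) {
  K <- n11 + n12
  n <- n11 + n21
  N <- n11 + n12 + n21 + n22
  if (n11 <= 0 || K == 0 || n == 0) return(1)
  sum(stats::dhyper(n11:min(K, n), K, N - K, n))
}
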