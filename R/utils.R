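# Internal helpers shared across the package.

#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the RNG seeded to `seed`, then restores the previous
#' RNG state so that package functions do not perturb the caller's random
#' stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The 20 canonical amino-acid one-letter codes
#' @noRd
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Canonical string identity of a clonotype
#'
#' Clonotype identity is the triple (V gene, J gene, CDR3 amino-acid
#' sequence); the key concatenates the three fields with `|`, which cannot
#' occur in gene symbols or amino-acid strings.
#'
#' @param v_gene,j_gene,cdr3_aa character vectors of equal length.
#' @return character vector of keys.
#' @export
clonotype_key <- function(v_gene, j_gene, cdr3_aa) {
  paste(v_gene, j_gene, cdr3_aa, sep = "|")
}

#' Split clonotype keys back into the (V, J, CDR3) triple
#' @param key character vector of keys produced by [clonotype_key()].
#' @return data.frame with columns `v_gene`, `j_gene`, `cdr3_aa`.
#' @export
split_clonotype_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(
    v_gene  = vapply(parts, `[[`, character(1), 1L),
    j_gene  = vapply(parts, `[[`, character(1), 2L),
    cdr3_aa = vapply(parts, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

#' Normalise a V/J gene call to gene level
#'
#' Strips allele designations (`*01` suffixes) and, when a call lists several
#' comma-separated candidate genes, keeps the first listed gene. Clonotype
#' identity is defined at gene level.
#'
#' @param calls character vector of gene calls, e.g. `"TRBV19*01"`.
#' @return character vector of gene symbols, e.g. `"TRBV19"`.
#' @export
normalize_gene <- function(calls) {
  first <- vapply(strsplit(as.character(calls), ",", fixed = TRUE),
                  function(x) if (length(x)) x[[1L]] else NA_character_,
                  character(1))
  sub("\\*.*$", "", trimws(first))
}
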