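# Reading rearrangement tables, productivity filtering, and collapsing
# rearrangements into clonotypes.

#' Default column map for ImmunoSEQ-style exports
#'
#' Maps the fields needed by [read_repertoire()] to the column names used by
#' typical ImmunoSEQ v2 exports. Export dialects differ in whether abundance
#' is reported as templates or reads; point `count` at whichever column
#' should define clonotype expansion.
#'
#' @param v_gene,j_gene,cdr3_aa,count,productive column names in the file.
#' @param productive_value the value of the `productive` column that marks an
#'   in-frame, stop-free rearrangement (ImmunoSEQ uses `frame_type == "In"`).
#' @return named list usable as the `colmap` argument of [read_repertoire()].
#' @export
immunoseq_colmap <- function(v_gene = "v_resolved",
                             j_gene = "j_resolved",
                             cdr3_aa = "amino_acid",
                             count = "templates",
                             productive = "frame_type",
                             productive_value = "In") {
  list(v_gene = v_gene, j_gene = j_gene, cdr3_aa = cdr3_aa,
       count = count, productive = productive,
       productive_value = productive_value)
}

.airr_colmap <- function() {
  list(v_gene = "v_call", j_gene = "j_call", cdr3_aa = "junction_aa",
       count = "duplicate_count", productive = "productive",
       productive_value = NULL)
}

#' Read a repertoire file into rearrangement records
#'
#' Reads one sample's rearrangement table in either the AIRR Rearrangement
#' TSV dialect (columns `v_call`, `j_call`, `junction_aa`, `duplicate_count`,
#' `productive`) or an ImmunoSEQ-style TSV described by a column map. Gene
#' calls are normalised to gene level (allele suffixes such as `*01`
#' stripped); no productivity filtering happens here — see
#' [filter_productive()].
#'
#' Rows with a missing V gene, J gene or CDR3 are skipped with a single
#' warning reporting how many were dropped. Missing or zero counts are
#' treated as 1 (presence observed).
#'
#' @param path path to a TSV file.
#' @param dialect `"airr"` or `"immunoseq"`.
#' @param colmap for `dialect = "immunoseq"`, a column map as returned by
#'   [immunoseq_colmap()], or a path to a YAML/JSON-like `key: value` /
#'   `key=value` text file with the same keys.
#' @return data.frame of rearrangement records with columns `v_gene`,
#'   `j_gene`, `cdr3_aa`, `count` (integer) and `productive` (logical;
#'   `NA` when the flag could not be interpreted).
#' @export
read_repertoire <- function(path, dialect = c("airr", "immunoseq"),
                            colmap = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("repertoire file not found: ", path)
  cm <- switch(dialect,
    airr = .airr_colmap(),
    immunoseq = .resolve_colmap(colmap)
  )
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  needed <- unlist(cm[c("v_gene", "j_gene", "cdr3_aa", "count", "productive")])
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("missing mandatory column(s) for dialect '", dialect, "': ",
         paste(missing_cols, collapse = ", "))
  }
  rearrangement_records(
    v_call = tab[[cm$v_gene]],
    j_call = tab[[cm$j_gene]],
    cdr3_aa = tab[[cm$cdr3_aa]],
    count = tab[[cm$count]],
    productive = tab[[cm$productive]],
    productive_value = cm$productive_value
  )
}

.resolve_colmap <- function(colmap) {
  if (is.null(colmap)) return(immunoseq_colmap())
  if (is.character(colmap) && length(colmap) == 1L) {
    lines <- readLines(colmap, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(sub("\\s*[:=]\\s*", "\x01", lines), "\x01", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed column-map line: ", lines[bad][1L])
    vals <- trimws(vapply(kv, `[[`, character(1), 2L))
    names(vals) <- trimws(vapply(kv, `[[`, character(1), 1L))
    colmap <- as.list(vals)
  }
  base <- immunoseq_colmap()
  base[names(colmap)] <- colmap
  base
}

.parse_productive <- function(x, productive_value = NULL) {
  if (!is.null(productive_value)) return(x == productive_value)
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE", "YES", "1")] <- TRUE
  out[up %in% c("F", "FALSE", "NO", "0")] <- FALSE
  out
}

#' Build rearrangement records from raw field vectors
#'
#' @param v_call,j_call raw gene calls (allele suffixes allowed).
#' @param cdr3_aa CDR3 amino-acid sequences.
#' @param count template/read counts; missing or zero become 1.
#' @param productive raw productivity flags.
#' @param productive_value see [immunoseq_colmap()]; `NULL` parses
#'   boolean-like flags (AIRR `T`/`F`).
#' @return data.frame of records (see [read_repertoire()]).
#' @export
rearrangement_records <- function(v_call, j_call, cdr3_aa, count = NULL,
                                  productive = TRUE,
                                  productive_value = NULL) {
  n <- length(cdr3_aa)
  count <- count %||% rep(1L, n)
  cnt <- suppressWarnings(as.integer(as.numeric(count)))
  cnt[is.na(cnt) | cnt <= 0L] <- 1L
  prod <- if (is.logical(productive)) {
    rep_len(productive, n)
  } else {
    .parse_productive(productive, productive_value)
  }
  rec <- data.frame(
    v_gene = normalize_gene(v_call),
    j_gene = normalize_gene(j_call),
    cdr3_aa = trimws(as.character(cdr3_aa)),
    count = cnt,
    productive = prod,
    stringsAsFactors = FALSE
  )
  bad <- is.na(rec$v_gene) | rec$v_gene == "" |
    is.na(rec$j_gene) | rec$j_gene == "" | is.na(rec$cdr3_aa)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing V/J/CDR3 fields were skipped")
    rec <- rec[!bad, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Keep productive rearrangements with a clean CDR3
#'
#' Retains records flagged productive whose CDR3 amino-acid sequence is
#' non-empty and contains only the 20 canonical amino-acid letters.
#' Sequences containing a stop (`*`), an ambiguous residue (`X`) or any
#' other non-canonical character are removed, as are records whose
#' productivity flag is false or could not be interpreted.
#'
#' @param records data.frame from [read_repertoire()].
#' @return the filtered data.frame.
#' @export
filter_productive <- function(records) {
  ok_seq <- nzchar(records$cdr3_aa) &
    !grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")),
           records$cdr3_aa)
  keep <- !is.na(records$productive) & records$productive & ok_seq
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse rearrangements into a clonotype repertoire
#'
#' Rearrangements sharing the same V gene, J gene and CDR3 amino-acid
#' sequence (e.g. synonymous nucleotide variants) are collapsed into a
#' single clonotype. Under `expansion_mode = "count"` the expansion
#' C(c, R) of a clonotype is the summed template/read count of its member
#' records; under `"binary"` each observed clonotype has expansion 1.
#' The repertoire depth C(R) is the number of distinct clonotypes.
#'
#' @param records productivity-filtered records (see [filter_productive()]).
#' @param sample_id sample identifier attached to the repertoire.
#' @param expansion_mode `"count"` (default) or `"binary"`.
#' @return a `repertoire` object: list with `sample_id`, `clonotypes`
#'   (data.frame `v_gene`, `j_gene`, `cdr3_aa`, `expansion`) and `depth`.
#' @export
collapse_repertoire <- function(records, sample_id = "sample",
                                expansion_mode = c("count", "binary")) {
  expansion_mode <- match.arg(expansion_mode)
  if (nrow(records) == 0L) {
    warning("collapsing an empty record set: repertoire '", sample_id,
            "' has depth 0")
    return(new_repertoire(sample_id, data.frame(
      v_gene = character(0), j_gene = character(0), cdr3_aa = character(0),
      expansion = integer(0), stringsAsFactors = FALSE)))
  }
  key <- clonotype_key(records$v_gene, records$j_gene, records$cdr3_aa)
  agg <- rowsum(records$count, group = key)
  keys <- rownames(agg)
  triple <- split_clonotype_key(keys)
  triple$expansion <- if (expansion_mode == "binary") {
    rep(1L, length(keys))
  } else {
    as.integer(agg[, 1L])
  }
  new_repertoire(sample_id, triple)
}

#' Construct a repertoire object
#'
#' @param sample_id sample identifier.
#' @param clonotypes data.frame with columns `v_gene`, `j_gene`, `cdr3_aa`,
#'   `expansion` (positive integers), one row per distinct clonotype.
#' @return a `repertoire` object.
#' @export
new_repertoire <- function(sample_id, clonotypes) {
  stopifnot(all(c("v_gene", "j_gene", "cdr3_aa", "expansion") %in%
                  names(clonotypes)))
  key <- clonotype_key(clonotypes$v_gene, clonotypes$j_gene,
                       clonotypes$cdr3_aa)
  if (anyDuplicated(key)) stop("duplicate clonotypes in repertoire")
  if (nrow(clonotypes) && any(clonotypes$expansion < 1)) {
    stop("clonotype expansions must be >= 1")
  }
  ord <- order(key)
  clonotypes <- clonotypes[ord, c("v_gene", "j_gene", "cdr3_aa", "expansion"),
                           drop = FALSE]
  rownames(clonotypes) <- NULL
  structure(
    list(sample_id = as.character(sample_id), clonotypes = clonotypes,
         depth = nrow(clonotypes)),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat("<repertoire> sample:", x$sample_id,
      "| depth C(R):", x$depth,
      "| total expansion:", sum(x$clonotypes$expansion), "\n")
  invisible(x)
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' One row per clonotype with `productive = "T"`, so the file round-trips
#' through [read_repertoire()] and [collapse_repertoire()].
#'
#' @param repertoire a `repertoire` object.
#' @param path output TSV path.
#' @export
write_repertoire_airr <- function(repertoire, path) {
  cl <- repertoire$clonotypes
  out <- data.frame(
    v_call = cl$v_gene,
    j_call = cl$j_gene,
    junction_aa = cl$cdr3_aa,
    duplicate_count = cl$expansion,
    productive = rep("T", nrow(cl)),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
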