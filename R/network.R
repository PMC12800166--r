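# Clonotype-HLA graphs and antigen-specificity annotation.
#
# Two clonotype nodes are connected when they share V and J genes and their
# equal-length CDR3s differ in at most one position (Hamming distance <= 1);
# a clonotype node is connected to an HLA-unit node when the clonotype is
# restricted to that unit.

.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
        strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Should two clonotypes share a similarity edge?
#'
#' TRUE iff both V genes match, both J genes match, the CDR3s have equal
#' length and their Hamming distance is at most 1. Unequal lengths give no
#' edge (Hamming distance is undefined across lengths).
#'
#' @param c1,c2 lists or named vectors with `v_gene`, `j_gene`, `cdr3_aa`.
#' @return logical scalar.
#' @export
similarity_edge <- function(c1, c2) {
  if (c1$v_gene != c2$v_gene || c1$j_gene != c2$j_gene) return(FALSE)
  if (nchar(c1$cdr3_aa) != nchar(c2$cdr3_aa)) return(FALSE)
  .hamming(c1$cdr3_aa, c2$cdr3_aa) <= 1L
}

# All similarity edges among a clonotype table, found by bucketing on
# (V, J, CDR3 length) before pairwise comparison.
.similarity_edges <- function(clonotypes) {
  key <- clonotype_key(clonotypes$v_gene, clonotypes$j_gene,
                       clonotypes$cdr3_aa)
  bucket <- paste(clonotypes$v_gene, clonotypes$j_gene,
                  nchar(clonotypes$cdr3_aa), sep = "\x01")
  from <- character(0); to <- character(0)
  for (rows in split(seq_len(nrow(clonotypes)), bucket)) {
    m <- length(rows)
    if (m < 2L) next
    chars <- do.call(rbind, strsplit(clonotypes$cdr3_aa[rows], "",
                                     fixed = TRUE))
    for (i in seq_len(m - 1L)) {
      d <- rowSums(chars[(i + 1L):m, , drop = FALSE] !=
                     matrix(chars[i, ], m - i, ncol(chars), byrow = TRUE))
      hits <- which(d <= 1L)
      if (length(hits)) {
        from <- c(from, rep(key[rows[i]], length(hits)))
        to <- c(to, key[rows[i + hits]])
      }
    }
  }
  data.frame(from = from, to = to, type = rep("similarity", length(from)),
             stringsAsFactors = FALSE)
}

#' Build the clonotype-HLA restriction graph
#'
#' Nodes are resolved clonotypes (keyed `V|J|CDR3`) and HLA units; edges
#' are clonotype-clonotype similarity edges (see [similarity_edge()]) and
#' clonotype-unit restriction edges. Connected components group clonotypes
#' that target the same HLA neighbourhood.
#'
#' @param assignments data.frame with `v_gene`, `j_gene`, `cdr3_aa`,
#'   `unit` (e.g. the `assignments` element of [resolve_associations()]).
#' @return list with `graph` (igraph object), `edges` (data.frame `from`,
#'   `to`, `type`), and `components` (named membership vector).
#' @export
build_clonotype_graph <- function(assignments) {
  cl <- unique(assignments[, c("v_gene", "j_gene", "cdr3_aa")])
  key <- clonotype_key(cl$v_gene, cl$j_gene, cl$cdr3_aa)
  sim <- .similarity_edges(cl)
  restrict <- data.frame(
    from = clonotype_key(assignments$v_gene, assignments$j_gene,
                         assignments$cdr3_aa),
    to = assignments$unit,
    type = rep("restriction", nrow(assignments)),
    stringsAsFactors = FALSE
  )
  restrict <- unique(restrict)
  edges <- rbind(sim, restrict)
  nodes <- data.frame(name = c(key, sort(unique(assignments$unit))),
                      kind = c(rep("clonotype", length(key)),
                               rep("hla_unit",
                                   length(unique(assignments$unit)))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)$membership
  list(graph = g, edges = edges, components = comp)
}

#' Write a graph's edge list as TSV
#'
#' Generic `from / to / type` edge-list export for external visualisation
#' tools (e.g. Cytoscape).
#'
#' @param graph output of [build_clonotype_graph()].
#' @param path output TSV path.
#' @export
write_edge_list <- function(graph, path) {
  data.table::fwrite(graph$edges, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Annotate clonotypes against an antigen-specificity table
#'
#' Joins clonotypes with a local VDJdb/McPAS-like table. The default join
#' key is the CDR3 amino-acid sequence alone (how the public databases are
#' commonly keyed); `by = "vj_cdr3"` additionally requires matching V and J
#' genes. Labels of multiply-matching rows are deduplicated and collapsed
#' with `";"`; unmatched clonotypes get `NA`.
#'
#' @param clonotypes data.frame with `v_gene`, `j_gene`, `cdr3_aa`.
#' @param specificity data.frame with a CDR3 column (`cdr3_aa`, `cdr3` or
#'   `CDR3`), optionally `v_gene`/`j_gene`, and a label column.
#' @param by `"cdr3"` (default) or `"vj_cdr3"`.
#' @param label_col name of the label column; by default the first of
#'   `antigen.species`, `antigen_species`, `pathology`, `pathogen`,
#'   `antigen`, `epitope` found in the table.
#' @return `clonotypes` with an added `antigen` column.
#' @export
annotate_clonotypes <- function(clonotypes, specificity,
                                by = c("cdr3", "vj_cdr3"),
                                label_col = NULL) {
  by <- match.arg(by)
  cdr3_col <- intersect(c("cdr3_aa", "cdr3", "CDR3"), names(specificity))
  if (!length(cdr3_col)) {
    stop("specificity table lacks a CDR3 column (cdr3_aa/cdr3/CDR3)")
  }
  cdr3_col <- cdr3_col[1L]
  if (is.null(label_col)) {
    label_col <- intersect(c("antigen.species", "antigen_species",
                             "pathology", "pathogen", "antigen", "epitope"),
                           names(specificity))
    if (!length(label_col)) stop("no label column found in specificity table")
    label_col <- label_col[1L]
  }
  if (by == "vj_cdr3") {
    stopifnot(all(c("v_gene", "j_gene") %in% names(specificity)))
    tab_key <- clonotype_key(specificity$v_gene, specificity$j_gene,
                             specificity[[cdr3_col]])
    cl_key <- clonotype_key(clonotypes$v_gene, clonotypes$j_gene,
                            clonotypes$cdr3_aa)
  } else {
    tab_key <- specificity[[cdr3_col]]
    cl_key <- clonotypes$cdr3_aa
  }
  labels <- split(as.character(specificity[[label_col]]), tab_key)
  ann <- vapply(cl_key, function(k) {
    hits <- labels[[k]]
    if (is.null(hits)) NA_character_
    else paste(sort(unique(hits)), collapse = ";")
  }, character(1))
  out <- clonotypes
  out$antigen <- unname(ann)
  out
}
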