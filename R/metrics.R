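#' Estimated storage size of the original graph, in bits
#'
#' `o_edges * 2 * log2(o_nodes)`: each edge stores two node ids.
#'
#' @param o_edges Edge count of the original graph.
#' @param o_nodes Node count of the original graph (`>= 2`).
#' @return Size in bits (real-valued; no ceiling is applied).
#' @export
original_size_bits <- function(o_edges, o_nodes) {
  if (o_nodes < 2) stop("undefined size: fewer than 2 nodes")
  o_edges * 2 * log2(o_nodes)
}

#' Estimated storage size of a summary, in bits
#'
#' `s_edges * 2 * log2(s_nodes) + o_nodes * log2(s_nodes)`: the edge-type
#' entries (super edges plus both correction lists) store two ids each in the
#' summary's id space, and every original node stores its super-node
#' assignment.
#'
#' @param s_edges Total summary edge entries, `|E/| + |C+| + |C-|`.
#' @param s_nodes Super-node count (`>= 2`).
#' @param o_nodes Original node count.
#' @return Size in bits.
#' @export
summary_size_bits <- function(s_edges, s_nodes, o_nodes) {
  if (s_nodes < 2) stop("undefined size: fewer than 2 super nodes")
  s_edges * 2 * log2(s_nodes) + o_nodes * log2(s_nodes)
}

#' Compression report of a summary
#'
#' Audits losslessness (decodes the summary and compares the edge set with
#' the input graph; a mismatch is an error), then reports all counts and the
#' compression ratio `summary bits / original bits`; a ratio below 1 means
#' the summary representation is smaller than the plain edge list. The ratio
#' is `NA` (flagged `undefined`) for graphs too small for the size formulas.
#'
#' @param result A list with `summary` and `corrections` ([encode_all()] or
#'   [summarize_graph()] output).
#' @param g The original `ipgs_graph`.
#' @return A list of class `ipgs_report` with fields `o_nodes`, `o_edges`,
#'   `s_nodes`, `superedges`, `c_plus_size`, `c_minus_size`,
#'   `s_edges_total`, `size_original_bits`, `size_summary_bits`, `ratio`
#'   and `undefined`. JSON-serializable.
#' @export
compression_report <- function(result, g) {
  dec <- decode_summary(result$summary, result$corrections, g$n_nodes)
  if (!(dec$n_nodes == g$n_nodes && nrow(dec$edges) == nrow(g$edges) &&
        all(dec$edges == g$edges))) {
    stop("lossless audit failed: decoded graph differs from the input")
  }
  o_nodes <- g$n_nodes
  o_edges <- nrow(g$edges)
  s_nodes <- length(result$summary$supers)
  sup <- nrow(result$summary$superedges)
  cp <- nrow(result$corrections$c_plus)
  cm <- nrow(result$corrections$c_minus)
  s_edges <- sup + cp + cm
  undefined <- o_nodes < 2 || s_nodes < 2 || o_edges == 0
  rep <- list(
    o_nodes = o_nodes, o_edges = o_edges,
    s_nodes = s_nodes, superedges = sup,
    c_plus_size = cp, c_minus_size = cm,
    s_edges_total = s_edges,
    size_original_bits = if (o_nodes >= 2) original_size_bits(o_edges, o_nodes) else NA_real_,
    size_summary_bits = if (s_nodes >= 2) summary_size_bits(s_edges, s_nodes, o_nodes) else NA_real_,
    ratio = NA_real_,
    undefined = undefined
  )
  if (!undefined) {
    rep$ratio <- rep$size_summary_bits / rep$size_original_bits
  }
  structure(rep, class = "ipgs_report")
}

#' @export
print.ipgs_report <- function(x, ...) {
  cat(sprintf(
    "<ipgs_report> nodes %d -> %d | E/ %d, C+ %d, C- %d (total %d of %d edges) | ratio %s\n",
    x$o_nodes, x$s_nodes, x$superedges, x$c_plus_size, x$c_minus_size,
    x$s_edges_total, x$o_edges,
    if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Write a compression report as JSON
#'
#' @param report An `ipgs_report`.
#' @param path Output path (conventionally `<prefix>.report.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
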