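#' Read a SNAP-style edge list
#'
#' Parses a plain-text edge list: one edge per line as
#' `src<whitespace>dst[<whitespace>weight]`, with `#`-prefixed comment lines.
#' Labels are mapped to contiguous internal ids in order of first appearance.
#' Self-loop lines are dropped (a message reports the count); duplicate lines
#' and reversed duplicates collapse to one edge (for weighted input the first
#' weight wins, with a warning).
#'
#' @param path Path to the edge-list file.
#' @param weighted If `TRUE`, every edge line must carry a third positive
#'   integer token, stored as the edge weight.
#' @return An `ipgs_graph`; external labels are kept in `$labels`.
#' @export
read_edge_list <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(ipgs_graph(0L, NULL, weights = if (weighted) integer(0) else NULL))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  want <- if (weighted) 3L else 2L
  bad <- which(nt < want)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected %d fields, got %d",
                 lineno[bad[1L]], path, want, nt[bad[1L]]))
  }
  us <- vapply(toks, `[[`, "", 1L)
  vs <- vapply(toks, `[[`, "", 2L)
  if (weighted) {
    ws <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 3L)))
    badw <- which(is.na(ws) | ws < 1L)
    if (length(badw)) {
      stop(sprintf("parse error at line %d of %s: weight must be a positive integer",
                   lineno[badw[1L]], path))
    }
  }
  labels <- unique(c(rbind(us, vs)))   # first-appearance order
  u <- match(us, labels)
  v <- match(vs, labels)
  loops <- u == v
  if (any(loops)) {
    message(sprintf("read_edge_list: dropped %d self-loop line(s)", sum(loops)))
    u <- u[!loops]; v <- v[!loops]
    if (weighted) ws <- ws[!loops]
  }
  lo <- pmin(u, v); hi <- pmax(u, v)
  key <- paste(lo, hi)
  dup <- duplicated(key)
  if (any(dup)) {
    if (weighted) {
      first <- match(key[dup], key)
      if (any(ws[dup] != ws[first])) {
        warning("duplicate weighted edge lines with differing weights; keeping first")
      } else {
        warning(sprintf("collapsed %d duplicate edge line(s)", sum(dup)))
      }
    } else {
      warning(sprintf("collapsed %d duplicate edge line(s)", sum(dup)))
    }
    lo <- lo[!dup]; hi <- hi[!dup]
    if (weighted) ws <- ws[!dup]
  }
  ipgs_graph(length(labels), cbind(lo, hi),
             weights = if (weighted) ws else NULL, labels = labels)
}

#' Write a graph as a SNAP-style edge list
#'
#' Writes the labelled edge set in deterministic canonical order, preceded by
#' a comment header. Re-reading the file reproduces the labelled edge set
#' exactly; isolated nodes have no edge line and are dropped with a warning.
#'
#' @param g An `ipgs_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  weighted <- !is.null(g$weights)
  iso <- setdiff(seq_len(g$n_nodes), unique(as.vector(g$edges)))
  if (length(iso)) {
    warning(sprintf("%d isolated node(s) not representable in an edge list; dropped",
                    length(iso)))
  }
  d <- label_edges(g)
  hdr <- sprintf("# ipgs edge list: %d nodes, %d edges%s",
                 g$n_nodes, nrow(d), if (weighted) " (weighted)" else "")
  body <- if (weighted) paste(d$u, d$v, d$w, sep = "\t") else paste(d$u, d$v, sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Export a graph or summary for visualization tools
#'
#' Writes GraphML 1.0 or GML readable by Gephi/Cytoscape. For a summary,
#' nodes are the super nodes, each carrying a `members` attribute (comma-joined
#' member labels) and a `size` attribute (member count); edges are the super
#' edges. Target nodes (or super nodes containing a target) carry
#' `is_target = "true"`.
#'
#' @param x An `ipgs_graph`, or an `ipgs_summary_result` as returned by
#'   [summarize_graph()].
#' @param path Output path.
#' @param format `"graphml"` or `"gml"`.
#' @param targets Optional character vector of target node labels.
#' @return `path`, invisibly.
#' @export
export_visualization <- function(x, path, format = c("graphml", "gml"),
                                 targets = NULL) {
  format <- match.arg(format)
  if (inherits(x, "ipgs_graph")) {
    ig <- igraph::make_empty_graph(n = x$n_nodes, directed = FALSE)
    igraph::V(ig)$name <- x$labels
    igraph::V(ig)$members <- x$labels
    igraph::V(ig)$size <- 1
    igraph::V(ig)$is_target <- ifelse(x$labels %in% targets, "true", "false")
    if (nrow(x$edges) > 0L) {
      ig <- igraph::add_edges(ig, t(x$edges))
      igraph::E(ig)$weight <- edge_weights(x)
    }
  } else if (inherits(x, "ipgs_summary_result") || inherits(x, "ipgs_summary")) {
    sg <- if (inherits(x, "ipgs_summary_result")) x$summary else x
    labels <- sg$labels
    k <- length(sg$supers)
    ig <- igraph::make_empty_graph(n = k, directed = FALSE)
    igraph::V(ig)$name <- paste0("S", sg$supers)
    igraph::V(ig)$members <- vapply(
      sg$members, function(m) paste(labels[m], collapse = ","), ""
    )
    igraph::V(ig)$size <- lengths(sg$members)
    has_target <- vapply(
      sg$members, function(m) any(labels[m] %in% targets), NA
    )
    igraph::V(ig)$is_target <- ifelse(has_target, "true", "false")
    if (nrow(sg$superedges) > 0L) {
      pos <- cbind(match(sg$superedges[, 1L], sg$supers),
                   match(sg$superedges[, 2L], sg$supers))
      # igraph disallows loop-free manipulation surprises: self super edges
      # are legal here and kept
      ig <- igraph::add_edges(ig, t(pos))
    }
  } else {
    stop("unsupported object for export")
  }
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}
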