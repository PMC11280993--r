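#' Cumulative flow rates from a target set
#'
#' Influence is propagated outward from the targets along minimum-hop paths:
#' nodes are layered by BFS distance from the target set, and the cumulative
#' flow rate of a node `v` in layer `d` is
#' `r(v) = max over neighbors u in layer d-1 of r(u) + w(u, v)`,
#' with `r(t) = 0` for every target `t`. The arg-max neighbor is recorded as
#' the flow-path predecessor (ties broken toward the smallest id). Nodes
#' unreachable from the targets carry no rate.
#'
#' @param g An `ipgs_graph` (unweighted graphs use unit weights).
#' @param targets Integer node ids, or character labels, of the target set.
#' @return A list of class `ipgs_flow`: `targets` (ids), `r` (named numeric
#'   vector of rates for reachable nodes), `parent` (named integer vector of
#'   predecessors; `NA` for targets).
#' @export
flow_rates <- function(g, targets) {
  if (length(targets) == 0L) stop("empty target set")
  if (is.character(targets)) {
    idx <- match(targets, g$labels)
    if (anyNA(idx)) stop("unknown target label: ", targets[which(is.na(idx))[1L]])
    targets <- idx
  }
  targets <- sort(unique(as.integer(targets)))
  if (any(targets < 1L | targets > g$n_nodes)) stop("target id out of range")
  adj <- adjacency(g)
  n <- g$n_nodes
  dist <- rep(NA_integer_, n)
  r <- rep(NA_real_, n)
  parent <- rep(NA_integer_, n)
  dist[targets] <- 0L
  r[targets] <- 0
  frontier <- targets
  d <- 0L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- adj$nbr[[u]]
      nxt <- c(nxt, nb[is.na(dist[nb])])
    }
    nxt <- sort(unique(nxt))
    if (length(nxt) == 0L) break
    dist[nxt] <- d + 1L
    for (v in nxt) {
      nb <- adj$nbr[[v]]
      w <- adj$w[[v]]
      prev <- which(!is.na(dist[nb]) & dist[nb] == d)
      cand <- r[nb[prev]] + w[prev]
      best <- max(cand)
      # tie-break: smallest predecessor id
      r[v] <- best
      parent[v] <- min(nb[prev][cand == best])
    }
    frontier <- nxt
    d <- d + 1L
  }
  reach <- which(!is.na(r))
  structure(
    list(targets = targets,
         r = stats::setNames(r[reach], reach),
         parent = stats::setNames(parent[reach], reach)),
    class = "ipgs_flow"
  )
}

#' @export
print.ipgs_flow <- function(x, ...) {
  cat(sprintf("<ipgs_flow> %d target(s), %d reachable node(s), max rate %g\n",
              length(x$targets), length(x$r), max(x$r)))
  invisible(x)
}

#' Personalized edge importance
#'
#' Scales each edge by how close it is (in flow-rate terms) to the targets:
#' with the normalized rate `rho(v) = r(v) / max(r)` (targets get 1,
#' unreachable nodes 0), the importance of edge `(u, v)` is
#' `1 + alpha * max(rho(u), rho(v))`. With `alpha = 0` every edge has
#' importance 1 and the personalized machinery degenerates to the plain one.
#' Importance is invariant to rescaling all edge weights by a positive
#' constant.
#'
#' @param g An `ipgs_graph`.
#' @param fr An `ipgs_flow` from [flow_rates()] on `g`.
#' @param alpha Non-negative personalization strength.
#' @return Numeric vector of importances (`>= 1`), aligned with `g$edges`.
#' @export
edge_importance <- function(g, fr, alpha) {
  stopifnot(alpha >= 0)
  rho <- rep(0, g$n_nodes)
  rmax <- max(fr$r)
  if (rmax > 0) rho[as.integer(names(fr$r))] <- fr$r / rmax
  rho[fr$targets] <- 1
  if (nrow(g$edges) == 0L) return(numeric(0))
  1 + alpha * pmax(rho[g$edges[, 1L]], rho[g$edges[, 2L]])
}

#' Extract the personalized flow view
#'
#' Keeps the `l` flow paths (target-to-node predecessor chains) with the
#' largest terminal rates, plus every node on them; retained non-target
#' nodes are contracted along their predecessor chains into at most `k`
#' super nodes. The objective is the sum of the selected terminal rates.
#' The view is deliberately lossy — it is a visualization aid, not a
#' summary representation.
#'
#' @param g An `ipgs_graph`.
#' @param fr An `ipgs_flow` from [flow_rates()] on `g`.
#' @param k Maximum number of non-target super nodes to retain.
#' @param l Number of flows to retain (truncated with a warning when it
#'   exceeds the number of reachable non-target nodes).
#' @return A list with `view` (an `ipgs_summary` over the retained nodes,
#'   relabelled to the original labels) and `objective`.
#' @export
flow_view <- function(g, fr, k, l) {
  stopifnot(k >= 1L, l >= 1L)
  ids <- as.integer(names(fr$r))
  nont <- ids[!(ids %in% fr$targets)]
  if (length(nont) == 0L) stop("no reachable non-target nodes")
  ord <- nont[order(-fr$r[as.character(nont)], nont)]
  if (l > length(ord)) {
    warning(sprintf("l = %d exceeds the %d reachable flows; truncated",
                    l, length(ord)))
    l <- length(ord)
  }
  sel <- ord[seq_len(l)]
  objective <- sum(fr$r[as.character(sel)])
  # retained = targets + selected terminals + their predecessor chains
  retained <- fr$targets
  for (v in sel) {
    while (!is.na(v) && !(v %in% retained)) {
      retained <- c(retained, v)
      v <- fr$parent[as.character(v)]
    }
  }
  retained <- sort(unique(retained))
  cluster <- stats::setNames(retained, retained)  # initial: singleton per node
  nt <- setdiff(retained, fr$targets)
  # contract chains: repeatedly fold the smallest-rate node into its
  # predecessor's cluster until at most k non-target clusters remain
  repeat {
    nclust <- length(unique(cluster[as.character(nt)]))
    if (nclust <= k) break
    byrate <- nt[order(fr$r[as.character(nt)], nt)]
    folded <- FALSE
    for (v in byrate) {
      p <- fr$parent[as.character(v)]
      if (!is.na(p) && !(p %in% fr$targets) &&
          cluster[as.character(p)] != cluster[as.character(v)]) {
        cluster[cluster == cluster[as.character(v)]] <- cluster[as.character(p)]
        folded <- TRUE
        break
      }
    }
    if (!folded) break  # irreducible: every chain hangs off a target
  }
  # build the view as a summary graph over the retained induced subgraph
  supers <- sort(unique(as.integer(cluster)))
  members <- lapply(supers, function(s) sort(retained[cluster == s]))
  keep <- g$edges[, 1L] %in% retained & g$edges[, 2L] %in% retained
  ed <- g$edges[keep, , drop = FALSE]
  node2cl <- stats::setNames(as.integer(cluster), names(cluster))
  if (nrow(ed) > 0L) {
    sa <- node2cl[as.character(ed[, 1L])]
    sb <- node2cl[as.character(ed[, 2L])]
    se <- unique(cbind(pmin(sa, sb), pmax(sa, sb)))
    se <- se[se[, 1L] != se[, 2L] |
               lengths(members)[match(se[, 1L], supers)] > 1L, , drop = FALSE]
    se <- se[order(se[, 1L], se[, 2L]), , drop = FALSE]
  } else {
    se <- matrix(integer(0), ncol = 2L)
  }
  view <- structure(
    list(supers = supers, members = members, superedges = se,
         labels = g$labels, n_nodes = g$n_nodes),
    class = "ipgs_summary"
  )
  list(view = view, objective = objective)
}
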