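#' Rank or product-moment correlation
#'
#' Spearman correlation is the Pearson correlation of mid-ranks (ties get
#' average ranks); Pearson is the standard product-moment coefficient.
#' Errors on degenerate input rather than returning NA.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation in \[-1, 1\].
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in ",
         if (stats::sd(x) == 0) "x" else "y")
  }
  cor(x, y, method = "pearson")
}

# internal: compute one named measure on a graph at a given level.
# Edge measures: or / fr / afr / ebc / emb / dis.
# Vertex measures: or / fr / afr (incident-edge sums), deg / bc / cc.
# `cache` is an environment used to share curvature tables between the two
# members of a pair computed on the same sample graph.
compute_measure <- function(g, name, level, alpha, cache = new.env()) {
  key <- paste0(level, ".", name)
  if (!is.null(cache[[key]])) return(cache[[key]])
  edge_tab <- function(nm) {
    k <- paste0("tab.", nm)
    if (is.null(cache[[k]])) {
      cache[[k]] <- switch(nm,
        or  = ollivier_curvature(g, alpha),
        fr  = forman_curvature(g),
        afr = augmented_forman_curvature(g),
        ebc = edge_betweenness_centrality(g),
        emb = embeddedness(g),
        dis = dispersion(g),
        stop("unknown edge measure: ", nm))
    }
    cache[[k]]
  }
  val <- if (level == "edge") {
    edge_tab(name)$value
  } else {
    switch(name,
      or  = vertex_curvature(g, edge_tab("or"))$value,
      fr  = vertex_curvature(g, edge_tab("fr"))$value,
      afr = vertex_curvature(g, edge_tab("afr"))$value,
      deg = vertex_degree(g)$value,
      bc  = vertex_betweenness(g)$value,
      cc  = clustering_coefficient(g)$value,
      stop("unknown vertex measure: ", name))
  }
  cache[[key]] <- val
  val
}

#' Ensemble correlation between two measures
#'
#' Draws `n_samples` seeded graphs from a model specification, restricts
#' each to its largest connected component, computes the two measures at
#' the requested level on it, and correlates them. The reported mean is
#' the arithmetic mean of the per-sample correlations (rounded to two
#' decimals only at the printing layer). Samples on which the correlation
#' is undefined (zero variance) are excluded with a recorded count.
#' Sample i uses seed `base_seed + i - 1`.
#'
#' @param spec A [model_spec()].
#' @param pair Character vector of two measure names. Edge level:
#'   `"or"`, `"fr"`, `"afr"`, `"ebc"`, `"emb"`, `"dis"`. Vertex level:
#'   `"or"`, `"fr"`, `"afr"`, `"deg"`, `"bc"`, `"cc"`.
#' @param level `"edge"` or `"vertex"`.
#' @param n_samples Number of ensemble samples (the reference protocol
#'   uses 100).
#' @param alpha Idleness for Ollivier-Ricci curvature.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param base_seed Integer; seeds are `base_seed + 0:(n_samples-1)`.
#' @return A list of class `correlation_report` with fields `pair`,
#'   `level`, `method`, `per_sample`, `mean`, `n_samples`, `n_dropped`,
#'   `spec`, `alpha`.
#' @export
ensemble_correlation <- function(spec, pair, level = c("edge", "vertex"),
                                 n_samples = 100, alpha = 0.5,
                                 method = c("spearman", "pearson"),
                                 base_seed = 1) {
  level <- match.arg(level)
  method <- match.arg(method)
  stopifnot(length(pair) == 2L)
  per <- numeric(0)
  dropped <- 0L
  for (i in seq_len(n_samples)) {
    g <- largest_connected_component(sample_network(spec, base_seed + i - 1L))
    cache <- new.env()
    r <- tryCatch({
      x <- compute_measure(g, pair[1L], level, alpha, cache)
      y <- compute_measure(g, pair[2L], level, alpha, cache)
      rank_correlation(x, y, method)
    }, error = function(e) NA_real_)
    if (is.na(r)) dropped <- dropped + 1L else per <- c(per, r)
  }
  structure(list(pair = pair, level = level, method = method,
                 per_sample = per, mean = mean(per),
                 n_samples = length(per), n_dropped = dropped,
                 spec = spec, alpha = alpha),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("%s correlation of %s vs %s (%s level): %.2f over %d samples",
              x$method, x$pair[1L], x$pair[2L], x$level, x$mean, x$n_samples))
  if (x$n_dropped > 0L) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Many ensemble correlations from shared samples
#'
#' Computes several measure pairs (possibly at both levels) on the *same*
#' sequence of sampled graphs, sharing the expensive curvature tables
#' between pairs. Equivalent to repeated [ensemble_correlation()] calls
#' with the same `base_seed`, but each sample graph and each measure is
#' computed once.
#'
#' @inheritParams ensemble_correlation
#' @param pairs A list; each element is `list(pair = c(a, b), level = ...)`.
#' @return A list of `correlation_report` objects, one per requested pair.
#' @export
ensemble_correlations <- function(spec, pairs, n_samples = 100, alpha = 0.5,
                                  method = "spearman", base_seed = 1) {
  acc <- lapply(pairs, function(p) list(per = numeric(0), dropped = 0L))
  for (i in seq_len(n_samples)) {
    g <- largest_connected_component(sample_network(spec, base_seed + i - 1L))
    cache <- new.env()
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      r <- tryCatch({
        x <- compute_measure(g, p$pair[1L], p$level, alpha, cache)
        y <- compute_measure(g, p$pair[2L], p$level, alpha, cache)
        rank_correlation(x, y, method)
      }, error = function(e) NA_real_)
      if (is.na(r)) acc[[k]]$dropped <- acc[[k]]$dropped + 1L
      else acc[[k]]$per <- c(acc[[k]]$per, r)
    }
  }
  lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    structure(list(pair = p$pair, level = p$level, method = method,
                   per_sample = acc[[k]]$per, mean = mean(acc[[k]]$per),
                   n_samples = length(acc[[k]]$per),
                   n_dropped = acc[[k]]$dropped, spec = spec, alpha = alpha),
              class = "correlation_report")
  })
}

#' Communication efficiency
#'
#' `E = 1 / (n (n - 1)) * sum_{i < j} 1 / d_ij` over unordered vertex
#' pairs, where `d_ij` is the hop distance and unreachable pairs contribute
#' exactly 0. With this normalization the complete graph attains E = 1/2.
#' `n_reference` is the vertex count of the intact network so that curves
#' under vertex removal remain comparable.
#'
#' @param g An igraph object (possibly after removals).
#' @param n_reference Reference vertex count (default: `vcount(g)`).
#' @return Nonnegative scalar.
#' @export
communication_efficiency <- function(g, n_reference = igraph::vcount(g)) {
  stopifnot(n_reference >= 2)
  if (igraph::ecount(g) == 0L || igraph::vcount(g) < 2L) return(0)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d[upper.tri(d)]
  sum(inv[is.finite(inv)]) / (n_reference * (n_reference - 1))
}

#' Robustness experiment under ranked removal
#'
#' Ranks the edges (or vertices) of the intact graph once by the chosen
#' strategy, removes them cumulatively in that order, and evaluates
#' communication efficiency at each fraction of the grid, holding the
#' reference vertex count fixed at the intact value. Ties in the ranking
#' are broken by ascending edge (u, v) / vertex id for reproducibility.
#'
#' Strategies (edge removal): `"random"`, `"fr_asc"`, `"afr_asc"`,
#' `"or_asc"` (curvature, most negative first), `"ebc_desc"` (edge
#' betweenness, largest first). Vertex removal additionally supports
#' `"bc_desc"`, `"deg_desc"`, `"cc_desc"`.
#'
#' @param g A connected igraph object (apply [largest_connected_component()] first).
#' @param unit `"edge"` or `"vertex"`.
#' @param strategy Removal strategy label.
#' @param fractions Increasing grid of removal fractions in \[0, 1\].
#' @param alpha Idleness for Ollivier-Ricci rankings.
#' @param seed Seed for the `"random"` strategy.
#' @return A list of class `removal_curve` with fields `strategy`, `unit`,
#'   `fractions`, `efficiency`.
#' @export
removal_experiment <- function(g, unit = c("edge", "vertex"), strategy,
                               fractions = seq(0, 1, by = 0.02),
                               alpha = 0.5, seed = 1) {
  unit <- match.arg(unit)
  stopifnot(!is.unsorted(fractions), all(fractions >= 0), all(fractions <= 1))
  edge_strats <- c("random", "fr_asc", "afr_asc", "or_asc", "ebc_desc")
  vert_strats <- c("random", "fr_asc", "afr_asc", "or_asc",
                   "bc_desc", "deg_desc", "cc_desc")
  allowed <- if (unit == "edge") edge_strats else vert_strats
  if (!strategy %in% allowed) {
    stop("unknown strategy '", strategy, "' for ", unit, " removal")
  }
  n_ref <- igraph::vcount(g)
  n_units <- if (unit == "edge") igraph::ecount(g) else igraph::vcount(g)

  score <- switch(strategy,
    random   = { set.seed(seed); runif(n_units) },
    fr_asc   = { tab <- forman_curvature(g)
                 if (unit == "vertex") vertex_curvature(g, tab)$value else tab$value },
    afr_asc  = { tab <- augmented_forman_curvature(g)
                 if (unit == "vertex") vertex_curvature(g, tab)$value else tab$value },
    or_asc   = { tab <- ollivier_curvature(g, alpha)
                 if (unit == "vertex") vertex_curvature(g, tab)$value else tab$value },
    ebc_desc = -edge_betweenness_centrality(g)$value,
    bc_desc  = -vertex_betweenness(g)$value,
    deg_desc = -vertex_degree(g)$value,
    cc_desc  = -clustering_coefficient(g)$value)

  # deterministic tie-break: ascending (u, v) lexicographic id / vertex id
  if (unit == "edge") {
    el <- igraph::as_edgelist(g, names = FALSE)
    ord <- order(score, pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  } else {
    ord <- order(score, seq_len(n_units))
  }

  counts <- pmin(floor(fractions * n_units), n_units)
  eff <- numeric(length(fractions))
  for (k in seq_along(fractions)) {
    nrem <- counts[k]
    h <- if (nrem == 0L) g else if (unit == "edge") {
      igraph::delete_edges(g, ord[seq_len(nrem)])
    } else {
      igraph::delete_vertices(g, ord[seq_len(nrem)])
    }
    eff[k] <- communication_efficiency(h, n_reference = n_ref)
  }
  structure(list(strategy = strategy, unit = unit,
                 fractions = fractions, efficiency = eff),
            class = "removal_curve")
}

#' @export
print.removal_curve <- function(x, ...) {
  cat("Removal curve (", x$unit, ", strategy ", x$strategy, "), ",
      length(x$fractions), " grid points, AUC = ",
      format(removal_auc(x)), "\n", sep = "")
  invisible(x)
}

#' Area under a removal curve
#'
#' Trapezoidal area of efficiency against removed fraction; smaller area
#' means faster disintegration.
#'
#' @param curve A `removal_curve`.
#' @return Nonnegative scalar.
#' @export
removal_auc <- function(curve) {
  f <- curve$fractions; e <- curve$efficiency
  sum(diff(f) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
}

#' Order removal strategies by disintegration speed
#'
#' Compares removal curves that share the same grid (and intact graph) by
#' their area under the curve and reports them sorted ascending, i.e.
#' fastest-disintegrating strategy first.
#'
#' @param curves A list of `removal_curve` objects on a common grid.
#' @return Data frame with columns `strategy` and `auc`, ascending by `auc`.
#' @export
targeted_vs_random_gap <- function(curves) {
  stopifnot(length(curves) >= 1L)
  grids <- lapply(curves, `[[`, "fractions")
  if (!all(vapply(grids, function(gr) identical(gr, grids[[1L]]), TRUE))) {
    stop("removal curves do not share a common fraction grid")
  }
  out <- data.frame(
    strategy = vapply(curves, `[[`, "", "strategy"),
    auc = vapply(curves, removal_auc, 1.0))
  out[order(out$auc), , drop = FALSE]
}
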