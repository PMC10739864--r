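#' Estimate rescaled cluster affinities from a partition
#'
#' Given a graph and a partition into `k` clusters, estimates the planted-SBM
#' probabilities as edge densities: `w_in_hat` = intra-cluster edges over
#' intra-cluster pairs, `w_out_hat` = inter-cluster edges over inter-cluster
#' pairs, and rescales to affinities `c_in = N w_in_hat`,
#' `c_out = N w_out_hat`, `c = (c_in + c_out) / 2`. Singleton clusters
#' contribute no intra pairs and are excluded from the intra denominator
#' (with a message).
#'
#' @param graph An igraph object.
#' @param partition A partition covering all graph nodes (see
#'   [as_partition()]) with at least 2 clusters.
#' @return An object of class `nb_affinity`: list with `c_in`, `c_out`, `c`,
#'   `w_in_hat`, `w_out_hat`, `k`, `N`, `n_intra_edges`, `n_inter_edges`.
#' @export
estimate_affinities <- function(graph, partition) {
  nodes <- graph_nodes(graph)
  lab <- partition_labels(partition, nodes)
  sizes <- table(lab)
  k <- length(sizes)
  if (k < 2L) abort("estimate_affinities needs at least 2 clusters")
  N <- length(nodes)

  el <- igraph::as_edgelist(graph)
  li <- lab[match(el[, 1], nodes)]
  lj <- lab[match(el[, 2], nodes)]
  n_intra <- sum(li == lj)
  n_inter <- sum(li != lj)

  ns <- as.numeric(sizes)
  if (any(ns == 1L)) {
    inform(paste0("estimate_affinities: ", sum(ns == 1L),
                  " singleton cluster(s) excluded from the intra denominator"))
  }
  intra_pairs <- sum(ns * (ns - 1) / 2)
  inter_pairs <- (N^2 - sum(ns^2)) / 2
  if (intra_pairs == 0) abort("all clusters are singletons; intra density undefined")

  w_in_hat <- n_intra / intra_pairs
  w_out_hat <- if (inter_pairs > 0) n_inter / inter_pairs else 0
  c_in <- N * w_in_hat
  c_out <- N * w_out_hat

  structure(list(c_in = c_in, c_out = c_out, c = (c_in + c_out) / 2,
                 w_in_hat = w_in_hat, w_out_hat = w_out_hat,
                 k = k, N = N, n_intra_edges = n_intra, n_inter_edges = n_inter),
            class = "nb_affinity")
}

#' @export
#' @method print nb_affinity
print.nb_affinity <- function(x, ...) {
  cat("<nb_affinity> k = ", x$k, ", N = ", x$N, "\n", sep = "")
  cat(sprintf("  c_in = %.3f (w_in_hat = %.4f), c_out = %.3f (w_out_hat = %.4f), c = %.3f\n",
              x$c_in, x$w_in_hat, x$c_out, x$w_out_hat, x$c))
  invisible(x)
}

#' @export
tidy.nb_affinity <- function(x, ...) {
  tibble(k = x$k, N = x$N, c_in = x$c_in, c_out = x$c_out, c = x$c,
         w_in_hat = x$w_in_hat, w_out_hat = x$w_out_hat)
}

#' Detectability condition for SBM-like community structure
#'
#' Communities of a sparse planted SBM are asymptotically resolvable only
#' when `c_in - c_out > k * sqrt(c)`. Returns the verdict together with the
#' signed margin `c_in - c_out - k sqrt(c)`.
#'
#' @param est An `nb_affinity` object (or anything with `c_in`, `c_out`, `c`
#'   fields).
#' @param k Cluster count; defaults to `est$k`.
#' @return A list with `detectable` (logical), `margin`, `gap`
#'   (`c_in - c_out`) and `threshold` (`k sqrt(c)`).
#' @export
detectable <- function(est, k = est$k) {
  gap <- est$c_in - est$c_out
  threshold <- k * sqrt(est$c)
  list(detectable = gap > threshold, margin = gap - threshold,
       gap = gap, threshold = threshold)
}

#' Select the maximal resolvable number of clusters
#'
#' Clusters the graph for each `k` in `k_range` with [spectral_cluster()],
#' estimates affinities from each partition, and evaluates the detectability
#' condition per `k`. The two diagnostic curves — the affinity gap
#' `c_in - c_out` and the threshold `k sqrt(c)` — cross at the resolution
#' limit; `k_max` is the largest `k` at which the gap still exceeds the
#' threshold. When the condition already fails at the smallest `k`, `k_max`
#' is 1 (no resolvable structure) with a warning.
#'
#' The closed-form diagnostic `(w_in_hat - w_out_hat) / w_bar * sqrt(N)`
#' (with `w_bar = c / N`) is reported as a column but plays no role in the
#' selection, which uses the direct per-`k` test.
#'
#' @param graph A connected igraph object.
#' @param k_range Integer vector of cluster counts to scan; defaults to
#'   `2:K` where `K` is the number of isolated flow eigenvalues.
#' @param operator Operator passed to [spectral_cluster()].
#' @param seed Integer seed (shared across the scan).
#' @param ... Further arguments to [spectral_cluster()].
#' @return An object of class `nb_kmax`: list with `k_max` and `table`, a
#'   tibble with columns `k`, `c_in`, `c_out`, `c`, `gap`, `threshold`,
#'   `margin`, `detectable`, `k_closed_form`.
#' @export
select_kmax <- function(graph, k_range = NULL, operator = "flow", seed = 1L, ...) {
  if (is.null(k_range)) {
    spec <- nb_spectrum(graph, kind = "flow", seed = seed)
    K <- max(length(spec$isolated), 2L)
    k_range <- seq(2L, K)
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L) abort("k_range must start at 2 or above")

  rows <- purrr::map_dfr(k_range, function(k) {
    fit <- spectral_cluster(graph, operator = operator, k = k, seed = seed, ...)
    est <- estimate_affinities(graph, fit)
    d <- detectable(est, k = k)
    tibble(k = k, c_in = est$c_in, c_out = est$c_out, c = est$c,
           gap = d$gap, threshold = d$threshold, margin = d$margin,
           detectable = d$detectable,
           k_closed_form = if (est$c > 0)
             (est$w_in_hat - est$w_out_hat) / (est$c / est$N) * sqrt(est$N)
           else NA_real_)
  })

  if (!any(rows$detectable)) {
    warn("detectability fails already at the smallest k; returning k_max = 1")
    k_max <- 1L
  } else {
    k_max <- max(rows$k[rows$detectable])
  }
  structure(list(k_max = k_max, table = rows, operator = operator,
                 seed = as.integer(seed)),
            class = "nb_kmax")
}

#' @export
#' @method print nb_kmax
print.nb_kmax <- function(x, ...) {
  cat("<nb_kmax> operator = ", x$operator, ", k_max = ", x$k_max, "\n", sep = "")
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @export
tidy.nb_kmax <- function(x, ...) x$table

#' @export
glance.nb_kmax <- function(x, ...) {
  tibble(operator = x$operator, k_max = x$k_max,
         k_scanned = nrow(x$table), seed = x$seed)
}
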