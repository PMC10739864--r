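#' Spectrum of a non-backtracking edge operator
#'
#' Computes the `n_eig` largest-real-part eigenpairs of the (non-symmetric)
#' flow or Hashimoto matrix together with the bulk radius ([bulk_radius()])
#' and the indices of the isolated eigenvalues ([find_isolated()]). The
#' number of isolated eigenvalues estimates the number of communities.
#'
#' Small operators (or requests close to full rank) are solved densely with
#' [base::eigen()]; larger ones with a sparse Arnoldi solve. Complex-conjugate
#' pairs are both retained.
#'
#' @param graph An igraph object. For `kind = "flow"` it must have minimum
#'   degree 2; pass the graph through [two_core()] first (done automatically,
#'   with a message, when leaves are present).
#' @param kind `"flow"` (default) or `"hashimoto"`.
#' @param n_eig Number of eigenpairs to compute (capped at `M - 2` for the
#'   sparse path).
#' @param seed Integer seed for the Arnoldi start vector.
#' @param imag_tol,margin Passed to [find_isolated()].
#' @return An object of class `nb_spectrum`: list with `values` (complex,
#'   sorted by descending real part), `vectors` (complex `M x n_eig`),
#'   `bulk_radius`, `isolated` (indices), `edge_index`, `graph`, `kind`.
#' @export
nb_spectrum <- function(graph, kind = c("flow", "hashimoto"), n_eig = 24L,
                        seed = 1L, imag_tol = 1e-6, margin = 0.02) {
  kind <- match.arg(kind)
  if (n_eig < 2L) abort("n_eig must be at least 2")
  if (kind == "flow" && any(igraph::degree(graph) < 2L)) {
    inform("nb_spectrum: pruning to the 2-core for the flow matrix")
    graph <- two_core(graph)$graph
  }
  if (igraph::ecount(graph) == 0L) abort("nb_spectrum: graph has no edges")

  edge_index <- directed_edge_index(graph)
  op <- if (kind == "flow") build_flow(graph, edge_index) else
    build_hashimoto(graph, edge_index)
  M <- nrow(op)

  eig <- eigs_largest_real(op, n_eig, seed)

  r <- bulk_radius(graph)
  out <- structure(
    list(values = eig$values, vectors = eig$vectors, bulk_radius = r,
         isolated = integer(), edge_index = edge_index, graph = graph,
         kind = kind, n_eig = length(eig$values)),
    class = "nb_spectrum")
  out$isolated <- find_isolated(out, imag_tol = imag_tol, margin = margin)
  out
}

# dense/sparse dispatch; returns eigenpairs sorted by descending real part
# (ties: descending imaginary part, so a conjugate pair is adjacent with the
# positive-imaginary member first)
eigs_largest_real <- function(op, n_eig, seed) {
  M <- nrow(op)
  n_eig <- as.integer(min(n_eig, M))
  dense <- M <= 400L || n_eig > M - 3L
  if (dense) {
    e <- eigen(as.matrix(op))
    vals <- as.complex(e$values)
    vecs <- matrix(as.complex(e$vectors), nrow = M)
  } else {
    X <- methods::as(methods::as(op, "generalMatrix"), "CsparseMatrix")
    # escalate the Krylov subspace on partial convergence
    subdim <- min(M, max(5L * n_eig, 128L))
    maxiter <- 300L
    res <- NULL
    for (attempt in 1:4) {
      res <- withr::with_seed(seed + attempt - 1L,
        eigs_lr_sparse(X, as.integer(n_eig), as.integer(maxiter),
                       as.integer(subdim)))
      if (res$nconv >= n_eig) break
      subdim <- min(M, subdim + (subdim %/% 2L))
      maxiter <- 2L * maxiter
    }
    if (res$nconv < n_eig) {
      warn(paste0("eigensolver converged only ", res$nconv, " of ", n_eig,
                  " requested eigenpairs"))
    }
    vals <- res$values
    vecs <- res$vectors
  }
  o <- order(-Re(vals), -Im(vals))
  vals <- vals[o]
  vecs <- vecs[, o, drop = FALSE]
  keep <- seq_len(min(n_eig, length(vals)))
  list(values = vals[keep], vectors = vecs[, keep, drop = FALSE])
}

#' Identify isolated eigenvalues
#'
#' An eigenvalue is isolated when it is (numerically) real and lies strictly
#' outside the bulk disc: `|Im(lambda)| <= imag_tol * max(1, |lambda|)` and
#' `|lambda| > r * (1 + margin)`. The trivial Perron eigenvalue (index 1) is
#' always classified as isolated, even when it sits on the bulk boundary as
#' it does for regular graphs.
#'
#' @param spectrum An `nb_spectrum` object.
#' @param imag_tol Relative imaginary-part tolerance.
#' @param margin Relative margin above the bulk radius.
#' @return Integer indices into `spectrum$values`, sorted by descending real
#'   part (index 1 always present).
#' @export
find_isolated <- function(spectrum, imag_tol = 1e-6, margin = 0.02) {
  v <- spectrum$values
  r <- spectrum$bulk_radius
  real_enough <- abs(Im(v)) <= imag_tol * pmax(1, Mod(v))
  outside <- Mod(v) > r * (1 + margin)
  idx <- which(real_enough & outside)
  sort(unique(c(1L, idx)))
}

#' Project edge-space eigenvectors onto nodes
#'
#' The flow eigenvectors live on directed edges; the node coordinate is the
#' total in-flow `u_i = sum_j A_ij v_{j->i}` (sum of the eigenvector
#' components over the directed edges pointing into `i`). Solvers return
#' eigenvectors up to a global complex phase; each vector is rotated by the
#' phase maximising the norm of its real part before projection, and for
#' isolated (real) eigenvalues the residual imaginary part is checked to be
#' numerically zero.
#'
#' @param spectrum An `nb_spectrum` object.
#' @param which Integer indices of eigenvectors to project. With
#'   `check_isolated = TRUE` (default) they must be isolated.
#' @param check_isolated Require the indices to be isolated eigenvalues and
#'   assert the rotated vectors are real.
#' @return A real `N x length(which)` matrix with vertex-name rownames
#'   (columns keep the requested order).
#' @export
edge_to_node <- function(spectrum, which = spectrum$isolated,
                         check_isolated = TRUE) {
  if (check_isolated && !all(which %in% spectrum$isolated)) {
    abort("edge_to_node: requested eigenvector index is not isolated")
  }
  U <- matrix(0, nrow = igraph::vcount(spectrum$graph), ncol = length(which),
              dimnames = list(graph_nodes(spectrum$graph), NULL))
  for (j in seq_along(which)) {
    pr <- project_edge_vector(spectrum, which[j])
    if (check_isolated && pr$resid > 1e-6) {
      abort(paste0("edge_to_node: eigenvector ", which[j],
                   " is not real after phase rotation (residual ",
                   format(pr$resid, digits = 3), ")"))
    }
    U[, j] <- Re(pr$u)
  }
  U
}

# phase-rotate eigenvector `j` and project to nodes; returns the complex node
# vector and the relative imaginary residual of the rotated edge vector
project_edge_vector <- function(spectrum, j) {
  nodes <- graph_nodes(spectrum$graph)
  heads <- match(spectrum$edge_index$to, nodes)
  v <- rotate_to_real(spectrum$vectors[, j])
  resid <- sqrt(sum(Im(v)^2)) / max(sqrt(sum(Mod(v)^2)), .Machine$double.eps)
  u <- complex(real = 0, imaginary = 0) * numeric(length(nodes))
  re <- rowsum(Re(v), group = heads)
  im <- rowsum(Im(v), group = heads)
  u[as.integer(rownames(re))] <- complex(real = re[, 1], imaginary = im[, 1])
  list(u = u, resid = resid)
}

# remove the global complex phase: rotate v by the angle maximising
# ||Re(e^{-i theta} v)||, i.e. theta = Arg(sum v_j^2) / 2
rotate_to_real <- function(v) {
  s <- sum(v^2)
  if (Mod(s) < .Machine$double.eps) return(v)
  w <- v * exp(-1i * Arg(s) / 2)
  # of the two antipodal solutions pick the one with non-negative first
  # significant real component, for reproducibility
  lead <- w[which.max(abs(Re(w)))]
  if (Re(lead) < 0) w <- -w
  w
}

#' @export
#' @method print nb_spectrum
print.nb_spectrum <- function(x, ...) {
  cat("<nb_spectrum> ", x$kind, " matrix, ", length(x$values),
      " eigenvalues (M = ", nrow(x$vectors), ")\n", sep = "")
  cat("  bulk radius r = ", format(x$bulk_radius, digits = 5),
      "; isolated eigenvalues: ", length(x$isolated), "\n", sep = "")
  iso <- format(Re(x$values[x$isolated]), digits = 4)
  cat("  ", paste(utils::head(iso, 12L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.nb_spectrum <- function(x, ...) {
  tibble(index = seq_along(x$values), re = Re(x$values), im = Im(x$values),
         modulus = Mod(x$values),
         isolated = seq_along(x$values) %in% x$isolated)
}

#' @export
glance.nb_spectrum <- function(x, ...) {
  tibble(kind = x$kind, n_eig = length(x$values), bulk_radius = x$bulk_radius,
         n_isolated = length(x$isolated),
         leading = Re(x$values[1]))
}
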