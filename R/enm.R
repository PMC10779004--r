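#' Build an elastic-network Hessian
#'
#' Hessian of the isotropic elastic network E = (spring/2) * sum over pairs
#' with native distance <= cutoff of (r_ij - r0_ij)^2, evaluated at the
#' native structure. Each interacting pair contributes the rank-one block
#' -spring * u u^T (u the unit inter-atom vector) off-diagonal, with the
#' diagonal accumulating the negatives.
#'
#' @param coords N x 3 coordinates or an `atomic_model`.
#' @param cutoff interaction cutoff (A).
#' @param spring uniform spring constant.
#' @return A symmetric 3N x 3N matrix.
#' @export
build_enm_hessian <- function(coords, cutoff = 8.0, spring = 1.0) {
  x <- if (inherits(coords, "atomic_model")) coords$coords else as.matrix(coords)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 atoms")
  stopifnot(cutoff > 0)
  H <- matrix(0, 3 * n, 3 * n)
  dmat <- as.matrix(stats::dist(x))
  pairs <- which(upper.tri(dmat) & dmat <= cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    warning("no atom pair within the ENM cutoff; Hessian is zero")
    return(H)
  }
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    u <- (x[j, ] - x[i, ]) / dmat[i, j]
    blk <- spring * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  H
}

#' Solve the mass-weighted normal-mode eigenproblem
#'
#' Diagonalizes M^(-1/2) H M^(-1/2) and returns the `n_modes` lowest modes
#' sorted by ascending eigenvalue (omega^2). Eigenvalues within the
#' rigid-body tolerance (1e-6 of the largest eigenvalue) are clipped at zero
#' and flagged rigid; for an unconstrained non-collinear structure exactly
#' six such modes exist (three translations, three rotations). The sign
#' convention fixes the first nonzero eigenvector component positive.
#'
#' @param hessian symmetric 3N x 3N matrix.
#' @param masses per-atom masses (length N).
#' @param n_modes number of modes to return (default all).
#' @return An object of class `normal_mode_set` with mass-weighted
#'   orthonormal `vectors` (3N x M), unit-normalized Cartesian
#'   `displacements`, `eigenvalues`, `frequency`, `rigid` flags and
#'   per-mode `collectivity`.
#' @export
compute_modes <- function(hessian, masses = NULL, n_modes = NULL) {
  H <- as.matrix(hessian)
  n3 <- nrow(H)
  if (n3 %% 3 != 0 || ncol(H) != n3) stop("hessian must be 3N x 3N")
  if (max(abs(H - t(H))) > 1e-8) stop("hessian is not symmetric")
  n <- n3 / 3
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n, all(masses > 0))
  if (is.null(n_modes)) n_modes <- n3
  n_modes <- min(n_modes, n3)
  m3 <- rep(masses, each = 3)
  W <- H / sqrt(outer(m3, m3))
  W <- (W + t(W)) / 2
  eig <- eigen(W, symmetric = TRUE)
  ord <- rev(seq_len(n3))[seq_len(n_modes)]  # ascending eigenvalue
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  zero_tol <- 1e-6 * max(abs(eig$values))
  vals[vals > -zero_tol & vals < 0] <- 0
  # deterministic sign: first component with magnitude > 1e-8 is positive
  for (m in seq_len(ncol(vecs))) {
    idx <- which(abs(vecs[, m]) > 1e-8)[1]
    if (!is.na(idx) && vecs[idx, m] < 0) vecs[, m] <- -vecs[, m]
  }
  disp <- vecs / sqrt(m3)
  disp <- sweep(disp, 2, sqrt(colSums(disp^2)), "/")
  kappa <- apply(disp, 2, collectivity)
  structure(list(vectors = vecs, displacements = disp,
                 eigenvalues = vals,
                 frequency = sqrt(pmax(vals, 0)),
                 mode_index = seq_len(n_modes),
                 rigid = vals < zero_tol,
                 collectivity = kappa,
                 zero_tol = zero_tol,
                 masses = masses, n_atoms = n),
            class = "normal_mode_set")
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat(sprintf("normal_mode_set: %d modes over %d atoms (%d rigid-body)\n",
              length(x$eigenvalues), x$n_atoms, sum(x$rigid)))
  invisible(x)
}

#' Degree of collectivity of a mode
#'
#' kappa = (1/N) exp(-sum_i alpha d_i^2 log(alpha d_i^2)) with d_i^2 the
#' squared per-atom displacement and alpha normalizing sum alpha d_i^2 = 1.
#' Equals 1 when every atom moves equally and 1/N when a single atom moves.
#'
#' @param mode_vector a 3N displacement vector.
#' @param n_atoms optional atom count (default length/3).
#' @return Collectivity in (0, 1].
#' @export
collectivity <- function(mode_vector, n_atoms = length(mode_vector) / 3) {
  v <- as.numeric(mode_vector)
  if (length(v) %% 3 != 0) stop("mode vector length must be 3N")
  d2 <- rowSums(matrix(v, ncol = 3, byrow = TRUE)^2)
  s <- sum(d2)
  if (s <= 0) stop("zero mode vector")
  p <- d2 / s
  p <- p[p > 0]
  exp(-sum(p * log(p))) / n_atoms
}

#' Compute ENM normal modes of a model in one call
#'
#' @param model a CA-only `atomic_model`.
#' @param cutoff ENM cutoff (A).
#' @param spring uniform spring constant.
#' @param n_modes number of modes to keep.
#' @return A `normal_mode_set`.
#' @export
enm_modes <- function(model, cutoff = 8.0, spring = 1.0, n_modes = NULL) {
  H <- build_enm_hessian(model, cutoff = cutoff, spring = spring)
  compute_modes(H, masses = model$mass, n_modes = n_modes)
}

#' Write modes as a plain-text matrix plus a per-mode summary table
#'
#' @param modes a `normal_mode_set`.
#' @param prefix output path prefix; writes `<prefix>_vectors.tsv` and
#'   `<prefix>_summary.tsv`.
#' @export
write_modes <- function(modes, prefix) {
  vec_path <- paste0(prefix, "_vectors.tsv")
  sum_path <- paste0(prefix, "_summary.tsv")
  write.table(modes$displacements, vec_path, sep = "\t",
              row.names = FALSE, col.names = paste0("mode", modes$mode_index))
  write.table(data.frame(mode = modes$mode_index,
                         eigenvalue = modes$eigenvalues,
                         frequency = modes$frequency,
                         rigid_body = modes$rigid,
                         collectivity = modes$collectivity),
              sum_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(vec_path, sum_path))
}
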