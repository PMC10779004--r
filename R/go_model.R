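#' Default force constants of the Ca structure-based (Go) model
#'
#' Reduced units throughout: energies in eps (1 eps == 1 kcal/mol for the
#' temperature mapping), lengths in Angstrom, angles in radians. The values
#' are the conventional Ca structure-based model defaults and can be
#' overridden per call.
#'
#' @param k_bond bond force constant (eps/A^2).
#' @param k_angle angle force constant (eps/rad^2).
#' @param k_dihedral1,k_dihedral3 dihedral force constants (eps) of the
#'   1- and 3-fold terms.
#' @param eps_contact native-contact well depth (eps).
#' @param eps_excl excluded-volume prefactor (eps).
#' @param r_excl excluded-volume radius (A).
#' @return A named list of force-field parameters.
#' @export
go_params <- function(k_bond = 100, k_angle = 20, k_dihedral1 = 1,
                      k_dihedral3 = 0.5, eps_contact = 1, eps_excl = 1,
                      r_excl = 4.0) {
  list(k_bond = k_bond, k_angle = k_angle, k_dihedral1 = k_dihedral1,
       k_dihedral3 = k_dihedral3, eps_contact = eps_contact,
       eps_excl = eps_excl, r_excl = r_excl)
}

angle_of <- function(x, i, j, k) {
  u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, ct)))
}

dihedral_of <- function(x, i, j, k, l) {
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Build a Ca Go topology from a native structure
#'
#' Bonded terms (bonds, angles, dihedrals) connect consecutive residues of a
#' chain and take their reference values from the native structure; native
#' contacts are all residue pairs at least `min_seq_sep` apart in sequence
#' and within `cutoff` in the native structure, with the pair distance as the
#' contact minimum. All remaining pairs at sequence separation >=
#' `min_seq_sep` repel through an excluded-volume term truncated and shifted
#' at `cutoff`, so the native structure is an exact stationary point of the
#' full potential. Consecutive Ca atoms more than 4.5 A
#' apart are treated as a chain break (warning, no bonded terms across).
#'
#' @param native a CA-only `atomic_model` (the native conformation).
#' @param cutoff native-contact distance cutoff (A).
#' @param min_seq_sep minimum residue separation of a native contact.
#' @param params force-field constants, see [go_params()].
#' @return An object of class `go_topology`.
#' @export
build_ca_go <- function(native, cutoff = 8.0, min_seq_sep = 4,
                        params = go_params()) {
  if (!all(native$atom_name == "CA"))
    stop("topology requires a CA-only model (see extract_ca)")
  x <- native$coords
  n <- nrow(x)
  if (n < 2) stop("need at least 2 residues")
  stopifnot(cutoff > 0, min_seq_sep >= 3)

  # segment the chain at chain-id changes and breaks (> 4.5 A)
  consec_ok <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    same_chain <- native$chain_id[i] == native$chain_id[i + 1]
    d <- sqrt(sum((x[i + 1, ] - x[i, ])^2))
    if (same_chain && d > 4.5)
      warning(sprintf("chain break between residues %d and %d (%.2f A)",
                      i, i + 1, d))
    consec_ok[i] <- same_chain && d <= 4.5
  }
  bonds <- which(consec_ok)
  bond_tab <- if (length(bonds)) {
    data.frame(i = bonds, j = bonds + 1L,
               r0 = vapply(bonds, function(i)
                 sqrt(sum((x[i + 1, ] - x[i, ])^2)), numeric(1)))
  } else data.frame(i = integer(), j = integer(), r0 = numeric())

  trip <- which(consec_ok[-length(consec_ok)] & consec_ok[-1])
  angle_tab <- if (length(trip)) {
    data.frame(i = trip, j = trip + 1L, k = trip + 2L,
               theta0 = vapply(trip, function(i)
                 angle_of(x, i, i + 1, i + 2), numeric(1)))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    theta0 = numeric())

  quad <- if (n >= 4)
    which(consec_ok[seq_len(n - 3)] & consec_ok[seq_len(n - 3) + 1] &
            consec_ok[seq_len(n - 3) + 2]) else integer()
  dih_tab <- if (length(quad)) {
    data.frame(i = quad, j = quad + 1L, k = quad + 2L, l = quad + 3L,
               phi0 = vapply(quad, function(i)
                 dihedral_of(x, i, i + 1, i + 2, i + 3), numeric(1)))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), phi0 = numeric())

  dmat <- as.matrix(stats::dist(x))
  pr <- which(upper.tri(dmat), arr.ind = TRUE)
  sep <- pr[, 2] - pr[, 1]
  is_contact <- sep >= min_seq_sep & dmat[pr] <= cutoff
  contact_tab <- data.frame(i = pr[is_contact, 1], j = pr[is_contact, 2],
                            sigma = dmat[pr][is_contact])
  is_excl <- sep >= min_seq_sep & !is_contact
  excl_tab <- data.frame(i = pr[is_excl, 1], j = pr[is_excl, 2])

  top <- structure(list(bonds = bond_tab, angles = angle_tab,
                        dihedrals = dih_tab, contacts = contact_tab,
                        excluded = excl_tab, params = params,
                        cutoff = cutoff, min_seq_sep = min_seq_sep,
                        n_atoms = n),
                   class = "go_topology")
  top$cpp <- top_to_cpp(top)
  top
}

# 0-based integer tables for the compiled evaluator
top_to_cpp <- function(top) {
  p <- top$params
  list(bonds = cbind(top$bonds$i, top$bonds$j) - 1L,
       bond_r0 = as.numeric(top$bonds$r0),
       angles = cbind(top$angles$i, top$angles$j, top$angles$k) - 1L,
       angle_t0 = as.numeric(top$angles$theta0),
       dihedrals = cbind(top$dihedrals$i, top$dihedrals$j,
                         top$dihedrals$k, top$dihedrals$l) - 1L,
       dih_p0 = as.numeric(top$dihedrals$phi0),
       contacts = cbind(top$contacts$i, top$contacts$j) - 1L,
       contact_sig = as.numeric(top$contacts$sigma),
       excl = cbind(top$excluded$i, top$excluded$j) - 1L,
       par = c(p$k_bond, p$k_angle, p$k_dihedral1, p$k_dihedral3,
               p$eps_contact, p$eps_excl, p$r_excl, top$cutoff))
}

#' @export
print.go_topology <- function(x, ...) {
  cat(sprintf(paste0("go_topology: %d atoms | %d bonds, %d angles, ",
                     "%d dihedrals, %d contacts, %d excluded pairs\n"),
              x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$contacts), nrow(x$excluded)))
  invisible(x)
}

#' Go model energy and forces
#'
#' Evaluates the Ca Go potential and its exact negative gradient.
#'
#' @param top a `go_topology`.
#' @param coords N x 3 coordinate matrix or an `atomic_model`.
#' @return A list with `energy` (an energy report: `total` plus the
#'   bond/angle/dihedral/contact/excluded terms) and `forces` (N x 3).
#' @export
go_energy_forces <- function(top, coords) {
  x <- if (inherits(coords, "atomic_model")) coords$coords else as.matrix(coords)
  if (nrow(x) != top$n_atoms) stop("coordinate count does not match topology")
  out <- cpp_go_energy_forces(x, top$cpp)
  list(energy = c(list(total = out$total), as.list(out$terms)),
       forces = out$forces)
}

#' Serialize a topology to a plain-text table file
#'
#' One section per term type (bonds, angles, dihedrals, contacts, excluded
#' pairs) preceded by a `[section]` header, plus the parameter block.
#'
#' @param top a `go_topology`.
#' @param path output path.
#' @export
write_topology <- function(top, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[params]", con)
  for (nm in names(top$params))
    writeLines(sprintf("%s = %g", nm, top$params[[nm]]), con)
  writeLines(sprintf("cutoff = %g", top$cutoff), con)
  writeLines(sprintf("min_seq_sep = %d", top$min_seq_sep), con)
  for (sec in c("bonds", "angles", "dihedrals", "contacts", "excluded")) {
    writeLines(paste0("[", sec, "]"), con)
    tab <- top[[sec]]
    if (nrow(tab) > 0)
      write.table(format(tab, digits = 10), con, quote = FALSE,
                  row.names = FALSE, sep = "\t")
  }
  invisible(path)
}
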