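#' Construct an atomic model
#'
#' The basic structure container: one row per atom with name, residue and
#' chain identity, Cartesian coordinates in Angstrom and a per-atom mass.
#' The Go force field operates in reduced units, so Ca bead masses default
#' to 1.
#'
#' @param coords numeric N x 3 matrix of coordinates (Angstrom).
#' @param atom_name character vector of atom names (default `"CA"`).
#' @param residue_index integer residue numbers, strictly increasing within
#'   each chain.
#' @param chain_id character chain identifiers.
#' @param residue_name character residue names (cosmetic, used when writing
#'   PDB files).
#' @param mass per-atom masses (reduced units).
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(coords,
                         atom_name = rep("CA", nrow(coords)),
                         residue_index = seq_len(nrow(coords)),
                         chain_id = rep("A", nrow(coords)),
                         residue_name = rep("ALA", nrow(coords)),
                         mass = rep(1, nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 1) stop("atomic model must contain at least one atom")
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  stopifnot(length(atom_name) == n, length(residue_index) == n,
            length(chain_id) == n, length(mass) == n)
  for (ch in unique(chain_id)) {
    r <- residue_index[chain_id == ch]
    ru <- r[c(TRUE, diff(r) != 0)]  # collapse atoms of the same residue
    if (any(diff(ru) <= 0))
      stop("residue_index must be strictly increasing within chain ", ch)
  }
  structure(list(atom_name = as.character(atom_name),
                 residue_index = as.integer(residue_index),
                 chain_id = as.character(chain_id),
                 residue_name = as.character(residue_name),
                 coords = coords,
                 mass = as.numeric(mass)),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms, %d chain(s)\n",
              nrow(x$coords), length(unique(x$chain_id))))
  invisible(x)
}

n_atoms <- function(model) nrow(model$coords)

#' Replace the coordinates of a model
#'
#' @param model an `atomic_model`.
#' @param coords new N x 3 coordinate matrix (same N).
#' @return The model with updated coordinates.
#' @export
set_coords <- function(model, coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n_atoms(model), ncol(coords) == 3)
  model$coords <- coords
  model
}

#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records at PDB fixed-column precision (delegating the
#' record parsing to bio3d). Only the first MODEL of a multi-model file is
#' read; alternate-location indicators other than blank or "A" are dropped.
#'
#' @param path path to a PDB file.
#' @return An [atomic_model()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # first MODEL only
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 0) {
    mend <- grep("^ENDMDL", lines)
    end <- if (length(mend) > 0) mend[1] else length(lines)
    lines <- lines[seq(mstart[1], end)]
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("empty model: no ATOM/HETATM records in ", path)
  atom_lines <- lines[is_atom]
  line_no <- which(is_atom)
  # validate the fixed coordinate columns (31-54) before parsing
  for (k in seq_along(atom_lines)) {
    for (col in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- substr(atom_lines[k], col[1], col[2])
      if (is.na(suppressWarnings(as.numeric(fld))))
        stop("malformed coordinate field on line ", line_no[k], ": '",
             trimws(atom_lines[k]), "'")
    }
  }
  alt <- substr(atom_lines, 17, 17)
  keep <- alt %in% c(" ", "", "A")
  atom_lines <- atom_lines[keep]
  if (length(atom_lines) == 0) stop("empty model: no usable ATOM records")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(atom_lines, "END"), tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = FALSE, multi = FALSE)
  a <- pdb$atom
  ch <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  atomic_model(coords = cbind(a$x, a$y, a$z),
               atom_name = trimws(a$elety),
               residue_index = a$resno,
               chain_id = ch,
               residue_name = trimws(a$resid))
}

format_atom_record <- function(serial, name, resname, chain, resno, xyz) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial %% 100000, nm, substr(resname, 1, 3), substr(chain, 1, 1),
          resno %% 10000, xyz[1], xyz[2], xyz[3], 1.0, 0.0)
}

model_to_records <- function(model) {
  vapply(seq_len(n_atoms(model)), function(i) {
    format_atom_record(i, model$atom_name[i], model$residue_name[i],
                       model$chain_id[i], model$residue_index[i],
                       model$coords[i, ])
  }, character(1))
}

#' Write an atomic model to a PDB file
#'
#' @param model an `atomic_model`.
#' @param path output path.
#' @export
write_pdb <- function(model, path) {
  writeLines(c(model_to_records(model), "END"), path)
  invisible(path)
}

#' Write a coordinate trajectory as a multi-MODEL PDB file
#'
#' @param models a list of `atomic_model` objects (identical atom content),
#'   or a single template model together with `coord_list`.
#' @param path output path.
#' @param coord_list optional list of N x 3 coordinate matrices used with a
#'   single template model.
#' @export
write_pdb_trajectory <- function(models, path, coord_list = NULL) {
  if (!is.null(coord_list)) {
    template <- if (inherits(models, "atomic_model")) models else models[[1]]
    models <- lapply(coord_list, function(x) set_coords(template, x))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(models)) {
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(model_to_records(models[[i]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract the Ca trace of a model
#'
#' Keeps atoms named CA, preserving order; residues lacking a CA atom are
#' dropped with a warning. Ca bead masses are reset to 1 (reduced units of
#' the Go model).
#'
#' @param model an `atomic_model`.
#' @return A CA-only `atomic_model`.
#' @export
extract_ca <- function(model) {
  if (n_atoms(model) < 1) stop("empty model")
  is_ca <- model$atom_name == "CA"
  if (!any(is_ca)) stop("model contains no CA atoms")
  res_key <- paste(model$chain_id, model$residue_index)
  missing <- setdiff(unique(res_key), unique(res_key[is_ca]))
  if (length(missing) > 0)
    warning(length(missing), " residue(s) lack a CA atom and were dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  keep <- which(is_ca)
  # at most one CA per residue: keep the first
  keep <- keep[!duplicated(res_key[keep])]
  atomic_model(coords = model$coords[keep, , drop = FALSE],
               atom_name = model$atom_name[keep],
               residue_index = model$residue_index[keep],
               chain_id = model$chain_id[keep],
               residue_name = model$residue_name[keep],
               mass = rep(1, length(keep)))
}

#' Root-mean-square deviation between two models
#'
#' Plain RMSD over paired atoms, with no superposition.
#'
#' @param a,b `atomic_model` objects (or N x 3 matrices) with the same atom
#'   count and ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  A <- if (inherits(a, "atomic_model")) a$coords else as.matrix(a)
  B <- if (inherits(b, "atomic_model")) b$coords else as.matrix(b)
  if (nrow(A) != nrow(B)) stop("models differ in atom count")
  sqrt(mean(rowSums((A - B)^2)))
}
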