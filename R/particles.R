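#' A set of particles (images or subtomograms) with poses
#'
#' @param items list of [density_image()] or [density_volume()] objects,
#'   all of identical shape and sampling.
#' @param poses list of [em_pose()] objects, one per item.
#' @param ids particle identifiers (default 1..n).
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(items, poses, ids = seq_along(items)) {
  stopifnot(length(items) >= 1, length(poses) == length(items),
            length(ids) == length(items))
  cls <- class(items[[1]])[1]
  if (!cls %in% c("density_image", "density_volume"))
    stop("items must be density_image or density_volume objects")
  D <- items[[1]]$D; sp <- items[[1]]$spacing
  for (it in items)
    if (!inherits(it, cls) || it$D != D || it$spacing != sp)
      stop("all items must share shape and sampling")
  structure(list(items = items, poses = poses, ids = ids,
                 kind = if (cls == "density_image") "images" else "subtomograms",
                 D = D, spacing = sp),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("particle_set: %d %s, D = %d, spacing = %.3g A\n",
              length(x$items), x$kind, x$D, x$spacing))
  invisible(x)
}

#' @export
length.particle_set <- function(x) length(x$items)

#' Write particle alignment metadata as TSV
#'
#' Columns: id, rot, tilt, psi, shift_x, shift_y and, for subtomograms,
#' shift_z. Angles are ZYZ intrinsic in degrees, shifts in pixels/voxels.
#'
#' @param particles a `particle_set`.
#' @param path output path.
#' @export
write_particle_metadata <- function(particles, path) {
  ps <- particles$poses
  tab <- data.frame(id = particles$ids,
                    rot = vapply(ps, `[[`, numeric(1), "rot"),
                    tilt = vapply(ps, `[[`, numeric(1), "tilt"),
                    psi = vapply(ps, `[[`, numeric(1), "psi"),
                    shift_x = vapply(ps, function(p) p$shift[1], numeric(1)),
                    shift_y = vapply(ps, function(p) p$shift[2], numeric(1)))
  if (particles$kind == "subtomograms")
    tab$shift_z <- vapply(ps, function(p) p$shift[3], numeric(1))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read particle alignment metadata from TSV
#'
#' @param path TSV with columns id, rot, tilt, psi, shift_x, shift_y
#'   and optionally shift_z.
#' @return A list of `em_pose` objects named by id (as attribute `ids`).
#' @export
read_particle_metadata <- function(path) {
  tab <- read.delim(path, sep = "\t")
  need <- c("id", "rot", "tilt", "psi", "shift_x", "shift_y")
  if (!all(need %in% names(tab)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  has_z <- "shift_z" %in% names(tab)
  poses <- lapply(seq_len(nrow(tab)), function(i) {
    sh <- if (has_z) c(tab$shift_x[i], tab$shift_y[i], tab$shift_z[i])
          else c(tab$shift_x[i], tab$shift_y[i])
    em_pose(tab$rot[i], tab$tilt[i], tab$psi[i], sh)
  })
  attr(poses, "ids") <- tab$id
  poses
}

#' Write a particle set as MRC/MRCS plus metadata TSV
#'
#' @param particles a `particle_set`.
#' @param prefix output prefix; writes `<prefix>.mrcs` (images) or
#'   `<prefix>.mrc` (subtomogram stack written one file per item:
#'   `<prefix>_####.mrc`) and `<prefix>.tsv`.
#' @export
write_particle_set <- function(particles, prefix) {
  if (particles$kind == "images") {
    stack <- array(0, c(particles$D, particles$D, length(particles)))
    for (i in seq_along(particles$items))
      stack[, , i] <- particles$items[[i]]$values
    write_mrc(stack, paste0(prefix, ".mrcs"), particles$spacing,
              is_stack = TRUE)
  } else {
    for (i in seq_along(particles$items))
      write_mrc(particles$items[[i]]$values,
                sprintf("%s_%04d.mrc", prefix, i), particles$spacing)
  }
  write_particle_metadata(particles, paste0(prefix, ".tsv"))
  invisible(prefix)
}

#' Read a particle image stack (MRCS) with its metadata
#'
#' @param stack_path path to an `.mrcs` stack (mode 2).
#' @param metadata_path path to the pose TSV.
#' @param spacing optional pixel size override (A); default from the header.
#' @return A `particle_set` of images.
#' @export
read_particle_stack <- function(stack_path, metadata_path, spacing = NULL) {
  m <- read_mrc(stack_path)
  if (is.null(spacing)) spacing <- m$spacing
  poses <- read_particle_metadata(metadata_path)
  n <- dim(m$data)[3]
  if (length(poses) != n)
    stop("metadata rows (", length(poses), ") != stack size (", n, ")")
  items <- lapply(seq_len(n), function(i)
    density_image(m$data[, , i], spacing))
  particle_set(items, poses, ids = attr(poses, "ids"))
}

#' Read a set of subtomogram volumes with metadata
#'
#' @param paths character vector of `.mrc` volume paths, in metadata order.
#' @param metadata_path path to the pose TSV (with shift_z).
#' @param spacing optional voxel size override (A).
#' @return A `particle_set` of subtomograms.
#' @export
read_subtomogram_set <- function(paths, metadata_path, spacing = NULL) {
  poses <- read_particle_metadata(metadata_path)
  if (length(poses) != length(paths))
    stop("metadata rows != number of volumes")
  items <- lapply(paths, function(p) {
    m <- read_mrc(p)
    density_volume(m$data, if (is.null(spacing)) m$spacing else spacing)
  })
  particle_set(items, poses, ids = attr(poses, "ids"))
}
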