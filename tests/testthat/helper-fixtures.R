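# Shared fixtures, built once per test file. Everything is generated in
# code; nothing is read from disk.

fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    val <- switch(name,
      model = make_toy_structure(20, "two_domain", seed = 1),
      helix = make_toy_structure(20, "helix", seed = 1),
      top = build_ca_go(fix("model")),
      modes = enm_modes(fix("model")),
      target3A = displace_along_modes(
        fix("model"), fix("modes")$displacements[, 7, drop = FALSE],
        2.35 * sqrt(20), top = fix("top")),
      stop("unknown fixture ", name))
    cache[[name]] <- val
    val
  }
})

# RMSD after optimal superposition
aligned_rmsd <- function(a, b) {
  al <- align_ensemble(list(a), b)[[1]]
  rmsd(al, b)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  cbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
      2 * (q[2] * q[4] - q[1] * q[3])),
    c(2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] + q[1] * q[2])),
    c(2 * (q[2] * q[4] + q[1] * q[3]), 2 * (q[3] * q[4] - q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
}

# central finite-difference gradient of the Go energy
go_fd_forces <- function(top, x, h = 1e-5) {
  fd <- x * 0
  for (i in seq_len(nrow(x))) for (k in 1:3) {
    xp <- x; xp[i, k] <- xp[i, k] + h
    xm <- x; xm[i, k] <- xm[i, k] - h
    fd[i, k] <- -(go_energy_forces(top, xp)$energy$total -
                  go_energy_forces(top, xm)$energy$total) / (2 * h)
  }
  fd
}
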