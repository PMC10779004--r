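# Flat key = value configuration files. Values are coerced to numeric when
# possible; comma-separated values become vectors; "true"/"false" become
# logicals. Lines starting with '#' are comments.

#' Read a flat key-value configuration file
#'
#' @param path path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(tolower(parts) %in% c("true", "false")))
        tolower(parts) == "true"
      else if (length(parts) > 1) parts else val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config a named list of scalars or vectors.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, scientific = FALSE), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build simulation parameters from a configuration list
#'
#' Recognized keys mirror [sim_params()] arguments, plus `preset`
#' (`"spa"`/`"tomo"`) applied first.
#'
#' @param config a named list (see [read_config()]).
#' @return A `sim_params` object.
#' @export
config_to_params <- function(config) {
  preset <- config$preset
  config$preset <- NULL
  keep <- intersect(names(config), names(formals(sim_params)))
  args <- config[keep]
  if (!is.null(preset)) do.call(sim_preset, c(list(name = preset), args))
  else do.call(sim_params, args)
}
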