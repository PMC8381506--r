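# Flat key = value configuration files shared by training, simulation
# and the CLI.  Values that parse as numbers become numeric; "true"/
# "false" become logical; everything else stays character.

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE))
      stop("config syntax error (expected 'key = value'): ", lines[i])
    key <- trimws(sub("=.*$", "", lines[i]))
    val <- trimws(sub("^[^=]*=", "", lines[i]))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalar values.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, "")
  writeLines(sprintf("%s = %s", names(config), vals), path)
  invisible(path)
}
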