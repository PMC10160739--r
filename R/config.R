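# Minimal flat `key: value` YAML-subset reader/writer plus JSON configs.
# Only scalars (numbers, logicals, strings) at the top level are supported --
# enough for schedule/network/training configs; nested structure uses JSON.

write_flat_yaml <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  fmt <- vapply(x, function(v) {
    if (is.numeric(v)) paste(format(v, digits = 17), collapse = ", ")
    else if (is.logical(v)) tolower(as.character(v))
    else as.character(v)
  }, character(1))
  writeLines(paste0(names(x), ": ", fmt), path)
  invisible(path)
}

read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stopf("config line without 'key: value': %s", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (grepl(",", val, fixed = TRUE)) {
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      out[[key]] <- if (anyNA(num)) parts else num
    } else {
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num
        else if (val %in% c("true", "false")) val == "true"
        else val
    }
  }
  out
}

# Reads .json or flat .yaml/.yml config files into a named list.
read_config_file <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else read_flat_yaml(path)
}
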