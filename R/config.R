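#' Read a flat key-value configuration file
#'
#' The accepted format is the flat scalar subset of TOML: one `key = value`
#' per line, `#` comments, bare numbers, `true`/`false`, quoted strings, and
#' comma-separated numeric lists for the grid keys (`lambdas`, `alphas`,
#' `Ls`, `snapshot_fractions`). Unknown keys are an error (fail-fast).
#'
#' @param path Path to the configuration file.
#' @return A named list of parsed values.
#' @export
read_config <- function(path) {
  allowed <- c("experiment", "L", "variant", "lambda", "alpha", "kappa", "g0",
               "p", "gamma", "Ks", "init", "invader_type", "seed",
               "max_events", "t_max", "record_stride", "snapshot_dt",
               "snapshot_fractions", "reps", "reps_per_probe", "tol",
               "horizon_mult", "neutral_reps", "lambdas", "alphas", "Ls",
               "reference_type", "display_bins", "out")
  list_keys <- c("lambdas", "alphas", "Ls", "snapshot_fractions")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed configuration line: ", ln)
    key <- m[2L]; val <- trimws(m[3L])
    if (!key %in% allowed) stop("unknown configuration key: ", key)
    parsed <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else if (key %in% list_keys) {
      v <- as.numeric(strsplit(val, ",")[[1L]])
      if (anyNA(v)) stop("malformed numeric list for key ", key, ": ", val)
      v
    } else {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) val else v  # bare word falls back to string
    }
    out[[key]] <- parsed
  }
  out
}

#' Write a flat key-value configuration file
#'
#' Inverse of [read_config()]; used to record the resolved configuration of
#' every experiment run.
#'
#' @param config Named list of scalars or numeric vectors.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
               collapse = ", ")
  }
  keep <- !vapply(config, is.null, logical(1))
  writeLines(sprintf("%s = %s", names(config)[keep],
                     vapply(config[keep], fmt, character(1))), path)
  invisible(path)
}
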