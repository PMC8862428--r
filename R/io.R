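# CSV I/O with '#'-prefixed provenance headers. No timestamps: identical
# configurations must give byte-identical files.

# FNV-1a 32-bit over a character vector; small stable config fingerprint
# without an external hashing dependency.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h in doubles since it
    # exceeds R's 32-bit integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split into 16-bit halves so
    # every intermediate stays within exact double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  # h can exceed R's integer range; format halves separately
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_header <- function(cfg_lines, seed) {
  c(sprintf("# atpasekin %s", as.character(utils::packageVersion("atpasekin"))),
    "# rates are min^-1 per transporter homodimer (MW basis 135 kDa)",
    sprintf("# seed: %s", format(seed)),
    sprintf("# config_hash: %s", fnv1a_hash(cfg_lines)),
    paste0("# ", cfg_lines))
}

write_csv_with_header <- function(df, path, header_lines) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rate-observation and time-course tables
#'
#' Plain CSV (comma separator, header row, dot decimal, UTF-8) with
#' provenance recorded in leading comment lines prefixed `#` (package
#' version, rate-unit basis, seed, configuration hash). Rate tables carry
#' columns `condition, atp_mM, gssg_mM, replicate, rate_per_min`
#' (plus `orientation_corrected`); time-course tables carry
#' `condition, atp_mM, gssg_mM, replicate, time_min, pi_uM`.
#'
#' @param obs,tc Table to write.
#' @param path File path.
#' @param seed Seed recorded in the provenance header.
#' @param config Named list echoed as `key=value` provenance lines.
#' @return The path (writers, invisibly) or a tibble (readers).
#' @export
write_rates_csv <- function(obs, path, seed = NA, config = list()) {
  stopifnot(is.data.frame(obs))
  cfg_lines <- config_lines(config)
  write_csv_with_header(obs, path, provenance_header(cfg_lines, seed))
}

#' @rdname write_rates_csv
#' @export
write_timecourses_csv <- function(tc, path, seed = NA, config = list()) {
  stopifnot(is.data.frame(tc))
  cfg_lines <- config_lines(config)
  write_csv_with_header(tc, path, provenance_header(cfg_lines, seed))
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  df <- read_csv_checked(path, c("condition", "atp_mM", "gssg_mM",
                                 "replicate", "rate_per_min"))
  if (any(!is.finite(df$rate_per_min))) {
    stop("parse error: non-finite rate at data row ",
         which(!is.finite(df$rate_per_min))[1L], " of ", path, call. = FALSE)
  }
  df
}

#' @rdname write_rates_csv
#' @export
read_timecourses_csv <- function(path) {
  read_csv_checked(path, c("condition", "atp_mM", "gssg_mM", "replicate",
                           "time_min", "pi_uM"))
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("parse error: file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0L) {
    stop("parse error: no data rows in ", path, call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("parse error: ", path, " lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

config_lines <- function(config) {
  if (length(config) == 0L) return(character())
  vapply(names(config),
         function(nm) paste0(nm, "=", paste(format(config[[nm]]),
                                            collapse = ",")),
         character(1L))
}

#' Read a flat key=value configuration file
#'
#' INI-like dialect: one `key=value` pair per line, `#` comments and blank
#' lines ignored, values coerced to numeric where possible.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config error: malformed line: ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
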