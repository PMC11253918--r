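#' Read and write radiometry files
#'
#' The radiometry dialect is a TSV with three header lines — the number of
#' observations, the number of channels, and the number of reads, one
#' integer each — followed by one row per read containing
#' `n_observations * n_channels` tab-separated values ordered
#' observation-major then channel. Values round-trip losslessly at 17
#' significant digits. Dye-track files use the same layout with integers.
#'
#' @param path File path.
#' @return A `read_set`.
#' @export
read_radiometry <- function(path) {
  rs <- read_table_file(path, integer_body = FALSE)
  read_set(rs$body, rs$n_channels)
}

#' @rdname read_radiometry
#' @param rs A `read_set` (or `dye_track_set` for the track variants).
#' @export
write_radiometry <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  write_table_file(rs, path, fmt = "%.17g")
}

#' @rdname read_radiometry
#' @export
read_dye_tracks <- function(path) {
  rs <- read_table_file(path, integer_body = TRUE)
  dye_track_set(rs$body, rs$n_channels)
}

#' @rdname read_radiometry
#' @export
write_dye_tracks <- function(rs, path) {
  stopifnot(inherits(rs, "dye_track_set"))
  write_table_file(rs, path, fmt = "%d")
}

read_table_file <- function(path, integer_body) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    stop("radiometry file has fewer than 3 header lines: ", path, call. = FALSE)
  }
  hdr <- suppressWarnings(as.integer(lines[1:3]))
  if (any(is.na(hdr)) || any(hdr < 0)) {
    stop("malformed header (lines 1-3 must be integers) in ", path, call. = FALSE)
  }
  n_obs <- hdr[1]; n_ch <- hdr[2]; n_reads <- hdr[3]
  body_lines <- lines[-(1:3)]
  body_lines <- body_lines[!(seq_along(body_lines) > n_reads & body_lines == "")]
  if (length(body_lines) != n_reads) {
    stop(sprintf("header says %d reads but body has %d rows (error at line %d)",
                 n_reads, length(body_lines),
                 3L + min(length(body_lines), n_reads) + 1L), call. = FALSE)
  }
  want <- n_obs * n_ch
  if (n_reads == 0) {
    return(list(body = matrix(numeric(0), 0, want), n_channels = n_ch))
  }
  parts <- strsplit(body_lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != want)) {
    bad <- which(lens != want)[1]
    stop(sprintf("ragged row: line %d has %d fields, expected %d",
                 bad + 3L, lens[bad], want), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    bad <- (which(is.na(vals))[1] - 1L) %/% want + 1L
    stop(sprintf("non-numeric field at line %d", bad + 3L), call. = FALSE)
  }
  body <- matrix(vals, nrow = n_reads, ncol = want, byrow = TRUE)
  if (integer_body) storage.mode(body) <- "integer"
  list(body = body, n_channels = n_ch)
}

write_table_file <- function(rs, path, fmt) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(as.character(c(rs$n_observations, rs$n_channels, rs$n_reads)), con)
  if (rs$n_reads > 0) {
    rows <- apply(rs$intensities, 1, function(v) {
      paste(sprintf(fmt, v), collapse = "\t")
    })
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read and write error-model and channel-model JSON
#'
#' The error-model schema is `{"edman_failure": float, "dye_loss": [...],
#' "detach": float, "dud": [...], "initial_block": float, "cyclic_block":
#' float}` (optionally `"fixed": [...]`); the channel-model schema is
#' `{"mu": [...], "sigma": [...], "bg_sigma": [...], "bg_mu": [...]}`
#' (optionally `"variance_mode"`).
#'
#' @param path File path.
#' @return An `error_model` / `channel_model`.
#' @export
read_error_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  error_model(edman_failure = j$edman_failure %||% 0,
              dye_loss = j$dye_loss %||% 0,
              detach = j$detach %||% 0,
              dud = j$dud %||% 0,
              initial_block = j$initial_block %||% 0,
              cyclic_block = j$cyclic_block %||% 0,
              n_channels = max(length(j$dye_loss %||% 0), length(j$dud %||% 0)),
              fixed = j$fixed %||% character(0))
}

#' @rdname read_error_model
#' @param m The object to serialize.
#' @export
write_error_model <- function(m, path) {
  stopifnot(inherits(m, "error_model"))
  jsonlite::write_json(
    list(edman_failure = m$edman_failure, dye_loss = m$dye_loss,
         detach = m$detach, dud = m$dud, initial_block = m$initial_block,
         cyclic_block = m$cyclic_block, fixed = m$fixed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_error_model
#' @export
read_channel_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel_model(mu = j$mu, sigma = j$sigma, bg_sigma = j$bg_sigma,
                bg_mu = j$bg_mu %||% 0,
                variance_mode = j$variance_mode %||% "linear")
}

#' @rdname read_error_model
#' @export
write_channel_model <- function(m, path) {
  stopifnot(inherits(m, "channel_model"))
  jsonlite::write_json(
    list(mu = m$mu, sigma = m$sigma, bg_sigma = m$bg_sigma, bg_mu = m$bg_mu,
         variance_mode = m$variance_mode),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a fit result to JSON
#'
#' Schema version 1: `estimate` (error-model schema), `method`,
#' `converged`, `n_iterations`, `fixed`, `loglik_trajectory`, `objective`,
#' `missing_reads`.
#'
#' @param fit A `fit_result`.
#' @param path File path.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  e <- fit$estimate
  jsonlite::write_json(
    list(schema_version = 1L,
         method = fit$method,
         estimate = list(edman_failure = e$edman_failure, dye_loss = e$dye_loss,
                         detach = e$detach, dud = e$dud,
                         initial_block = e$initial_block,
                         cyclic_block = e$cyclic_block),
         fixed = fit$fixed,
         converged = fit$converged,
         n_iterations = fit$n_iterations,
         loglik_trajectory = fit$loglik_trajectory,
         objective = fit$objective,
         missing_reads = fit$missing_reads),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Serialize a bootstrap result to JSON
#'
#' Holds all replicate estimates (for downstream box plots), the point
#' estimate, and the percentile intervals.
#'
#' @param boot A `bootstrap_result`.
#' @param path File path.
#' @export
write_bootstrap_result <- function(boot, path) {
  stopifnot(inherits(boot, "bootstrap_result"))
  jsonlite::write_json(
    list(schema_version = 1L,
         ci_level = boot$ci_level,
         point = as.list(boot$point),
         ci_lower = as.list(boot$ci[1, ]),
         ci_upper = as.list(boot$ci[2, ]),
         replicates = as.data.frame(boot$replicates),
         n_failed = boot$n_failed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
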