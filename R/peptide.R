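#' Parse a labeled-peptide notation string
#'
#' Fluorosequencing peptides are written as single-letter amino acid codes
#' (multi-character residues in braces, e.g. `{azK}` for azido-lysine), with
#' an asterisk after every fluorescently labeled residue. An optional prefix
#' records the N-terminal state: `NH2-` (ordinary free N-terminus), `fmoc-`
#' (Fmoc protecting group, removed before sequencing, so also free), or
#' `ac-` (acetylated, which blocks Edman degradation). A trailing `|` marks
#' that the sequence was truncated at the last labeled residue; unlabeled
#' C-terminal residues carry no signal and are conventionally omitted.
#'
#' For peptides labeled in more than one color, a label may carry an explicit
#' zero-based channel index, e.g. `K*1` puts that label on channel 1. A bare
#' `*` means channel 0.
#'
#' @param notation Notation string, e.g. `"NH2-G{azK}*AG{azK}*|"`.
#' @return A `labeled_peptide` object: a list with elements
#'   `sequence` (character vector of residue codes, 1-based positions),
#'   `labels` (data frame with columns `position`, `channel`),
#'   `n_term_status` (`"free"` or `"acetylated"`), `prefix` (the prefix as
#'   written, for faithful rendering), `truncated` (logical), and
#'   `n_channels`.
#' @examples
#' p <- parse_peptide("NH2-G{azK}*AG{azK}*|")
#' label_counts(p)
#' @seealso [render_peptide()], [label_counts()]
#' @export
parse_peptide <- function(notation) {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation)) {
    stop("`notation` must be a single string", call. = FALSE)
  }
  chars <- strsplit(notation, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  prefix <- "NH2-"
  n_term <- "free"
  for (pfx in c("NH2-", "fmoc-", "ac-")) {
    if (startsWith(notation, pfx)) {
      prefix <- pfx
      n_term <- if (pfx == "ac-") "acetylated" else "free"
      pos <- nchar(pfx) + 1L
      break
    }
  }

  residues <- character(0)
  label_pos <- integer(0)
  label_ch <- integer(0)
  truncated <- FALSE

  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "|") {
      if (pos != n) {
        stop(sprintf("parse error at character %d: '|' must end the notation", pos),
             call. = FALSE)
      }
      truncated <- TRUE
      pos <- pos + 1L
    } else if (ch == "{") {
      close <- pos + 1L
      while (close <= n && chars[close] != "}") close <- close + 1L
      if (close > n) {
        stop(sprintf("parse error at character %d: unclosed '{'", pos), call. = FALSE)
      }
      if (close == pos + 1L) {
        stop(sprintf("parse error at character %d: empty braced residue", pos),
             call. = FALSE)
      }
      residues <- c(residues, paste(chars[(pos + 1L):(close - 1L)], collapse = ""))
      pos <- close + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      residues <- c(residues, ch)
      pos <- pos + 1L
    } else if (ch == "*") {
      if (length(residues) == 0L) {
        stop(sprintf("parse error at character %d: '*' attaches to no residue", pos),
             call. = FALSE)
      }
      r <- length(residues)
      if (r %in% label_pos) {
        stop(sprintf("parse error at character %d: residue %d labeled twice", pos, r),
             call. = FALSE)
      }
      pos <- pos + 1L
      channel <- 0L
      digits <- character(0)
      while (pos <= n && grepl("^[0-9]$", chars[pos])) {
        digits <- c(digits, chars[pos])
        pos <- pos + 1L
      }
      if (length(digits) > 0L) channel <- as.integer(paste(digits, collapse = ""))
      label_pos <- c(label_pos, r)
      label_ch <- c(label_ch, channel)
    } else {
      stop(sprintf("parse error at character %d: unexpected '%s'", pos, ch),
           call. = FALSE)
    }
  }

  if (length(residues) == 0L) {
    stop("parse error: empty sequence", call. = FALSE)
  }
  if (length(label_pos) == 0L) {
    stop("parse error: peptide has zero labels and is unobservable", call. = FALSE)
  }
  used <- sort(unique(label_ch))
  n_channels <- max(label_ch) + 1L
  if (!identical(used, seq_len(n_channels) - 1L)) {
    stop(sprintf("channel indices must be contiguous from 0; got {%s}",
                 paste(used, collapse = ",")), call. = FALSE)
  }

  new_labeled_peptide(residues, label_pos, label_ch, n_term, prefix, truncated)
}

new_labeled_peptide <- function(residues, label_pos, label_ch, n_term, prefix,
                                truncated) {
  stopifnot(all(diff(label_pos) > 0), all(label_pos >= 1L),
            all(label_pos <= length(residues)))
  structure(
    list(
      sequence = residues,
      labels = data.frame(position = as.integer(label_pos),
                          channel = as.integer(label_ch)),
      n_term_status = n_term,
      prefix = prefix,
      truncated = truncated,
      n_channels = max(label_ch) + 1L
    ),
    class = "labeled_peptide"
  )
}

#' Render a labeled peptide back to notation
#'
#' Inverse of [parse_peptide()]: `parse_peptide(render_peptide(p))` is
#' identical to `p`.
#'
#' @param p A `labeled_peptide`.
#' @return Notation string.
#' @export
render_peptide <- function(p) {
  stopifnot(inherits(p, "labeled_peptide"))
  toks <- ifelse(nchar(p$sequence) > 1L, paste0("{", p$sequence, "}"), p$sequence)
  for (k in seq_len(nrow(p$labels))) {
    i <- p$labels$position[k]
    ch <- p$labels$channel[k]
    toks[i] <- paste0(toks[i], "*", if (ch > 0L) ch else "")
  }
  paste0(p$prefix, paste(toks, collapse = ""), if (p$truncated) "|" else "")
}

#' Per-channel label counts
#'
#' @param p A `labeled_peptide`.
#' @return Integer vector of length `p$n_channels`; element `ch + 1` is the
#'   number of labels on zero-based channel `ch`.
#' @export
label_counts <- function(p) {
  stopifnot(inherits(p, "labeled_peptide"))
  as.integer(tabulate(p$labels$channel + 1L, nbins = p$n_channels))
}

#' Position of the last labeled residue
#'
#' States with more successful Edman cycles than this carry no fluorophores,
#' so the model never needs to distinguish them; the simulator and HMM cap
#' their cycle tracking here. This makes likelihoods invariant to appending
#' unlabeled C-terminal residues.
#'
#' @param p A `labeled_peptide`.
#' @return Integer position (1-based).
#' @export
last_label_position <- function(p) {
  max(p$labels$position)
}

#' @export
print.labeled_peptide <- function(x, ...) {
  cat("Labeled peptide:", render_peptide(x), "\n")
  cat(sprintf("  %d residues, %d label(s) on %d channel(s); N-terminus %s\n",
              length(x$sequence), nrow(x$labels), x$n_channels, x$n_term_status))
  invisible(x)
}
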