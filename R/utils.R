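# Internal numeric and label helpers shared across modules.

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise logsumexp of a matrix (returns one value per column).
#' @noRd
col_logsumexp <- function(X) {
  m <- apply(X, 2L, max)
  m + log(colSums(exp(sweep(X, 2L, m, "-"))))
}

#' @noRd
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Number of folded (1) bits in a macrobasin label.
#' @noRd
label_nfolded <- function(labels) {
  vapply(strsplit(labels, ""), function(ch) sum(ch == "1"), numeric(1))
}

#' @noRd
check_labels <- function(labels) {
  if (length(labels) == 0L) stop("empty label set", call. = FALSE)
  len <- nchar(labels)
  if (length(unique(len)) != 1L) {
    stop("macrobasin labels have mixed lengths: ",
         paste(sort(unique(len)), collapse = ", "), call. = FALSE)
  }
  if (!all(grepl("^[01]+$", labels))) {
    stop("macrobasin labels must consist of characters 0 and 1", call. = FALSE)
  }
  invisible(labels)
}

# Integer state index (0-based bit pattern) <-> label string.
# Leftmost character of the label is foldon 1 (N-terminal) and maps to the
# lowest-order bit so that label "1000..." for state 1 reads left-to-right.
#' @noRd
state_to_label <- function(state, n) {
  bits <- bitwAnd(bitwShiftR(state, 0:(n - 1L)), 1L)
  paste(bits, collapse = "")
}

#' @noRd
label_to_state <- function(label) {
  bits <- as.integer(strsplit(label, "")[[1]])
  sum(bits * 2L^(seq_along(bits) - 1L))
}

#' @noRd
all_labels <- function(n) {
  vapply(0:(2L^n - 1L), state_to_label, character(1), n = n)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
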