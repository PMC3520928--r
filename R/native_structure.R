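#' Parse a native structure from PDB text
#'
#' Reads the C-alpha trace of a single chain from standard PDB ATOM records.
#' Residues are renumbered 1..n in file order regardless of author numbering;
#' the original numbering is retained for reporting. Alternate locations are
#' resolved by highest occupancy, ties by first occurrence.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines, or a
#'   single string containing the whole file.
#' @param chain Chain identifier (single character). Default `"A"`.
#' @return An object of class `native_structure`: a list with
#'   `ca_coords` (n x 3 matrix, Angstrom), `residue_index` (1-based,
#'   contiguous), `author_resid` (original PDB residue numbering),
#'   `n_residues`.
#' @export
read_structure <- function(pdb, chain = "A") {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else if (length(pdb) == 1L) {
    strsplit(pdb, "\n", fixed = TRUE)[[1]]
  } else {
    pdb
  }
  atom <- lines[startsWith(lines, "ATOM")]
  if (length(atom) == 0L) stop("no ATOM records found", call. = FALSE)
  # PDB fixed columns (1-based): name 13-16, altLoc 17, chain 22,
  # resSeq 23-26, iCode 27, x 31-38, y 39-46, z 47-54, occupancy 55-60.
  fld <- function(x, a, b) trimws(substr(x, a, b))
  rec <- data.frame(
    name    = fld(atom, 13, 16),
    altloc  = substr(atom, 17, 17),
    chain   = substr(atom, 22, 22),
    resseq  = fld(atom, 23, 26),
    icode   = substr(atom, 27, 27),
    x = as.numeric(substr(atom, 31, 38)),
    y = as.numeric(substr(atom, 39, 46)),
    z = as.numeric(substr(atom, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(atom, 55, 60))),
    stringsAsFactors = FALSE
  )
  rec$occ[is.na(rec$occ)] <- 1
  rec <- rec[rec$chain == chain, , drop = FALSE]
  if (nrow(rec) == 0L) stop("chain '", chain, "' has no ATOM records",
                            call. = FALSE)
  reskey <- paste0(rec$resseq, rec$icode)
  res_order <- unique(reskey)
  n <- length(res_order)
  coords <- matrix(NA_real_, n, 3L)
  author <- character(n)
  for (i in seq_len(n)) {
    sub <- rec[reskey == res_order[i], , drop = FALSE]
    author[i] <- trimws(res_order[i])
    ca <- sub[sub$name == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) {
      stop("residue ", author[i], " (chain ", chain, ") has no CA atom",
           call. = FALSE)
    }
    ca <- ca[order(-ca$occ), , drop = FALSE]  # highest occupancy, ties first
    coords[i, ] <- c(ca$x[1], ca$y[1], ca$z[1])
  }
  structure(list(ca_coords = coords,
                 residue_index = seq_len(n),
                 author_resid = author,
                 n_residues = n),
            class = "native_structure")
}

#' @export
print.native_structure <- function(x, ...) {
  cat("<native_structure>", x$n_residues, "residues (CA trace)\n")
  invisible(x)
}

#' Build the native contact set
#'
#' Enumerates all residue pairs (i, j), j - i >= `min_seq_sep`, whose native
#' C-alpha distance is at most `cutoff`, and attaches a sequence-separation
#' dependent Gaussian width `sigma_ij = sigma0 * (1 + |i - j|)^sigma_exp` to
#' each pair. These pairs, native distances and widths define the native
#' similarity coordinate Q (see [compute_q()]).
#'
#' @param structure A `native_structure`.
#' @param cutoff Contact distance cutoff in Angstrom (default 9.5, the usual
#'   C-alpha Go-model convention).
#' @param min_seq_sep Minimum sequence separation |i - j| (default 3).
#' @param sigma0,sigma_exp Width-rule parameters, `sigma_ij =
#'   sigma0 * (1 + |i - j|)^sigma_exp` Angstrom (defaults 1 and 0.15).
#' @return An object of class `contact_set`: data frame with columns
#'   `i`, `j` (1-based, i < j), `r_native` and `sigma` (Angstrom), plus
#'   attributes `n_pairs`, `cutoff`, `min_seq_sep`.
#' @export
build_contact_set <- function(structure, cutoff = 9.5, min_seq_sep = 3L,
                              sigma0 = 1, sigma_exp = 0.15) {
  stopifnot(inherits(structure, "native_structure"))
  if (structure$n_residues < 2L) stop("structure must have >= 2 residues",
                                      call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (min_seq_sep < 1L) stop("min_seq_sep must be >= 1", call. = FALSE)
  n <- structure$n_residues
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  keep <- (j - i) >= min_seq_sep
  i <- i[keep]; j <- j[keep]
  d <- sqrt(rowSums((structure$ca_coords[i, , drop = FALSE] -
                     structure$ca_coords[j, , drop = FALSE])^2))
  keep <- d <= cutoff
  cs <- data.frame(i = i[keep], j = j[keep], r_native = d[keep])
  cs <- cs[order(cs$i, cs$j), , drop = FALSE]
  rownames(cs) <- NULL
  cs$sigma <- sigma0 * (1 + abs(cs$j - cs$i))^sigma_exp
  attr(cs, "n_pairs") <- nrow(cs)
  attr(cs, "cutoff") <- cutoff
  attr(cs, "min_seq_sep") <- min_seq_sep
  class(cs) <- c("contact_set", "data.frame")
  cs
}

#' Define a foldon partition
#'
#' Splits residues 1..n into ordered, contiguous, non-overlapping segments.
#' Foldon 1 is N-terminal. Accepts either a vector of segment lengths or an
#' explicit two-column matrix / list of `(start, end)` ranges.
#'
#' @param spec Integer vector of segment lengths, or a 2-column matrix (or
#'   list of length-2 vectors) of 1-based inclusive residue ranges.
#' @param n_residues Total number of residues the partition must cover.
#' @return An object of class `foldon_partition`: data frame with columns
#'   `foldon`, `start`, `end`.
#' @examples
#' define_foldons(c(12, 19, 14, 19, 14, 19, 14, 15), 126)
#' @export
define_foldons <- function(spec, n_residues) {
  if (is.list(spec)) spec <- do.call(rbind, spec)
  if (is.matrix(spec)) {
    ranges <- spec
  } else {
    lens <- as.integer(spec)
    if (any(lens <= 0L)) stop("zero-length foldon segment", call. = FALSE)
    if (sum(lens) != n_residues) {
      stop("segment lengths sum to ", sum(lens), " but n_residues is ",
           n_residues, call. = FALSE)
    }
    end <- cumsum(lens)
    ranges <- cbind(end - lens + 1L, end)
  }
  ranges <- matrix(as.integer(ranges), ncol = 2L)
  if (any(ranges[, 2L] < ranges[, 1L])) stop("zero-length foldon segment",
                                             call. = FALSE)
  if (ranges[1L, 1L] != 1L || ranges[nrow(ranges), 2L] != n_residues ||
      (nrow(ranges) > 1L &&
       any(ranges[-1L, 1L] != ranges[-nrow(ranges), 2L] + 1L))) {
    stop("segments must tile 1..", n_residues,
         " contiguously and in order", call. = FALSE)
  }
  out <- data.frame(foldon = seq_len(nrow(ranges)),
                    start = ranges[, 1L], end = ranges[, 2L])
  class(out) <- c("foldon_partition", "data.frame")
  out
}

#' Write / read a contact set as TSV
#'
#' Columns: `i`, `j`, `r_native_angstrom`, `sigma_angstrom`.
#' @param contacts A `contact_set`.
#' @param path Output file path.
#' @export
write_contact_set <- function(contacts, path) {
  df <- data.frame(i = contacts$i, j = contacts$j,
                   r_native_angstrom = contacts$r_native,
                   sigma_angstrom = contacts$sigma)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_set
#' @export
read_contact_set <- function(path) {
  df <- utils::read.delim(path)
  cs <- data.frame(i = as.integer(df$i), j = as.integer(df$j),
                   r_native = df$r_native_angstrom,
                   sigma = df$sigma_angstrom)
  attr(cs, "n_pairs") <- nrow(cs)
  class(cs) <- c("contact_set", "data.frame")
  cs
}
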