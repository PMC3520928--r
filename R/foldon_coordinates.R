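#' Native-similarity coordinate Q for a frame
#'
#' Computes
#' \deqn{Q = \frac{1}{N_{pairs}} \sum_{(i,j)}
#'   \exp\left(-\frac{(r_{ij} - r_{ij}^N)^2}{2\sigma_{ij}^2}\right)}
#' over a subset of the native contact pairs, where \eqn{r_{ij}} is the
#' instantaneous C-alpha distance, \eqn{r_{ij}^N} the native distance and
#' \eqn{\sigma_{ij}} the sequence-separation dependent width. Q is 1 when
#' every pair sits at its native distance and tends to 0 when all pairs are
#' far from native.
#'
#' @param frame_coords n x 3 matrix of C-alpha coordinates (Angstrom), rows
#'   indexed by the same 1-based residue numbering as the contact set.
#' @param contacts A `contact_set` from [build_contact_set()].
#' @param pair_subset Integer indices of rows of `contacts` to include;
#'   default all pairs (the global Q).
#' @return A value in \[0, 1\].
#' @export
compute_q <- function(frame_coords, contacts, pair_subset = NULL) {
  if (is.null(pair_subset)) pair_subset <- seq_len(nrow(contacts))
  if (length(pair_subset) == 0L) {
    stop("empty pair subset: Q normalizer undefined", call. = FALSE)
  }
  i <- contacts$i[pair_subset]; j <- contacts$j[pair_subset]
  if (max(i, j) > nrow(frame_coords)) {
    stop("frame coordinates do not cover all residues in the pair subset",
         call. = FALSE)
  }
  r <- sqrt(rowSums((frame_coords[i, , drop = FALSE] -
                     frame_coords[j, , drop = FALSE])^2))
  dn <- contacts$r_native[pair_subset]
  sg <- contacts$sigma[pair_subset]
  mean(exp(-(r - dn)^2 / (2 * sg^2)))
}

# Pair ownership: a pair belongs to foldon f if at least one endpoint lies in
# f. Cross-boundary pairs therefore contribute to both foldons' q, each with
# its own normalizer.
#' @noRd
foldon_pair_indices <- function(contacts, partition) {
  lapply(seq_len(nrow(partition)), function(f) {
    lo <- partition$start[f]; hi <- partition$end[f]
    which((contacts$i >= lo & contacts$i <= hi) |
          (contacts$j >= lo & contacts$j <= hi))
  })
}

#' Per-foldon and global Q for a frame
#'
#' Each foldon's q uses all contact pairs with at least one residue inside
#' that foldon (intra-foldon pairs plus cross-boundary pairs); the global Q
#' uses all unique pairs.
#'
#' @inheritParams compute_q
#' @param partition A `foldon_partition`.
#' @param energy Optional potential energy of the frame (model units),
#'   carried through for temperature reweighting.
#' @return A `frame_observables` list: `foldon_q` (vector in \[0,1\]),
#'   `global_q`, `energy`.
#' @export
compute_foldon_qs <- function(frame_coords, contacts, partition,
                              energy = NA_real_) {
  idx <- foldon_pair_indices(contacts, partition)
  empty <- which(vapply(idx, length, integer(1)) == 0L)
  if (length(empty) > 0L) {
    stop("foldon(s) with no eligible contact pairs: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  fq <- vapply(idx, function(p) compute_q(frame_coords, contacts, p),
               numeric(1))
  structure(list(foldon_q = fq,
                 global_q = compute_q(frame_coords, contacts),
                 energy = energy),
            class = "frame_observables")
}

#' Assign a frame to a macrobasin
#'
#' Bit f of the label is 1 iff foldon f's q strictly exceeds the foldedness
#' threshold. The leftmost character is foldon 1 (N-terminal): q =
#' (0.1, 0.9, 0.1, 0.9) at threshold 0.6 gives "0101", i.e. the second and
#' fourth foldons folded.
#'
#' @param obs A `frame_observables`, or a bare numeric vector of foldon q
#'   values.
#' @param threshold Foldedness threshold in (0, 1); default 0.6.
#' @return A macrobasin label string.
#' @export
assign_macrobasin <- function(obs, threshold = 0.6) {
  q <- if (inherits(obs, "frame_observables")) obs$foldon_q else as.numeric(obs)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  paste(as.integer(q > threshold), collapse = "")
}

#' Label a trajectory of frames
#'
#' @param frames A numeric matrix (rows = frames, columns = foldons) of q
#'   values, or a list of `frame_observables`.
#' @param threshold Foldedness threshold; see [assign_macrobasin()].
#' @return List with `labels` (character, one per frame) and `census`
#'   (named integer counts of observed macrobasins, sorted by label).
#' @export
label_trajectory <- function(frames, threshold = 0.6) {
  if (is.list(frames) && !is.data.frame(frames)) {
    nf <- unique(vapply(frames, function(f) length(f$foldon_q), integer(1)))
    if (length(nf) != 1L) {
      stop("inconsistent foldon counts across frames", call. = FALSE)
    }
    qmat <- do.call(rbind, lapply(frames, function(f) f$foldon_q))
  } else {
    qmat <- as.matrix(frames)
  }
  if (nrow(qmat) == 0L) stop("empty frame sequence", call. = FALSE)
  labels <- apply(qmat, 1L, assign_macrobasin, threshold = threshold)
  census <- table(labels)
  census <- census[order(names(census))]
  list(labels = labels,
       census = stats::setNames(as.integer(census), names(census)))
}

#' Read / write frame-observable tables
#'
#' TSV with columns `window_id`, `frame`, `energy`, `global_q`,
#' `q_1` .. `q_N`.
#'
#' @param frames Data frame in that layout.
#' @param path File path.
#' @export
write_frame_table <- function(frames, path) {
  utils::write.table(frames, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_table
#' @export
read_frame_table <- function(path) {
  df <- utils::read.delim(path)
  qcols <- grep("^q_[0-9]+$", names(df), value = TRUE)
  if (length(qcols) == 0L) stop("no q_<i> columns in ", path, call. = FALSE)
  df[, c("window_id", "frame", "energy", "global_q",
         qcols[order(as.integer(sub("^q_", "", qcols)))])]
}
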