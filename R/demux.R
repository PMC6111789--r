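#' Levenshtein edit distance between base strings
#'
#' Unit-cost substitutions, insertions and deletions. Barcode design and
#' demultiplexing use this metric so that both substitution and indel
#' sequencing errors in the barcode can be corrected.
#'
#' @param a,b character vectors; recycled against each other.
#' @return integer vector of distances (elementwise).
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  d <- integer(n)
  for (i in seq_len(n)) d[i] <- utils::adist(a[i], b[i])
  d
}

# cross matrix of edit distances (reads x barcodes), via adist in C
edit_distance_matrix <- function(a, b) {
  m <- utils::adist(a, b)
  storage.mode(m) <- "integer"
  m
}

# Separation used for barcode design: the sequence-Levenshtein distance,
# i.e. the minimum Levenshtein distance over all truncations of either
# barcode. In a read the bases following a barcode are arbitrary insert
# sequence, so an indel near the barcode end shifts the boundary; only this
# truncation-closed metric guarantees that error balls of different
# barcodes cannot collide at the boundary. (The DP-table row/column minima
# of the Levenshtein computation are exactly the truncation distances.)
barcode_separation <- function(a, b) {
  ta <- substring(a, 1, 0:nchar(a))
  tb <- substring(b, 1, 0:nchar(b))
  min(utils::adist(a, tb), utils::adist(ta, b))
}

#' Design a set of error-tolerant variable-length barcodes
#'
#' Greedily accumulates random barcodes of lengths in `length_range`,
#' accepting a candidate only if its sequence-Levenshtein distance (the
#' minimum Levenshtein distance over all truncations of either barcode,
#' which accounts for indels at the barcode/insert boundary) to every
#' accepted barcode is at least `min_distance`. A floor of `2k + 1` permits
#' correction of up to `k` errors per read.
#'
#' @param n number of barcodes (one per pooled sample).
#' @param length_range integer range of barcode lengths, within 6-9.
#' @param min_distance minimum pairwise edit distance.
#' @param seed integer seed; the greedy search is deterministic under it.
#' @param max_attempts candidate budget before giving up.
#' @return a `barcode_set` data.frame (`sample_id`, `barcode`) with
#'   attribute `min_pairwise_distance`.
#' @export
design_barcodes <- function(n, length_range = c(6, 9), min_distance = 3,
                            seed = NULL, max_attempts = 500 * n) {
  if (!is_count(n)) stop_param("n must be a positive integer")
  if (min_distance < 1) stop_param("min_distance must be >= 1")
  if (length_range[1] < 6 || length_range[2] > 9 ||
      length_range[1] > length_range[2])
    stop_param("length_range must lie within [6, 9]")
  with_seed(seed, {
    accepted <- character(0)
    lengths <- seq.int(length_range[1], length_range[2])
    attempts <- 0L
    while (length(accepted) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      L <- if (length(lengths) == 1) lengths else sample(lengths, 1)
      cand <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
      ok <- all(vapply(accepted, function(b)
        barcode_separation(cand, b) >= min_distance, logical(1)))
      if (ok) accepted <- c(accepted, cand)
    }
    if (length(accepted) < n)
      stop_param("could not design ", n, " barcodes at min_distance ",
                 min_distance, " within ", max_attempts,
                 " attempts: relax the constraints")
    out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                      barcode = accepted, stringsAsFactors = FALSE)
    attr(out, "min_pairwise_distance") <- min_distance
    class(out) <- c("barcode_set", "data.frame")
    out
  })
}

#' Validate a barcode set against its invariants
#'
#' Checks uniqueness, 6-9 bp lengths and the pairwise edit-distance floor.
#'
#' @param barcode_set data.frame with `sample_id` and `barcode`.
#' @param min_distance floor to verify; defaults to the set's own attribute
#'   (or 1).
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_barcodes <- function(barcode_set, min_distance = NULL) {
  bc <- as.data.frame(barcode_set)
  if (anyDuplicated(bc$barcode)) stop_param("duplicate barcodes in set")
  if (any(nchar(bc$barcode) < 6 | nchar(bc$barcode) > 9))
    stop_param("barcode lengths must lie within [6, 9]")
  min_distance <- min_distance %||%
    (attr(barcode_set, "min_pairwise_distance") %||% 1)
  if (nrow(bc) > 1) {
    cmb <- utils::combn(nrow(bc), 2)
    d <- apply(cmb, 2, function(ij)
      barcode_separation(bc$barcode[ij[1]], bc$barcode[ij[2]]))
    if (min(d) < min_distance)
      stop_param("pairwise barcode distance ", min(d),
                 " below required ", min_distance)
  }
  invisible(TRUE)
}

#' Trim the buffer and low-quality read tails
#'
#' Removes the leading `buffer_length` bases (the constant buffer that keeps
#' the barcode inside the high-quality region of the read), then trims
#' trailing bases while the terminal base quality is below `min_quality`
#' (default Q36, ~99.99% base-call accuracy). Reads that end up empty, or
#' were shorter than the buffer, are discarded and counted.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33 string).
#' @param buffer_length leading bases to drop.
#' @param min_quality minimum terminal Phred quality kept.
#' @return the trimmed read data.frame, with attribute `n_discarded`.
#' @export
trim_reads <- function(reads, buffer_length = 8, min_quality = 36) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop_param("sequence and quality strings must have equal length")
  n <- nrow(reads)
  keep_len <- integer(n)
  for (i in seq_len(n)) {
    L <- nchar(reads$qual[i])
    if (L <= buffer_length) { keep_len[i] <- 0L; next }
    q <- utf8ToInt(substr(reads$qual[i], buffer_length + 1, L)) - 33L
    last <- length(q)
    while (last > 0 && q[last] < min_quality) last <- last - 1L
    keep_len[i] <- last
  }
  out <- data.frame(
    id = reads$id,
    seq = substr(reads$seq, buffer_length + 1, buffer_length + keep_len),
    qual = substr(reads$qual, buffer_length + 1, buffer_length + keep_len),
    stringsAsFactors = FALSE)
  discarded <- keep_len == 0L
  out <- out[!discarded, , drop = FALSE]
  rownames(out) <- NULL
  if (any(discarded))
    warning(sum(discarded), " read(s) discarded: shorter than buffer or fully below Q",
            min_quality, call. = FALSE)
  attr(out, "n_discarded") <- sum(discarded)
  out
}

#' Demultiplex pooled reads by barcode with edit-distance rescue
#'
#' After removing the leading `buffer_length` bases, each read's prefix is
#' compared to every barcode at that barcode's length. The read is assigned
#' to the unique barcode of minimal edit distance `<= max_distance`; ties at
#' the minimal distance between barcodes of *different* samples make the
#' read unassigned, while ties between barcodes of the same sample prefer
#' the longest barcode (whose length is then removed from the read).
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param barcode_set a [design_barcodes()] result or (`sample_id`,
#'   `barcode`) data.frame.
#' @param max_distance maximum barcode edit distance rescued (default 1).
#' @param buffer_length leading bases to drop before matching (0 if the
#'   reads were already buffer-trimmed).
#' @return list with `samples` (named list of read data.frames, barcode
#'   removed), `unassigned` (read data.frame), `assignments` (per-read
#'   table) and `report` (per-sample counts).
#' @export
demultiplex <- function(reads, barcode_set, max_distance = 1,
                        buffer_length = 8) {
  bc <- as.data.frame(barcode_set)
  validate_barcodes(bc, min_distance = 1)
  mpd <- attr(barcode_set, "min_pairwise_distance")
  if (!is.null(mpd) && max_distance >= mpd / 2)
    warning("max_distance ", max_distance, " >= min_pairwise_distance/2 (",
            mpd, "/2): unambiguous error correction is not guaranteed",
            call. = FALSE)
  n <- nrow(reads)
  body <- substr(reads$seq, buffer_length + 1, nchar(reads$seq))
  qbody <- substr(reads$qual, buffer_length + 1, nchar(reads$qual))

  nb <- nrow(bc)
  # indel errors shift the barcode/insert boundary, so each barcode is
  # compared against read prefixes of its own length +/- max_distance and
  # the minimum distance over those windows is used
  dist_mat <- matrix(NA_integer_, n, nb)
  for (L in sort(unique(nchar(bc$barcode)))) {
    idx <- which(nchar(bc$barcode) == L)
    d <- NULL
    for (w in seq.int(max(1L, L - max_distance), L + max_distance)) {
      dw <- edit_distance_matrix(substr(body, 1, w), bc$barcode[idx])
      d <- if (is.null(d)) dw else pmin(d, dw)
    }
    dist_mat[, idx] <- d
  }
  best <- apply(dist_mat, 1, min)
  assigned_bc <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (best[i] > max_distance) next
    cand <- which(dist_mat[i, ] == best[i])
    if (length(unique(bc$sample_id[cand])) > 1L) next   # cross-sample tie
    # same sample at several lengths: take the longest barcode
    assigned_bc[i] <- cand[which.max(nchar(bc$barcode[cand]))]
  }
  ok <- !is.na(assigned_bc)
  blen <- ifelse(ok, nchar(bc$barcode[assigned_bc]), 0L)
  assignments <- data.frame(
    id = reads$id,
    sample_id = ifelse(ok, bc$sample_id[assigned_bc], NA_character_),
    barcode = ifelse(ok, bc$barcode[assigned_bc], NA_character_),
    distance = ifelse(ok, best, NA_integer_),
    stringsAsFactors = FALSE)
  trimmed <- data.frame(id = reads$id,
                        seq = substr(body, blen + 1, nchar(body)),
                        qual = substr(qbody, blen + 1, nchar(qbody)),
                        stringsAsFactors = FALSE)
  samples <- split(trimmed[ok, , drop = FALSE],
                   factor(assignments$sample_id[ok], levels = bc$sample_id))
  unassigned <- trimmed[!ok, , drop = FALSE]
  rownames(unassigned) <- NULL
  report <- data.frame(sample_id = c(bc$sample_id, "unassigned"),
                       n_reads = c(vapply(samples, nrow, integer(1)),
                                   nrow(unassigned)),
                       stringsAsFactors = FALSE)
  stopifnot(sum(report$n_reads) == n)   # conservation
  list(samples = samples, unassigned = unassigned,
       assignments = assignments, report = report)
}
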