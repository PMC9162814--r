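#' MIT-BIH cross-patient record split
#'
#' The fixed training-set record list (`DS1`) used for cross-patient
#' evaluation on the MIT-BIH arrhythmia database, the two records excluded
#' because their first channel is not MLII, and the full 48-record roster.
#'
#' @format `MITBIH_DS1` is a character vector of 22 record names;
#'   `MITBIH_EXCLUDED` the 2 excluded records; `MITBIH_ALL_RECORDS` all 48.
#' @name mitbih_split
NULL

#' @rdname mitbih_split
#' @export
MITBIH_DS1 <- c("101", "106", "108", "109", "112", "114", "115", "116",
                "118", "119", "122", "124", "201", "203", "205", "207",
                "208", "209", "215", "220", "223", "230")

#' @rdname mitbih_split
#' @export
MITBIH_EXCLUDED <- c("102", "104")

#' @rdname mitbih_split
#' @export
MITBIH_ALL_RECORDS <- c(
  "100", "101", "102", "103", "104", "105", "106", "107", "108", "109",
  "111", "112", "113", "114", "115", "116", "117", "118", "119", "121",
  "122", "123", "124", "200", "201", "202", "203", "205", "207", "208",
  "209", "210", "212", "213", "214", "215", "217", "219", "220", "221",
  "222", "223", "228", "230", "231", "232", "233", "234")

#' Split record ids into the fixed DS1/DS2 cross-patient partition
#'
#' Drops records 102 and 104 (first channel not MLII), then partitions the
#' remaining ids: those on the fixed DS1 list train, the rest validate. Train
#' and validation therefore never share a patient.
#'
#' @param available_record_ids Character (or numeric) vector of MIT-BIH
#'   record names, drawn from the 48-record roster.
#' @return A list with character vectors `ds1` and `ds2`.
#' @export
#' @examples
#' sp <- split_ds1_ds2(MITBIH_ALL_RECORDS)
#' length(sp$ds1) # 22
#' length(sp$ds2) # 24
split_ds1_ds2 <- function(available_record_ids) {
  ids <- as.character(available_record_ids)
  unknown <- setdiff(ids, MITBIH_ALL_RECORDS)
  if (length(unknown) > 0) {
    stop("unknown record id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ids <- setdiff(ids, MITBIH_EXCLUDED)
  list(ds1 = intersect(MITBIH_DS1, ids),
       ds2 = setdiff(ids, MITBIH_DS1))
}

#' Extract a fixed-length window centred on a sample
#'
#' Returns the `2 * half_width + 1` samples centred on `center`. Windows that
#' would overrun the record boundary raise a condition of class
#' `qrsnet_boundary` so callers can skip the candidate.
#'
#' @param signal An [ecg_signal].
#' @param center 0-based sample index of the window centre.
#' @param half_width Half-width in samples (window length `2*half_width+1`;
#'   50/75/100 give the standard 101/151/201 lengths).
#' @return Numeric vector of `2 * half_width + 1` voltages.
#' @export
extract_window <- function(signal, center, half_width) {
  stopifnot(inherits(signal, "ecg_signal"))
  n <- length(signal$samples)
  if (center - half_width < 0 || center + half_width >= n) {
    cond <- structure(
      class = c("qrsnet_boundary", "error", "condition"),
      list(message = sprintf(
             "window [%d, %d] overruns signal of length %d",
             center - half_width, center + half_width, n),
           call = sys.call(-1)))
    stop(cond)
  }
  # 0-based center -> 1-based R indexing
  signal$samples[(center - half_width + 1L):(center + half_width + 1L)]
}

#' Sample random non-R window centres
#'
#' Draws `n` distinct positions uniformly from the samples lying at least
#' `min_distance` samples from every annotated R peak (and far enough from the
#' record edges to fit a window of the given half-width, when supplied via
#' `half_width`). Reproducible under `seed`.
#'
#' @param annotation An [rpeak_annotation] of true R peaks.
#' @param signal_length Record length in samples.
#' @param n Number of negative centres to draw.
#' @param min_distance Minimum distance in samples from any annotated peak
#'   (default 25, about 70 ms at 360 Hz).
#' @param seed Integer seed.
#' @param half_width Optional half-width; when given, candidates too close to
#'   the record boundary are excluded up front.
#' @return Integer vector of `n` strictly increasing 0-based sample indices.
#' @export
sample_negative_centers <- function(annotation, signal_length, n,
                                    min_distance = 25, seed = 1L,
                                    half_width = 0L) {
  stopifnot(inherits(annotation, "rpeak_annotation"))
  pos <- seq.int(half_width, signal_length - 1L - half_width)
  if (length(annotation$indices) > 0) {
    # distance from each candidate to the nearest annotated peak
    near <- findInterval(pos, annotation$indices)
    d_lo <- ifelse(near >= 1, pos - annotation$indices[pmax(near, 1L)], Inf)
    d_hi <- ifelse(near < length(annotation$indices),
                   annotation$indices[pmin(near + 1L,
                                           length(annotation$indices))] - pos,
                   Inf)
    dist <- pmin(d_lo, d_hi)
    pos <- pos[dist >= min_distance]
  }
  if (length(pos) < n) {
    stop(sprintf("only %d eligible negative positions for n = %d",
                 length(pos), n), call. = FALSE)
  }
  set.seed(as.integer(seed))
  sort(sample(pos, n))
}

#' Build a labelled fixed-length window dataset
#'
#' For each record, takes one positive window per annotated R peak (peaks too
#' close to the boundary are skipped) and `ceiling(ratio * positives)` random
#' non-R windows at least `min_distance` samples from any peak. Every window
#' is z-score normalised per segment (mean 0, sd 1; flat segments map to
#' zeros) — the scaling the window classifier is trained on.
#'
#' @param records List of record entries, each a list with elements `signal`
#'   ([ecg_signal]) and `annotation` ([rpeak_annotation]).
#' @param half_width Window half-width in samples (50, 75 or 100 for the
#'   standard lengths).
#' @param negatives_per_positive Ratio of negative to positive windows
#'   (default 1 for class balance).
#' @param min_distance Minimum negative-to-peak distance in samples.
#' @param seed Integer seed for negative sampling.
#'
#' @return An object of class `window_dataset`: list with `x` (matrix,
#'   one row per window, `2*half_width+1` columns), `label` (factor
#'   `R`/`nonR`), `center` (0-based centres), `record_id`, `half_width`,
#'   `class_counts`.
#' @export
build_window_dataset <- function(records, half_width = 75,
                                 negatives_per_positive = 1,
                                 min_distance = 25, seed = 1L) {
  if (length(records) == 0) stop("`records` must be non-empty", call. = FALSE)
  if (!half_width %in% c(50L, 75L, 100L)) {
    # other widths work mechanically but are outside the studied lengths
    warning("half_width outside the standard {50, 75, 100}")
  }
  win_len <- 2L * half_width + 1L
  xs <- list()
  labels <- character(0)
  centers <- integer(0)
  rec_ids <- character(0)
  set.seed(as.integer(seed))
  rec_seeds <- sample.int(.Machine$integer.max, length(records))

  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    sig <- rec$signal
    ann <- rec$annotation
    n <- length(sig$samples)
    usable <- ann$indices[ann$indices - half_width >= 0 &
                          ann$indices + half_width < n]
    n_skip <- length(ann$indices) - length(usable)
    if (n_skip > 0) {
      warning(sprintf("record '%s': skipped %d boundary peak(s)",
                      sig$record_id, n_skip))
    }
    if (length(usable) == 0) next
    n_neg <- ceiling(negatives_per_positive * length(usable))
    neg <- sample_negative_centers(ann, n, n_neg, min_distance,
                                   seed = rec_seeds[ri],
                                   half_width = half_width)
    cen <- c(usable, neg)
    lab <- c(rep("R", length(usable)), rep("nonR", length(neg)))
    m <- matrix(0, length(cen), win_len)
    for (i in seq_along(cen)) {
      m[i, ] <- extract_window(sig, cen[i], half_width)
    }
    xs[[length(xs) + 1L]] <- m
    labels <- c(labels, lab)
    centers <- c(centers, cen)
    rec_ids <- c(rec_ids, rep(sig$record_id, length(cen)))
  }
  if (length(xs) == 0) stop("no usable windows in any record", call. = FALSE)
  x <- do.call(rbind, xs)
  x <- normalize_segments(x)
  label <- factor(labels, levels = c("nonR", "R"))
  structure(
    list(x = x, label = label, center = centers, record_id = rec_ids,
         half_width = as.integer(half_width),
         class_counts = table(label)),
    class = "window_dataset"
  )
}

#' Per-segment z-score normalisation
#'
#' Centres and scales each row of a window matrix to mean 0 and sd 1. Flat
#' rows (sd 0) map to all zeros.
#'
#' @param x Numeric matrix, one window per row.
#' @return Matrix of the same shape.
#' @export
normalize_segments <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowSums(xc^2) / (ncol(x) - 1L))
  sdv[sdv == 0] <- Inf  # flat rows -> zeros
  xc / sdv
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf(
    "<window_dataset> %d windows of length %d (R: %d, nonR: %d) from %d record(s)\n",
    nrow(x$x), 2L * x$half_width + 1L,
    sum(x$label == "R"), sum(x$label == "nonR"),
    length(unique(x$record_id))))
  invisible(x)
}
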