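# Sequence-level zipcode analysis: degenerate motif scanning, GA-content
# windows, GA-rich region calling, overlap and enrichment statistics,
# deletion-construct arithmetic and antisense-probe classification.
#
# Coordinates are 1-based inclusive throughout (so "nucleotides 204-211" is an
# 8-nt interval); BED export converts to 0-based half-open.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Normalize an RNA/DNA sequence for scanning
#'
#' Upper-cases, maps U to T, and rejects any residue outside A/C/G/T
#' (ambiguity codes are not accepted in input sequences).
#'
#' @param sequence a single character string.
#' @return The normalized sequence string.
#' @export
normalize_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      nchar(sequence) == 0)
    stop("sequence must be a single non-empty string", call. = FALSE)
  s <- chartr("u", "T", chartr("U", "T", toupper(sequence)))
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0)
    stop(sprintf("invalid residue '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  s
}

#' Construct a labeled 3'UTR sequence set
#'
#' @param id character vector of unique sequence ids.
#' @param sequence character vector of sequences (U is mapped to T; only
#'   A/C/G/T accepted after normalization).
#' @param group group label per sequence (e.g. "APC-dependent" /
#'   "APC-independent").
#' @return A `utr_set` data frame with columns `id`, `sequence`, `group`.
#' @export
utr_set <- function(id, sequence, group) {
  stopifnot(length(id) == length(sequence), length(id) == length(group))
  if (anyDuplicated(id))
    stop("duplicate ids in UTR set: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  sequence <- vapply(sequence, normalize_sequence, character(1),
                     USE.NAMES = FALSE)
  out <- data.frame(id = as.character(id), sequence = sequence,
                    group = as.character(group), stringsAsFactors = FALSE)
  class(out) <- c("utr_set", "data.frame")
  out
}

#' Degenerate motif specification
#'
#' The default consensus is RGAAGRR, the 7-nt GA-rich element (R = purine,
#' A or G) found in 3'UTRs of protrusion-localized, APC-dependent mRNAs.
#'
#' @param consensus IUPAC consensus string.
#' @return A `motif_spec` object with fields `consensus` and `length`.
#' @export
motif_spec <- function(consensus = "RGAAGRR") {
  if (!is.character(consensus) || length(consensus) != 1 ||
      nchar(consensus) == 0)
    stop("consensus must be a single non-empty string", call. = FALSE)
  consensus <- toupper(consensus)
  chars <- strsplit(consensus, "")[[1]]
  if (!all(chars %in% names(IUPAC_SETS)))
    stop("consensus contains non-IUPAC characters: ",
         paste(setdiff(chars, names(IUPAC_SETS)), collapse = ", "),
         call. = FALSE)
  structure(list(consensus = consensus, length = nchar(consensus)),
            class = "motif_spec")
}

as_sequence <- function(record) {
  if (inherits(record, "utr_set")) {
    stopifnot(nrow(record) == 1)
    record$sequence
  } else if (is.list(record) && !is.null(record$sequence)) {
    record$sequence
  } else {
    normalize_sequence(record)
  }
}

record_id <- function(record) {
  if ((is.list(record) || is.data.frame(record)) && !is.null(record$id))
    as.character(record$id)[1]
  else NA_character_
}

#' Scan a sequence for a degenerate IUPAC motif
#'
#' Reports all matches, including overlapping ones, sorted by start. A
#' position matches when every sequence residue lies in the IUPAC set of the
#' corresponding consensus character. Scanning is single-stranded (mRNA
#' sense); the reverse complement is never searched.
#'
#' @param record a single-row `utr_set`, a list with `$sequence` (and
#'   optionally `$id`), or a plain sequence string.
#' @param spec a [motif_spec()].
#' @return A data frame of hits: `utr_id`, `start`, `end` (1-based
#'   inclusive), `matched`.
#' @export
scan_motif <- function(record, spec = motif_spec()) {
  seq <- as_sequence(record)
  id <- record_id(record)
  k <- spec$length
  n <- nchar(seq)
  empty <- data.frame(utr_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  if (n < k) return(empty)
  chars <- strsplit(seq, "")[[1]]
  cons <- strsplit(spec$consensus, "")[[1]]
  starts <- seq_len(n - k + 1)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(k)) {
    ok <- ok & chars[starts + j - 1L] %in% IUPAC_SETS[[cons[j]]]
  }
  s <- starts[ok]
  if (!length(s)) return(empty)
  data.frame(utr_id = rep(id, length(s)), start = s, end = s + k - 1L,
             matched = substring(seq, s, s + k - 1L),
             stringsAsFactors = FALSE)
}

#' Sliding-window GA-content profile
#'
#' Fraction of G+A residues in each window of width `window` (default 30 nt,
#' the window used to plot %GA content along the Rab13 3'UTR), advancing by
#' `step`.
#'
#' @inheritParams scan_motif
#' @param window window width in nt.
#' @param step step between window starts in nt.
#' @return A data frame with `window_start` (1-based) and `ga_fraction`,
#'   carrying the sequence length as attribute `seq_length`.
#' @export
ga_profile <- function(record, window = 30, step = 1) {
  stop_if_not_scalar_number(window, "window", 1)
  stop_if_not_scalar_number(step, "step", 1)
  seq <- as_sequence(record)
  n <- nchar(seq)
  if (n < window)
    stop(sprintf("sequence length %d is shorter than window %d", n, window),
         call. = FALSE)
  isga <- strsplit(seq, "")[[1]] %in% c("G", "A")
  cs <- c(0, cumsum(isga))
  starts <- seq(1L, n - window + 1L, by = as.integer(step))
  frac <- (cs[starts + window] - cs[starts]) / window
  structure(data.frame(window_start = starts, ga_fraction = frac),
            seq_length = n)
}

#' GA-rich region parameters
#'
#' Defaults operationalize "GA content > 75% for at least 30 consecutive
#' nucleotides": 30-nt windows, strict > 0.75, minimum region length 30 nt.
#'
#' @param window window width in nt.
#' @param min_ga minimum GA fraction, strict inequality.
#' @param min_len minimum region length in nt (must be >= `window`).
#' @export
region_params <- function(window = 30, min_ga = 0.75, min_len = 30) {
  stop_if_not_scalar_number(window, "window", 1)
  if (!(min_ga > 0 && min_ga < 1))
    stop("min_ga must lie strictly between 0 and 1", call. = FALSE)
  if (min_len < window)
    stop("min_len must be >= window", call. = FALSE)
  structure(list(window = window, min_ga = min_ga, min_len = min_len),
            class = "region_params")
}

#' Detect GA-rich regions
#'
#' Every window of `params$window` nt whose GA fraction strictly exceeds
#' `params$min_ga` qualifies; regions are the maximal merged unions of
#' qualifying windows (so a region can extend a few nt into flanking
#' pyrimidines), filtered to length >= `params$min_len`, reported sorted and
#' non-overlapping with the GA fraction over their full span.
#'
#' @inheritParams scan_motif
#' @param params a [region_params()].
#' @return Data frame with `utr_id`, `start`, `end`, `ga_fraction`.
#' @export
detect_ga_rich_regions <- function(record, params = region_params()) {
  seq <- as_sequence(record)
  id <- record_id(record)
  prof <- ga_profile(record, window = params$window, step = 1)
  q <- prof$window_start[prof$ga_fraction > params$min_ga]
  empty <- data.frame(utr_id = character(), start = integer(),
                      end = integer(), ga_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(q)) return(empty)
  w <- params$window
  # merge qualifying windows [s, s+w-1]: a gap opens when the next qualifying
  # start lies beyond the current region end
  ends <- q + w - 1L
  brk <- which(q[-1] > cummax(ends[-length(ends)]) + 1L)
  grp <- rep(seq_len(length(brk) + 1L), diff(c(0L, brk, length(q))))
  starts <- tapply(q, grp, min)
  rends <- tapply(ends, grp, max)
  keep <- (rends - starts + 1L) >= params$min_len
  starts <- as.integer(starts[keep]); rends <- as.integer(rends[keep])
  if (!length(starts)) return(empty)
  isga <- strsplit(seq, "")[[1]] %in% c("G", "A")
  cs <- c(0, cumsum(isga))
  frac <- (cs[rends + 1L] - cs[starts]) / (rends - starts + 1L)
  data.frame(utr_id = rep(id, length(starts)), start = starts, end = rends,
             ga_fraction = frac, stringsAsFactors = FALSE)
}

#' Fraction of motif hits contained in GA-rich regions
#'
#' A hit counts as inside only when its full span is contained in a region
#' of the same UTR (the containment semantics behind "148 of 239 motifs are
#' found within more extended GA-rich regions").
#'
#' @param hits data frame from [scan_motif()] (possibly row-bound over
#'   records).
#' @param regions data frame from [detect_ga_rich_regions()].
#' @return A list with `n_inside`, `n_total` and `fraction` (`NA` when there
#'   are no hits).
#' @export
motif_region_overlap <- function(hits, regions) {
  stopifnot(is.data.frame(hits), is.data.frame(regions))
  if (nrow(hits) && nrow(regions)) {
    known <- stats::na.omit(unique(regions$utr_id))
    seen <- stats::na.omit(unique(hits$utr_id))
    if (length(known) && length(seen) && !any(seen %in% known) &&
        !any(known %in% seen) && !all(is.na(hits$utr_id)))
      stop("hits and regions share no utr_id", call. = FALSE)
  }
  n_total <- nrow(hits)
  if (n_total == 0)
    return(list(n_inside = 0L, n_total = 0L, fraction = NA_real_))
  inside <- vapply(seq_len(n_total), function(i) {
    r <- regions[is.na(hits$utr_id[i]) | is.na(regions$utr_id) |
                   regions$utr_id == hits$utr_id[i], , drop = FALSE]
    any(r$start <= hits$start[i] & hits$end[i] <= r$end)
  }, logical(1))
  n_inside <- sum(inside)
  list(n_inside = as.integer(n_inside), n_total = as.integer(n_total),
       fraction = n_inside / n_total)
}

#' Per-UTR motif and region summary table
#'
#' One row per record (`has_motif`, `n_motifs`, `n_regions`,
#' `n_motifs_in_region`) plus per-group aggregates (fraction of UTRs carrying
#' at least one motif), the statistic behind "~60% of APC-dependent RNAs".
#'
#' @param records a `utr_set`.
#' @param spec a [motif_spec()].
#' @param params a [region_params()].
#' @return A list with `per_utr` (data frame) and `group_fraction` (named
#'   numeric).
#' @export
summarize_groups <- function(records, spec = motif_spec(),
                             params = region_params()) {
  stopifnot(inherits(records, "utr_set") || is.data.frame(records))
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  if (anyDuplicated(records$id))
    stop("duplicate ids in record set", call. = FALSE)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    class(rec) <- c("utr_set", "data.frame")
    hits <- scan_motif(rec, spec)
    regs <- if (nchar(rec$sequence) >= params$window)
      detect_ga_rich_regions(rec, params)
    else
      data.frame(utr_id = character(), start = integer(), end = integer(),
                 ga_fraction = numeric())
    ov <- motif_region_overlap(hits, regs)
    data.frame(id = rec$id, group = rec$group,
               has_motif = nrow(hits) > 0, n_motifs = nrow(hits),
               n_regions = nrow(regs),
               n_motifs_in_region = ov$n_inside,
               stringsAsFactors = FALSE)
  })
  per_utr <- do.call(rbind, rows)
  group_fraction <- tapply(per_utr$has_motif, per_utr$group, mean)
  list(per_utr = per_utr,
       group_fraction = group_fraction[!is.na(group_fraction)])
}

#' Two-group motif enrichment (Fisher's exact test, Bonferroni-corrected)
#'
#' Builds the 2x2 table (group x has-motif) and computes the two-sided
#' Fisher exact p-value (summation of hypergeometric probabilities no larger
#' than the observed table's), with Bonferroni correction over `m_tests`
#' hypotheses.
#'
#' @param flags_a,flags_b logical vectors: motif presence per UTR in each
#'   group.
#' @param m_tests number of tests for the Bonferroni correction (>= 1).
#' @return A list with `table`, `odds_ratio` (conditional MLE), `p_value`,
#'   `p_bonferroni` and `m_tests`.
#' @export
motif_enrichment <- function(flags_a, flags_b, m_tests = 1) {
  stopifnot(is.logical(flags_a), is.logical(flags_b))
  if (!length(flags_a) || !length(flags_b))
    stop("both groups must be non-empty", call. = FALSE)
  stop_if_not_scalar_number(m_tests, "m_tests", 1)
  tab <- matrix(c(sum(flags_a), sum(!flags_a),
                  sum(flags_b), sum(!flags_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("A", "B"),
                                motif = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value,
       p_bonferroni = min(1, m_tests * ft$p.value),
       m_tests = as.integer(m_tests))
}

validate_intervals <- function(deletions, seq_len) {
  stopifnot(is.data.frame(deletions),
            all(c("start", "end") %in% names(deletions)))
  d <- deletions[order(deletions$start), , drop = FALSE]
  if (any(d$start < 1 | d$end > seq_len | d$start > d$end))
    stop("deletion interval out of range or inverted", call. = FALSE)
  if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
    stop("deletion intervals overlap", call. = FALSE)
  d
}

#' Apply deletion intervals to a UTR and remap annotations
#'
#' Removes the given 1-based inclusive intervals from the sequence (e.g. the
#' 8-nt region-1 deletion 204-211, or the 53-nt 202-254 deletion spanning the
#' antisense-targeted GA-rich region). Annotations overlapping a deleted
#' position are dropped with a warning; surviving annotations shift left by
#' the total length removed upstream of them.
#'
#' @inheritParams scan_motif
#' @param deletions data frame with `start`, `end` columns (non-overlapping,
#'   in range).
#' @param annotations optional data frame with `start`, `end` columns to
#'   remap (e.g. motif hits).
#' @return A list with `sequence` (spliced string), `removed_nt`, and
#'   `annotations` (remapped, possibly fewer rows).
#' @export
apply_deletion <- function(record, deletions, annotations = NULL) {
  seq <- as_sequence(record)
  n <- nchar(seq)
  d <- validate_intervals(deletions, n)
  deleted <- logical(n)
  for (i in seq_len(nrow(d))) deleted[d$start[i]:d$end[i]] <- TRUE
  keep <- which(!deleted)
  new_seq <- paste(strsplit(seq, "")[[1]][keep], collapse = "")
  removed <- sum(deleted)
  new_ann <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    shift_at <- cumsum(deleted)  # removed nt at or before each position
    overlaps <- vapply(seq_len(nrow(annotations)), function(i)
      any(deleted[annotations$start[i]:annotations$end[i]]), logical(1))
    if (any(overlaps))
      warning(sprintf("%d annotation(s) overlapping a deletion were dropped",
                      sum(overlaps)), call. = FALSE)
    new_ann <- annotations[!overlaps, , drop = FALSE]
    if (nrow(new_ann)) {
      new_ann$start <- new_ann$start - shift_at[new_ann$start]
      new_ann$end <- new_ann$end - shift_at[new_ann$end]
    }
  }
  list(sequence = new_seq, removed_nt = as.integer(removed),
       annotations = new_ann)
}

#' Classify an antisense probe interval against motifs and GA-rich regions
#'
#' Mirrors how 25-nt PMO probes are described: a probe that intersects any
#' motif hit (>= 1 nt overlap) is `overlaps_motif`; otherwise one that
#' intersects a GA-rich region is `overlaps_ga_region`; otherwise `outside`.
#'
#' @param probe_start 1-based start of the probe.
#' @param probe_length probe length in nt (default 25).
#' @param regions,hits data frames with `start`, `end` columns.
#' @param seq_length sequence length for bounds checking (optional).
#' @return One of `"overlaps_motif"`, `"overlaps_ga_region"`, `"outside"`.
#' @export
classify_probe <- function(probe_start, probe_length = 25, regions, hits,
                           seq_length = NULL) {
  stop_if_not_scalar_number(probe_start, "probe_start", 1)
  stop_if_not_scalar_number(probe_length, "probe_length", 1)
  pe <- probe_start + probe_length - 1
  if (!is.null(seq_length) && (probe_start < 1 || pe > seq_length))
    stop("probe interval out of sequence bounds", call. = FALSE)
  intersects <- function(df) nrow(df) > 0 &&
    any(df$start <= pe & df$end >= probe_start)
  if (intersects(hits)) "overlaps_motif"
  else if (intersects(regions)) "overlaps_ga_region"
  else "outside"
}
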