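# Ratio-based enrichment quantification: protrusion/cell-body (Ps/CB)
# fractionation normalized to housekeeping genes, and spike-normalized RNA
# co-immunoprecipitation referenced to a control gene.

#' Construct a fractionation count matrix
#'
#' @param counts non-negative genes x samples matrix with dimnames.
#' @param samples data frame with columns `sample`, `fraction` (values
#'   `"Ps"`/`"CB"` or `"eluate"`/`"input"`) and `replicate`.
#' @param housekeeping character vector of housekeeping gene ids (required
#'   for [ps_cb_enrichment()]; there is no default set).
#' @param spike optional spike-in gene id (required for
#'   [rip_enrichment()]).
#' @return A `fraction_counts` object.
#' @export
fraction_counts <- function(counts, samples, housekeeping = character(),
                            spike = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), is.data.frame(samples),
            all(c("sample", "fraction", "replicate") %in% names(samples)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!identical(colnames(counts), samples$sample))
    stop("column names of counts must match samples$sample", call. = FALSE)
  missing <- setdiff(c(housekeeping, spike), rownames(counts))
  if (length(missing))
    stop("normalizer gene(s) absent from the count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(counts = counts, samples = samples,
                 housekeeping = housekeeping, spike = spike),
            class = "fraction_counts")
}

#' @export
print.fraction_counts <- function(x, ...) {
  cat(sprintf("fraction_counts: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$fraction), collapse = "/")))
  invisible(x)
}

sample_for <- function(fc, fraction, replicate) {
  i <- which(fc$samples$fraction == fraction &
               fc$samples$replicate == replicate)
  if (length(i) != 1)
    stop(sprintf("expected exactly one '%s' sample in replicate %s",
                 fraction, replicate), call. = FALSE)
  fc$counts[, i]
}

aggregate_ratios <- function(ratio_mat) {
  # ratio_mat: genes x replicates, may contain NA for flagged entries
  n <- rowSums(!is.na(ratio_mat))
  mean_r <- rowMeans(ratio_mat, na.rm = TRUE)
  sd_r <- apply(ratio_mat, 1, stats::sd, na.rm = TRUE)
  data.frame(gene = rownames(ratio_mat), mean_ratio = mean_r,
             sem = sd_r / sqrt(n), n = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Protrusion/cell-body enrichment ratios
#'
#' Per replicate, each gene's counts are normalized to the geometric mean of
#' the housekeeping set within the same sample, and the enrichment ratio is
#' the normalized Ps value over the normalized CB value:
#' \deqn{r_g = \frac{Ps_g / \mathrm{geomean}(Ps_{hk})}{CB_g /
#'   \mathrm{geomean}(CB_{hk})}}
#' Ratios are aggregated across replicates as mean ± s.e.m. Replicates with
#' a zero housekeeping count are excluded with a warning; a zero CB count
#' flags that gene's replicate ratio as undefined (`NA`).
#'
#' @param fc a [fraction_counts()] with paired Ps/CB samples and a
#'   non-empty housekeeping set.
#' @return A data frame (`gene`, `mean_ratio`, `sem`, `n`) with the
#'   per-replicate ratio matrix in attribute `replicate_ratios`.
#' @export
ps_cb_enrichment <- function(fc) {
  stopifnot(inherits(fc, "fraction_counts"))
  if (!length(fc$housekeeping))
    stop("a housekeeping gene set is required", call. = FALSE)
  fr <- unique(fc$samples$fraction)
  labs <- if (all(c("Ps", "CB") %in% fr)) c("Ps", "CB")
  else if (all(c("eluate", "input") %in% fr)) c("eluate", "input")
  else stop("samples must be labeled Ps/CB (or eluate/input)", call. = FALSE)
  reps <- sort(unique(fc$samples$replicate))
  genes <- rownames(fc$counts)
  ratio_mat <- matrix(NA_real_, length(genes), length(reps),
                      dimnames = list(genes, reps))
  for (j in seq_along(reps)) {
    ps <- sample_for(fc, labs[1], reps[j])
    cb <- sample_for(fc, labs[2], reps[j])
    hk_ps <- ps[fc$housekeeping]; hk_cb <- cb[fc$housekeeping]
    if (any(hk_ps == 0) || any(hk_cb == 0)) {
      warning(sprintf("replicate %s excluded: zero housekeeping count",
                      reps[j]), call. = FALSE)
      next
    }
    num <- ps / geomean(hk_ps)
    den <- cb / geomean(hk_cb)
    r <- ifelse(den == 0, NA_real_, num / den)
    if (any(den == 0))
      warning(sprintf(
        "replicate %s: %d gene(s) with zero %s count flagged as NA",
        reps[j], sum(den == 0), labs[2]), call. = FALSE)
    ratio_mat[, j] <- r
  }
  out <- aggregate_ratios(ratio_mat)
  structure(out, replicate_ratios = ratio_mat)
}

#' Spike-normalized RIP enrichment over a reference gene
#'
#' Per replicate, each gene's eluate/input recovery is corrected by the
#' spike RNA, \eqn{E_g = (eluate_g / eluate_{spike}) / (input_g /
#' input_{spike})}, and the reported enrichment is
#' \eqn{E_{target} / E_{reference}} (e.g. the tagged transcript over GAPDH).
#' Replicates with zero spike or zero input counts are excluded with a
#' warning. Multiplying all eluate (or all input) counts of a replicate by a
#' constant leaves the result unchanged.
#'
#' @param fc a [fraction_counts()] with eluate/input samples and a spike id.
#' @param target target gene id.
#' @param reference reference gene id.
#' @return A one-row data frame (`gene`, `mean_ratio`, `sem`, `n`) with
#'   per-replicate values in attribute `replicate_ratios`.
#' @export
rip_enrichment <- function(fc, target, reference) {
  stopifnot(inherits(fc, "fraction_counts"))
  if (is.null(fc$spike)) stop("a spike gene id is required", call. = FALSE)
  missing <- setdiff(c(target, reference), rownames(fc$counts))
  if (length(missing))
    stop("gene(s) absent from the count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  reps <- sort(unique(fc$samples$replicate))
  vals <- rep(NA_real_, length(reps))
  for (j in seq_along(reps)) {
    elu <- sample_for(fc, "eluate", reps[j])
    inp <- sample_for(fc, "input", reps[j])
    if (elu[fc$spike] == 0 || inp[fc$spike] == 0 ||
        inp[target] == 0 || inp[reference] == 0 || elu[reference] == 0) {
      warning(sprintf("replicate %s excluded: zero spike or input count",
                      reps[j]), call. = FALSE)
      next
    }
    E <- function(g) (elu[g] / elu[fc$spike]) / (inp[g] / inp[fc$spike])
    vals[j] <- E(target) / E(reference)
  }
  mat <- matrix(vals, nrow = 1,
                dimnames = list(paste0(target, "/", reference), reps))
  structure(aggregate_ratios(mat), replicate_ratios = mat)
}
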