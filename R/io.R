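# File formats: FASTA sequence sets (Biostrings), BED interval export
# (0-based half-open), label-mask and intensity TIFFs, spot and count CSVs,
# JSON results.

#' Read a labeled UTR set from FASTA plus a group table
#'
#' @param fasta_path path to a FASTA file of 3'UTR sequences (RNA or DNA;
#'   U is mapped to T).
#' @param groups either a data frame with columns `id`, `group`, or a path
#'   to a two-column CSV; when `NULL` all records get group `"unlabeled"`.
#' @return A [utr_set()].
#' @export
read_utr_fasta <- function(fasta_path, groups = NULL) {
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (is.null(groups)) {
    grp <- rep("unlabeled", length(ids))
  } else {
    if (is.character(groups)) groups <- utils::read.csv(groups)
    stopifnot(all(c("id", "group") %in% names(groups)))
    m <- match(ids, groups$id)
    if (anyNA(m))
      stop("no group label for sequence(s): ",
           paste(ids[is.na(m)], collapse = ", "), call. = FALSE)
    grp <- groups$group[m]
  }
  utr_set(ids, seqs, grp)
}

#' Write a UTR set to FASTA
#'
#' @param records a [utr_set()].
#' @param path output path.
#' @export
write_utr_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Export motif hits or GA-rich regions as BED
#'
#' Internal 1-based inclusive intervals become 0-based half-open BED lines.
#' The score column carries the GA fraction x 1000 (rounded) for regions and
#' 0 for motif hits.
#'
#' @param features data frame with `utr_id`, `start`, `end` and optionally
#'   `ga_fraction`.
#' @param path output path.
#' @param name feature name to place in the BED name column.
#' @export
write_bed <- function(features, path, name = "feature") {
  score <- if ("ga_fraction" %in% names(features))
    round(features$ga_fraction * 1000) else rep(0L, nrow(features))
  bed <- data.frame(chrom = features$utr_id,
                    start = features$start - 1L,  # 0-based
                    end = features$end,           # half-open
                    name = name, score = score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a label-mask TIFF (0 background, 1 cell, 2 nucleus)
#'
#' Masks are stored as 16-bit single-channel label images.
#'
#' @param cell a [cell_geometry()].
#' @param path TIFF path.
#' @export
write_mask_tiff <- function(cell, path) {
  lab <- matrix(0L, nrow(cell$cell_mask), ncol(cell$cell_mask))
  lab[cell$cell_mask] <- 1L
  lab[cell$nucleus_mask] <- 2L
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  lab <- round(tiff::readTIFF(path) * 65535)
  cell_geometry(lab >= 1, lab == 2)
}

#' Write / read a single-channel intensity TIFF (32-bit float)
#'
#' @param image numeric matrix.
#' @param path TIFF path.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image, path, bits.per.sample = 32,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  tiff::readTIFF(path)
}

#' Write / read spot tables as CSV (`cell_id`, `x`, `y`[, `intensity`])
#'
#' @param spots a [spot_set()] or data frame.
#' @param path CSV path.
#' @param cell_id cell identifier written with every row.
#' @export
write_spots_csv <- function(spots, path, cell_id = "cell_1") {
  df <- cbind(cell_id = cell_id, as.data.frame(spots))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  utils::read.csv(path)
}

#' Write / read a fractionation count matrix as CSV
#'
#' Sample metadata (fraction, replicate) and normalizer ids travel in a
#' `#`-prefixed header block above the gene x sample matrix.
#'
#' @param fc a [fraction_counts()].
#' @param path CSV path.
#' @export
write_fraction_csv <- function(fc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#fraction=", paste(fc$samples$fraction, collapse = ",")),
    paste0("#replicate=", paste(fc$samples$replicate, collapse = ",")),
    paste0("#housekeeping=", paste(fc$housekeeping, collapse = ",")),
    paste0("#spike=", if (is.null(fc$spike)) "" else fc$spike)), con)
  utils::write.csv(as.data.frame(fc$counts), con)
  invisible(path)
}

#' @rdname write_fraction_csv
#' @export
read_fraction_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    v <- sub(paste0("^#", key, "="), "", grep(paste0("^#", key, "="),
                                              hdr, value = TRUE))
    if (!length(v) || v == "") character() else strsplit(v, ",")[[1]]
  }
  mat <- as.matrix(utils::read.csv(text = lines[!grepl("^#", lines)],
                                   row.names = 1, check.names = FALSE))
  samples <- data.frame(sample = colnames(mat), fraction = get("fraction"),
                        replicate = as.integer(get("replicate")),
                        stringsAsFactors = FALSE)
  spike <- get("spike")
  fraction_counts(mat, samples, housekeeping = get("housekeeping"),
                  spike = if (length(spike)) spike else NULL)
}

write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
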