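# Synthetic-data generators with recorded ground truth: labeled UTR sets
# with planted motifs/GA-rich regions, disk-based cell geometries, radially
# biased spot patterns, PLA images with planted dots, and fractionation
# count tables with known enrichment ratios.
#
# Default parameter values are the package's study conditions: a localized
# group in which ~60% of UTRs carry at least one planted RGAAGRR copy
# (Poisson rate 0.92) versus a low-rate control group, and disk cells of
# radius 100 px with a 30 px nucleus.

#' UTR simulation parameters
#'
#' @param n_per_group number of UTRs per group.
#' @param length_range min/max UTR length (nt, min >= 30).
#' @param background_weights named probabilities for A, C, G, T (sum to 1).
#' @param motif_rate_localized,motif_rate_control expected number of planted
#'   consensus copies per UTR (Poisson rate) in the localized / control
#'   group. The default localized rate 0.92 gives a ~60% chance of at least
#'   one copy.
#' @param region_plant optional `list(length =, ga_fraction =)` describing a
#'   GA-rich region planted in every localized UTR (length >= 30 nt,
#'   fraction > 0.75).
#' @param seed integer seed.
#' @export
utr_sim_params <- function(n_per_group = 20,
                           length_range = c(300, 1500),
                           background_weights = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                           motif_rate_localized = 0.92,
                           motif_rate_control = 0.1,
                           region_plant = NULL,
                           seed = 1L) {
  stop_if_not_scalar_number(n_per_group, "n_per_group", 1)
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2])
  if (length_range[1] < 30)
    stop("minimum UTR length must be >= 30", call. = FALSE)
  if (!setequal(names(background_weights), c("A", "C", "G", "T")))
    stop("background_weights must be named A, C, G, T", call. = FALSE)
  if (any(background_weights < 0) ||
      abs(sum(background_weights) - 1) > 1e-8)
    stop("background_weights must be non-negative and sum to 1",
         call. = FALSE)
  stop_if_not_scalar_number(motif_rate_localized, "motif_rate_localized", 0)
  stop_if_not_scalar_number(motif_rate_control, "motif_rate_control", 0)
  if (!is.null(region_plant)) {
    stopifnot(is.list(region_plant),
              all(c("length", "ga_fraction") %in% names(region_plant)))
    if (region_plant$length < 30)
      stop("planted region length must be >= 30 nt", call. = FALSE)
    if (region_plant$ga_fraction <= 0.75 || region_plant$ga_fraction > 1)
      stop("planted region GA fraction must be in (0.75, 1]", call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 length_range = as.integer(length_range),
                 background_weights = background_weights[c("A", "C", "G", "T")],
                 motif_rate_localized = motif_rate_localized,
                 motif_rate_control = motif_rate_control,
                 region_plant = region_plant,
                 seed = as.integer(seed)),
            class = "utr_sim_params")
}

instantiate_consensus <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else sample(set, 1)
  }, character(1)), collapse = "")
}

# choose `n` non-overlapping start positions for length-k features in 1..L,
# also avoiding positions overlapping `blocked` (logical of length L)
plant_positions <- function(n, k, L, blocked = logical(L)) {
  starts <- integer(0)
  occupied <- blocked
  for (i in seq_len(n)) {
    cand <- which(vapply(seq_len(L - k + 1), function(s)
      !any(occupied[s:(s + k - 1)]), logical(1)))
    if (!length(cand)) break  # no room left; planted fewer than requested
    s <- if (length(cand) == 1) cand else sample(cand, 1)
    occupied[s:(s + k - 1)] <- TRUE
    starts <- c(starts, s)
  }
  sort(starts)
}

#' Generate a labeled synthetic UTR set with planted features
#'
#' Background sequence is i.i.d. per base; planted motifs are concrete
#' instantiations of the consensus overwriting the background at uniformly
#' chosen non-overlapping positions; an optional GA-rich region (exact
#' composition, shuffled) is planted in each localized UTR. The truth table
#' lists planted features only — the random background can contain
#' additional chance matches.
#'
#' @param params a [utr_sim_params()].
#' @param spec a [motif_spec()]; planted motifs instantiate this consensus.
#' @return A list with `records` (a [utr_set()], groups `"localized"` and
#'   `"control"`) and `truth` (data frame `id`, `feature`, `start`, `end`).
#' @export
gen_utr_set <- function(params = utr_sim_params(), spec = motif_spec()) {
  stopifnot(inherits(params, "utr_sim_params"))
  with_seed(params$seed, {
    bases <- c("A", "C", "G", "T")
    n <- params$n_per_group
    ids <- c(sprintf("loc_%03d", seq_len(n)), sprintf("ctl_%03d", seq_len(n)))
    groups <- rep(c("localized", "control"), each = n)
    rates <- rep(c(params$motif_rate_localized, params$motif_rate_control),
                 each = n)
    seqs <- character(2 * n)
    truth <- list()
    for (i in seq_len(2 * n)) {
      L <- sample(params$length_range[1]:params$length_range[2], 1)
      s <- sample(bases, L, replace = TRUE, prob = params$background_weights)
      blocked <- logical(L)
      # plant region first (localized group only)
      if (!is.null(params$region_plant) && groups[i] == "localized") {
        rl <- params$region_plant$length
        if (rl > L)
          stop(sprintf("planted region longer than UTR '%s'", ids[i]),
               call. = FALSE)
        n_ga <- ceiling(rl * params$region_plant$ga_fraction)
        comp <- sample(c(sample(c("G", "A"), n_ga, replace = TRUE),
                         sample(c("C", "T"), rl - n_ga, replace = TRUE)))
        rs <- sample(L - rl + 1, 1)
        s[rs:(rs + rl - 1)] <- comp
        blocked[rs:(rs + rl - 1)] <- TRUE
        truth[[length(truth) + 1]] <-
          data.frame(id = ids[i], feature = "region", start = rs,
                     end = rs + rl - 1L)
      }
      n_mot <- stats::rpois(1, rates[i])
      if (n_mot > 0) {
        if (spec$length > L)
          stop(sprintf("motif longer than UTR '%s'", ids[i]), call. = FALSE)
        # motifs may land inside a planted region, but not on each other
        starts <- plant_positions(n_mot, spec$length, L)
        for (st in starts) {
          inst <- strsplit(instantiate_consensus(spec$consensus), "")[[1]]
          s[st:(st + spec$length - 1)] <- inst
          truth[[length(truth) + 1]] <-
            data.frame(id = ids[i], feature = "motif", start = st,
                       end = st + spec$length - 1L)
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    truth <- if (length(truth)) do.call(rbind, truth)
    else data.frame(id = character(), feature = character(),
                    start = integer(), end = integer())
    list(records = utr_set(ids, seqs, groups), truth = truth)
  })
}

#' Cell geometry simulation parameters
#'
#' @param image_size image side length (px).
#' @param cell_radius,nucleus_radius disk radii (px, > 0).
#' @param nucleus_offset (x, y) offset of the nucleus center from the cell
#'   center (px); the nucleus must remain inside the cell.
#' @param seed integer seed (kept for interface symmetry; the geometry is
#'   deterministic).
#' @export
cell_sim_params <- function(image_size = 256, cell_radius = 100,
                            nucleus_radius = 30, nucleus_offset = c(0, 0),
                            seed = 1L) {
  stop_if_not_scalar_number(cell_radius, "cell_radius", 0, strict = TRUE)
  stop_if_not_scalar_number(nucleus_radius, "nucleus_radius", 0, strict = TRUE)
  stopifnot(length(nucleus_offset) == 2)
  if (sqrt(sum(nucleus_offset^2)) + nucleus_radius > cell_radius)
    stop("nucleus is not fully inside the cell", call. = FALSE)
  if (2 * cell_radius + 2 > image_size)
    stop("cell does not fit in the image", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 nucleus_offset = as.numeric(nucleus_offset),
                 seed = as.integer(seed)),
            class = "cell_sim_params")
}

disk_mask <- function(size, center, radius) {
  r <- matrix(seq_len(size), size, size)
  c <- t(r)
  (c - center[1])^2 + (r - center[2])^2 <= radius^2
}

#' Generate a disk-cell geometry
#'
#' @param params a [cell_sim_params()].
#' @return A [cell_geometry()].
#' @export
gen_cell <- function(params = cell_sim_params()) {
  stopifnot(inherits(params, "cell_sim_params"))
  ctr <- rep((params$image_size + 1) / 2, 2)
  cell <- disk_mask(params$image_size, ctr, params$cell_radius)
  nuc <- disk_mask(params$image_size, ctr + params$nucleus_offset,
                   params$nucleus_radius)
  cell_geometry(cell, nuc)
}

#' Spot pattern simulation parameters
#'
#' Spots are sampled over the support with weight proportional to
#' `(d / d_max)^beta`, d the distance from the nucleus centroid: beta = 0 is
#' uniform (diffuse), beta > 0 peripheral, beta < 0 perinuclear.
#'
#' @param n_spots number of spots (>= 0).
#' @param bias_exponent the radial weight exponent beta (finite).
#' @param support `"whole_cell"` or `"cytoplasm_only"`.
#' @param seed integer seed.
#' @export
spot_sim_params <- function(n_spots = 500, bias_exponent = 0,
                            support = c("whole_cell", "cytoplasm_only"),
                            seed = 1L) {
  stop_if_not_scalar_number(n_spots, "n_spots", 0)
  stop_if_not_scalar_number(bias_exponent, "bias_exponent")
  structure(list(n_spots = as.integer(n_spots),
                 bias_exponent = bias_exponent,
                 support = match.arg(support), seed = as.integer(seed)),
            class = "spot_sim_params")
}

#' Generate a radially biased spot pattern in a cell
#'
#' Support pixels are drawn with probability proportional to
#' `(d / d_max)^beta` and spots jittered uniformly within their pixel. For
#' negative beta, distances are clamped below at half a pixel so the weight
#' at the centroid pixel stays finite.
#'
#' @param cell a [cell_geometry()].
#' @param params a [spot_sim_params()].
#' @return A [spot_set()].
#' @export
gen_spots <- function(cell, params = spot_sim_params()) {
  stopifnot(inherits(cell, "cell_geometry"),
            inherits(params, "spot_sim_params"))
  support <- if (params$support == "whole_cell") cell$cell_mask
  else cell$cell_mask & !cell$nucleus_mask
  if (!any(support)) stop("empty spot support", call. = FALSE)
  if (params$n_spots == 0)
    return(spot_set(numeric(0), numeric(0)))
  with_seed(params$seed, {
    idx <- which(support, arr.ind = TRUE)
    d <- sqrt((idx[, 2] - cell$nucleus_centroid["x"])^2 +
                (idx[, 1] - cell$nucleus_centroid["y"])^2)
    if (params$bias_exponent < 0) d <- pmax(d, 0.5)
    w <- (d / max(d))^params$bias_exponent
    pick <- sample.int(nrow(idx), params$n_spots, replace = TRUE, prob = w)
    x <- idx[pick, 2] + stats::runif(params$n_spots, -0.5, 0.5)
    y <- idx[pick, 1] + stats::runif(params$n_spots, -0.5, 0.5)
    spot_set(x, y)
  })
}

#' PLA image simulation parameters
#'
#' @param background_mean,background_sd Gaussian background intensity
#'   parameters (sd > 0); pixel values are clipped at 0.
#' @param n_dots number of planted dots.
#' @param dot_amplitude dot intensity above the background mean (>= 0).
#' @param dot_radius dot disk radius (px).
#' @param dot_region_split fraction of dots placed in the peripheral band
#'   (in [0, 1]).
#' @param seed integer seed.
#' @export
pla_sim_params <- function(background_mean = 100, background_sd = 10,
                           n_dots = 20, dot_amplitude = 100, dot_radius = 2,
                           dot_region_split = 0.5, seed = 1L) {
  stop_if_not_scalar_number(background_sd, "background_sd", 0, strict = TRUE)
  stop_if_not_scalar_number(dot_amplitude, "dot_amplitude", 0)
  stop_if_not_scalar_number(n_dots, "n_dots", 0)
  if (dot_region_split < 0 || dot_region_split > 1)
    stop("dot_region_split must lie in [0, 1]", call. = FALSE)
  structure(list(background_mean = background_mean,
                 background_sd = background_sd, n_dots = as.integer(n_dots),
                 dot_amplitude = dot_amplitude, dot_radius = dot_radius,
                 dot_region_split = dot_region_split,
                 seed = as.integer(seed)),
            class = "pla_sim_params")
}

#' Generate a synthetic PLA image with planted dots
#'
#' Background pixels are Normal(mean, sd) clipped at 0; each dot is a hard
#' disk of radius `dot_radius` whose pixels are set to
#' `background_mean + dot_amplitude`. Dot centers are sampled on pixels of
#' the peripheral band (a `dot_region_split` fraction) or the remaining cell
#' body, with a minimum center separation of `2 * dot_radius + 2` px so
#' planted dots remain individually resolvable; the truth table records each
#' center and its compartment.
#'
#' @param cell a [cell_geometry()].
#' @param params a [pla_sim_params()].
#' @param spec a [compartment_spec()] defining the peripheral band used for
#'   placement.
#' @return A list with `image` (matrix) and `truth` (data frame `x`, `y`,
#'   `compartment`).
#' @export
gen_pla_image <- function(cell, params = pla_sim_params(),
                          spec = compartment_spec()) {
  stopifnot(inherits(cell, "cell_geometry"),
            inherits(params, "pla_sim_params"))
  bands <- compartment_bands(cell, spec)
  body <- cell$cell_mask & !bands$peripheral
  with_seed(params$seed, {
    dm <- dim(cell$cell_mask)
    img <- matrix(pmax(0, stats::rnorm(prod(dm), params$background_mean,
                                       params$background_sd)),
                  nrow = dm[1])
    n_peri <- round(params$dot_region_split * params$n_dots)
    n_body <- params$n_dots - n_peri
    placed_x <- numeric(0); placed_y <- numeric(0)
    min_sep <- 2 * params$dot_radius + 2  # keep planted dots resolvable
    place <- function(mask, n, compartment) {
      if (n == 0)
        return(data.frame(x = numeric(), y = numeric(),
                          compartment = character()))
      px <- which(mask)
      if (!length(px))
        stop(sprintf("cannot place a dot: empty %s compartment",
                     compartment), call. = FALSE)
      xs <- numeric(n); ys <- numeric(n)
      for (i in seq_len(n)) {
        for (try in seq_len(1000)) {
          pick <- px[sample.int(length(px), 1)]
          x <- (pick - 1) %/% dm[1] + 1; y <- (pick - 1) %% dm[1] + 1
          if (!length(placed_x) ||
              all((placed_x - x)^2 + (placed_y - y)^2 >= min_sep^2)) break
          if (try == 1000)
            stop("cannot place all dots without overlap; reduce n_dots",
                 call. = FALSE)
        }
        placed_x <<- c(placed_x, x); placed_y <<- c(placed_y, y)
        xs[i] <- x; ys[i] <- y
      }
      data.frame(x = xs, y = ys, compartment = compartment)
    }
    truth <- rbind(place(bands$peripheral, n_peri, "peripheral"),
                   place(body, n_body, "body"))
    if (nrow(truth)) {
      if (!all(points_in_mask(truth$x, truth$y, cell$cell_mask)))
        stop("dot placed outside the cell mask", call. = FALSE)
      for (i in seq_len(nrow(truth))) {
        dot <- disk_mask_around(dm, c(truth$x[i], truth$y[i]),
                                params$dot_radius)
        img[dot] <- params$background_mean + params$dot_amplitude
      }
    }
    list(image = img, truth = truth)
  })
}

disk_mask_around <- function(dm, center, radius) {
  rr <- max(1, floor(center[2] - radius)):min(dm[1], ceiling(center[2] + radius))
  cc <- max(1, floor(center[1] - radius)):min(dm[2], ceiling(center[1] + radius))
  sub <- outer((rr - center[2])^2, (cc - center[1])^2, "+") <= radius^2
  idx <- which(sub, arr.ind = TRUE)
  cbind(rr[idx[, 1]], cc[idx[, 2]])
}

#' Fractionation count simulation parameters
#'
#' @param true_ratio_per_gene named vector of true enrichment ratios
#'   (protrusion/cell-body or eluate/input), all > 0.
#' @param n_replicates number of paired replicates.
#' @param baseline expected baseline count per gene in the reference
#'   fraction (scalar or named per gene).
#' @param library_size_factors per-sample scale factors (> 0), length
#'   `2 * n_replicates`, ordered as the generated samples; default all 1.
#' @param noise if `TRUE`, counts are Poisson draws around their expected
#'   values; if `FALSE`, expected values are returned exactly.
#' @param mode `"ps_cb"` (fractions Ps/CB) or `"rip"` (eluate/input).
#' @param seed integer seed.
#' @export
fraction_sim_params <- function(true_ratio_per_gene, n_replicates = 3,
                                baseline = 1000,
                                library_size_factors = NULL,
                                noise = TRUE, mode = c("ps_cb", "rip"),
                                seed = 1L) {
  stopifnot(is.numeric(true_ratio_per_gene),
            !is.null(names(true_ratio_per_gene)))
  if (any(true_ratio_per_gene <= 0))
    stop("true ratios must be > 0", call. = FALSE)
  stop_if_not_scalar_number(n_replicates, "n_replicates", 1)
  if (is.null(library_size_factors))
    library_size_factors <- rep(1, 2 * n_replicates)
  if (length(library_size_factors) != 2 * n_replicates)
    stop("library_size_factors must have length 2 * n_replicates",
         call. = FALSE)
  if (any(library_size_factors <= 0))
    stop("library size factors must be > 0", call. = FALSE)
  if (any(baseline <= 0)) stop("baseline must be > 0", call. = FALSE)
  structure(list(true_ratio_per_gene = true_ratio_per_gene,
                 n_replicates = as.integer(n_replicates),
                 baseline = baseline,
                 library_size_factors = library_size_factors,
                 noise = isTRUE(noise), mode = match.arg(mode),
                 seed = as.integer(seed)),
            class = "fraction_sim_params")
}

#' Generate a fractionation count matrix with known enrichment ratios
#'
#' Expected count is `baseline * size_factor * ratio` in the enriched
#' fraction (Ps or eluate) and `baseline * size_factor` in the reference
#' fraction (CB or input); Poisson noise is applied when `noise = TRUE`.
#' Two housekeeping genes (`HK1`, `HK2`) and a spike row (`SPIKE`), all at
#' ratio 1, are appended as normalizers.
#'
#' @param params a [fraction_sim_params()].
#' @return A list with `counts` (a [fraction_counts()]) and `truth` (named
#'   ratio vector for the non-normalizer genes).
#' @export
gen_fraction_counts <- function(params) {
  stopifnot(inherits(params, "fraction_sim_params"))
  ratios <- c(params$true_ratio_per_gene, HK1 = 1, HK2 = 1, SPIKE = 1)
  genes <- names(ratios)
  base <- if (length(params$baseline) == 1)
    stats::setNames(rep(params$baseline, length(genes)), genes)
  else c(params$baseline, HK1 = 1000, HK2 = 1000, SPIKE = 1000)
  fr_labels <- if (params$mode == "ps_cb") c("Ps", "CB")
  else c("eluate", "input")
  n_rep <- params$n_replicates
  samples <- data.frame(
    sample = paste0(rep(fr_labels, n_rep), "_", rep(seq_len(n_rep), each = 2)),
    fraction = rep(fr_labels, n_rep),
    replicate = rep(seq_len(n_rep), each = 2),
    stringsAsFactors = FALSE)
  expected <- outer(seq_along(genes), seq_len(nrow(samples)),
                    Vectorize(function(g, s) {
                      enr <- samples$fraction[s] == fr_labels[1]
                      base[g] * params$library_size_factors[s] *
                        (if (enr) ratios[g] else 1)
                    }))
  dimnames(expected) <- list(genes, samples$sample)
  counts <- if (params$noise)
    with_seed(params$seed,
              matrix(stats::rpois(length(expected), expected),
                     nrow = nrow(expected), dimnames = dimnames(expected)))
  else expected
  list(counts = fraction_counts(counts, samples,
                                housekeeping = c("HK1", "HK2"),
                                spike = "SPIKE"),
       truth = params$true_ratio_per_gene)
}
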