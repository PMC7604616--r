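# Independent brute-force oracles. These deliberately share no code with the
# package internals: the IUPAC table is restated, windows are counted by
# substring, regions are derived from per-position coverage, and the Fisher
# p-value is a direct hypergeometric enumeration.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_scan <- function(seq, consensus = "RGAAGRR") {
  k <- nchar(consensus)
  n <- nchar(seq)
  cons <- strsplit(consensus, "")[[1]]
  starts <- integer(0)
  if (n >= k) for (s in 1:(n - k + 1)) {
    win <- strsplit(substr(seq, s, s + k - 1), "")[[1]]
    if (all(mapply(function(ch, cc) ch %in% oracle_iupac[[cc]], win, cons)))
      starts <- c(starts, s)
  }
  starts
}

oracle_ga_windows <- function(seq, W = 30) {
  n <- nchar(seq)
  vapply(1:(n - W + 1), function(s) {
    win <- strsplit(substr(seq, s, s + W - 1), "")[[1]]
    sum(win %in% c("G", "A")) / W
  }, numeric(1))
}

oracle_regions <- function(seq, W = 30, theta = 0.75, min_len = 30) {
  n <- nchar(seq)
  if (n < W) return(data.frame(start = integer(), end = integer()))
  frac <- oracle_ga_windows(seq, W)
  covered <- logical(n)
  for (s in which(frac > theta)) covered[s:(s + W - 1)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# two-sided Fisher exact p for table rbind(c(a, b), c(c, d)) by summing all
# hypergeometric probabilities not exceeding the observed one
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_acgt <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# shared fixture: concentric disk cell matching the diffuse-PDI setup
disk_cell <- function(cell_radius = 100, nucleus_radius = 30,
                      image_size = 2 * cell_radius + 56) {
  gen_cell(cell_sim_params(image_size = image_size,
                           cell_radius = cell_radius,
                           nucleus_radius = nucleus_radius))
}
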