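# Independent oracles and tiny fixture builders used across the suite.

# Brute-force connected components (8-neighbourhood), implemented as an
# iterative region-growing sweep independent of label_patches().
oracle_patch_count <- function(codes, mask) {
  nr <- nrow(codes); nc <- ncol(codes)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    # grow the region by repeated full-grid sweeps (slow but obviously right)
    region <- matrix(FALSE, nr, nc)
    region[r0, c0] <- TRUE
    repeat {
      grown <- region
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        if (grown[r, c] || !mask[r, c] ||
            codes[r, c] != codes[r0, c0]) next
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              region[rr, cc]) grown[r, c] <- TRUE
        }
      }
      if (identical(grown, region)) break
      region <- grown
    }
    seen <- seen | region
  }
  count
}

# Exhaustive Jenks: minimal within-class SSE over all ordered partitions
# of the sorted values into k non-empty contiguous blocks.
oracle_jenks_sse <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  # choose k-1 cut positions among n-1 gaps
  cuts <- utils::combn(n - 1, k - 1)
  if (k == 1) return(sse(x))
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(m)
      sse(x[(b[m] + 1):b[m + 1]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

jenks_sse_of <- function(values, classes) {
  sum(vapply(split(values, classes), function(v)
    sum((v - mean(v))^2), numeric(1)))
}

# flat RGB image builder
flat_image <- function(col, h = 10, w = 10) {
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- col[ch]
  arr
}

# grid with exact class cell counts, scattered at random
grid_with_counts <- function(counts, codes = seq_along(counts),
                             cell_size_m = 10, seed = 1) {
  n <- sum(counts)
  side <- ceiling(sqrt(n))
  vals <- rep(codes, counts)
  set.seed(seed)
  vals <- sample(vals)
  length(vals) <- side^2
  m <- matrix(vals, side, side)
  land_cover_grid(m, cell_size_m, mask = !is.na(m))
}
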