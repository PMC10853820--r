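# Small, fast scene configuration for tests that only need geometry.
tiny_config <- function(...) {
  args <- list(image_shape = c(128L, 128L), cell_radius = 5,
               centrosome_separation = 4, n_rna_free = 15)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_config, args)
}

# Brute-force sum of pixels whose centres lie within radius of a point;
# independent of the disk-mask implementation (explicit double loop).
brute_force_disk <- function(image, center_um, radius_um, pixel_size) {
  total <- 0; npx <- 0L
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      dy <- (i - 1) - center_um[1] / pixel_size
      dx <- (j - 1) - center_um[2] / pixel_size
      if (dy * dy + dx * dx <= (radius_um / pixel_size)^2 + 1e-9) {
        total <- total + image[i, j]
        npx <- npx + 1L
      }
    }
  }
  list(total = total, n_pixels = npx)
}

# Brute-force signed-argmax with the stated tie rules: maximum value,
# then smallest |position|, then the negative (spindle) side.
brute_force_peak <- function(positions, values) {
  best <- NULL
  for (i in seq_along(values)) {
    if (is.null(best)) { best <- i; next }
    if (values[i] > values[best]) { best <- i; next }
    if (values[i] == values[best]) {
      if (abs(positions[i]) < abs(positions[best])) { best <- i; next }
      if (abs(positions[i]) == abs(positions[best]) &&
          positions[i] < positions[best]) best <- i
    }
  }
  positions[best]
}

# F1 of detections vs ground truth under a match radius, using a maximum
# bipartite matching (igraph) so no greedy pairing artefacts enter.
match_f1 <- function(det, truth, radius_um) {
  nd <- nrow(det); nt <- nrow(truth)
  if (nd == 0 || nt == 0) return(0)
  d <- sqrt(outer(det$y_um, truth$y_um, "-")^2 +
              outer(det$x_um, truth$x_um, "-")^2)
  pairs <- which(d <= radius_um, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0)
  g <- igraph::make_empty_graph(n = nd + nt, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(cbind(pairs[, 1],
                                              nd + pairs[, 2]))))
  igraph::V(g)$type <- c(rep(FALSE, nd), rep(TRUE, nt))
  tp <- igraph::max_bipartite_match(g)$matching_size
  prec <- tp / nd; rec <- tp / nt
  2 * prec * rec / (prec + rec)
}

# Brute-force probe-candidate enumeration: every (start, length) window
# scored by directly counting G/C characters in the substring.
brute_force_candidates <- function(tx, len_range = c(26L, 32L),
                                   gc_range = c(0.40, 0.60)) {
  tx <- toupper(tx)
  chars <- strsplit(tx, "")[[1]]
  n <- length(chars)
  rows <- list()
  for (start in 0:max(0, n - len_range[1])) {
    for (L in len_range[1]:len_range[2]) {
      if (start + L > n) next
      w <- chars[(start + 1):(start + L)]
      gc <- sum(w == "G" | w == "C") / L
      if (gc >= gc_range[1] && gc <= gc_range[2])
        rows[[length(rows) + 1L]] <- data.frame(
          start = start, length = L,
          sequence = paste(w, collapse = ""), gc = gc)
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(), length = integer(),
                      sequence = character(), gc = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$length), ]
}

# Welch t statistic and p computed from first principles.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

random_transcript <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}
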