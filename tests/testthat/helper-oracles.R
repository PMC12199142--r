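# Independent oracles used across the suite. Each reimplements its target
# quantity by the most direct route available (brute force, closed form, or
# an external reference evaluator) without sharing code with the package.

# Brute-force AUROC: count concordant pairs, ties half.
brute_auroc <- function(pos_scores, neg_scores) {
  total <- 0
  for (p in pos_scores) {
    for (n in neg_scores) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos_scores) * length(neg_scores))
}

# Brute-force per-position structure codes: classify each unpaired position
# by directly inspecting its innermost enclosing pair and that pair's
# children helices.
brute_codes <- function(pair_table) {
  n <- length(pair_table)
  opens <- which(pair_table > seq_len(n))
  enclosing <- function(pos) {
    cand <- opens[opens < pos & pair_table[opens] > pos]
    if (length(cand) == 0) return(NULL)
    widths <- pair_table[cand] - cand
    c(cand[which.min(widths)], pair_table[cand[which.min(widths)]])
  }
  children <- function(i, j) {
    # outermost pairs strictly inside (i, j)
    inner <- opens[opens > i & opens < j]
    kids <- list()
    k <- i + 1L
    while (k < j) {
      if (pair_table[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, pair_table[k])
        k <- pair_table[k] + 1L
      } else k <- k + 1L
    }
    kids
  }
  codes <- character(n)
  first_p <- if (any(pair_table > 0)) min(which(pair_table > 0)) else NA
  last_p <- if (any(pair_table > 0)) max(which(pair_table > 0)) else NA
  for (pos in seq_len(n)) {
    if (pair_table[pos] > 0) { codes[pos] <- "S"; next }
    enc <- enclosing(pos)
    if (is.null(enc)) {
      codes[pos] <- if (is.na(first_p) || pos < first_p || pos > last_p) "E"
                    else "X"
      next
    }
    kids <- children(enc[1], enc[2])
    if (length(kids) == 0) { codes[pos] <- "H"; next }
    if (length(kids) == 1) {
      g5 <- kids[[1]][1] - enc[1] - 1L
      g3 <- enc[2] - kids[[1]][2] - 1L
      codes[pos] <- if (g5 > 0 && g3 > 0) "I" else "B"
      next
    }
    codes[pos] <- "M"
  }
  codes
}

# Reference nearest-neighbor evaluator on the same Turner 2004 tables
# (d0: no dangling ends, matching the package's scored terms).
rnaeval_total <- function(sequences, dotbrackets) {
  inp <- as.vector(rbind(sequences, dotbrackets))
  out <- suppressWarnings(system2("RNAeval", "-d0", input = inp,
                                  stdout = TRUE, stderr = FALSE))
  vals <- out[grepl("\\(", out) & grepl("\\)$", out)]
  as.numeric(sub(".*\\( *(-?[0-9.]+)\\)$", "\\1", vals))
}

# Profile whose A-only sequence has the positives unpaired and the
# negatives paired among themselves (m must be even).
make_profile_from_scores <- function(pos_scores, neg_scores) {
  k <- length(pos_scores); m <- length(neg_scores)
  stopifnot(m %% 2 == 0)
  pt <- integer(k + m)
  for (i in seq_len(m %/% 2)) {
    a <- k + i; b <- k + m + 1L - i
    pt[a] <- b; pt[b] <- a
  }
  reactivity_profile("t", paste(rep("A", k + m), collapse = ""), pt,
                     c(pos_scores, neg_scores))
}
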