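# Independent oracles: deliberately naive implementations used to verify
# the package's algorithms on small random inputs.  They share no code
# with the implementations they check.

# Maximal runs of TRUE of length >= min_len, by explicit scanning.
oracle_idrs <- function(flags, min_len) {
  n <- length(flags)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (flags[i] && (i == 1L || !flags[i - 1L])) {
      j <- i
      while (j < n && flags[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        starts <- c(starts, i); ends <- c(ends, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends, length = ends - starts + 1L)
}

# Set-algebra Jaccard on disordered column index sets.
oracle_jaccard <- function(a, b) {
  A <- which(a == "disordered")
  B <- which(b == "disordered")
  u <- union(A, B)
  if (length(u) == 0L) return(1)
  length(intersect(A, B)) / length(u)
}

# Exhaustive O(n^2) maximal-scoring segment: every (i, j) sum, ties by
# smallest start then smallest length.
oracle_max_segment <- function(values) {
  n <- length(values)
  S <- c(0, cumsum(values))
  best <- -Inf; bs <- NA_integer_; be <- NA_integer_
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- S[j + 1L] - S[i]
      if (s > best ||
          (s == best && (i < bs || (i == bs && (j - i) < (be - bs))))) {
        best <- s; bs <- i; be <- j
      }
    }
  }
  list(score = best, start = bs, end = be)
}

# Exhaustive maximal segment by scoring every (start, end) substring at
# once from the prefix-sum table (no incremental scan; same tie rules).
oracle_max_segment_enum <- function(values) {
  n <- length(values)
  S <- c(0, cumsum(values))
  sums <- outer(S[-1L], S[-(n + 1L)], `-`)   # sums[j, i] = sum(i..j)
  valid <- row(sums) >= col(sums)
  best <- max(sums[valid])
  hit <- which(sums == best & valid, arr.ind = TRUE)
  pick <- hit[order(hit[, 2L], hit[, 1L]), , drop = FALSE][1L, ]
  list(score = best, start = unname(pick[2L]), end = unname(pick[1L]))
}

# Exhaustive CBR detector: per type, score every position against the
# homopolymer, repeatedly accept the oracle maximal segment when it
# meets the threshold, mask in-segment occurrences of the type, repeat.
oracle_detect_cbrs <- function(seq, threshold = 40, types = NULL,
                               matrix = disevo_blosum62()) {
  if (is.null(types)) {
    types <- c("A","R","N","D","C","Q","E","G","H","I",
               "L","K","M","F","P","S","T","W","Y","V")
  }
  chars0 <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (tp in types) {
    chars <- chars0
    repeat {
      ps <- as.numeric(matrix[chars, tp])
      seg <- oracle_max_segment_enum(ps)
      if (seg$score < threshold) break
      rows[[length(rows) + 1L]] <- data.frame(
        bias_type = tp, start = seg$start, end = seg$end,
        score = as.integer(seg$score), stringsAsFactors = FALSE)
      occ <- seg$start:seg$end
      occ <- occ[chars[occ] == tp]
      if (length(occ) == 0L) break
      chars[occ] <- "X"
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(bias_type = character(0), start = integer(0),
               end = integer(0), score = integer(0))
  }
  out <- out[order(out$start, out$bias_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal edge count by explicit pair enumeration.
oracle_internal_edges <- function(network, node_set) {
  key <- paste(pmin(network$edges$a, network$edges$b),
               pmax(network$edges$a, network$edges$b))
  if (length(node_set) < 2L) return(0L)
  pairs <- t(combn(sort(node_set), 2L))
  sum(paste(pairs[, 1L], pairs[, 2L]) %in% key)
}

random_aa_string <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}

# Label-permutation-invariant clustering agreement: fraction of rows in
# the majority true class of their predicted cluster.
cluster_agreement <- function(truth, predicted) {
  tab <- table(predicted, truth)
  sum(apply(tab, 1L, max)) / length(truth)
}
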