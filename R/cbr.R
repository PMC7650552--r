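## Compositionally biased region (CBR) detection.
##
## A CBR is detected by scoring every residue of a protein against a
## homopolymer of one amino-acid type under BLOSUM62 (no gaps) and taking
## maximal-scoring segments.  Per type, segments scoring >= threshold
## (default 40) are accepted iteratively: after accepting a segment, the
## occurrences of the bias type inside it are masked to a neutral token
## and the search repeats until the best segment falls below threshold.
## Types are treated independently, so CBRs of different types may
## overlap.

.blosum_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix used for CBR detection
#'
#' The standard integer BLOSUM62 matrix restricted to the 20 amino-acid
#' letters plus `X`, with the `X` row and column set to 0 so that unknown
#' residues (and masked positions) are neutral: they never contribute
#' positive or negative score against any bias type.
#'
#' @return A 21 x 21 integer matrix.
#' @export
disevo_blosum62 <- function() {
  if (is.null(.blosum_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[.AA_ALPHABET, .AA_ALPHABET]
    m["X", ] <- 0L
    m[, "X"] <- 0L
    storage.mode(m) <- "integer"
    .blosum_env$mat <- m
  }
  .blosum_env$mat
}

#' Score residues against a homopolymer of one amino-acid type
#'
#' `position_scores(seq, t)[i]` is the substitution score of residue *i*
#' aligned (without gaps) to the bias type `t`.
#'
#' @param seq Residue string, or a character vector of single residues.
#' @param bias_type One of the 20 standard amino-acid letters.
#' @param matrix Substitution matrix, default [disevo_blosum62()].
#' @return An integer vector of per-position scores.
#' @export
#' @examples
#' position_scores("QQQ", "Q")  # 5 5 5
position_scores <- function(seq, bias_type, matrix = disevo_blosum62()) {
  if (!bias_type %in% .AA20) {
    stop("bias_type must be one of the 20 standard amino-acid letters",
         call. = FALSE)
  }
  chars <- if (length(seq) == 1L) strsplit(seq, "", fixed = TRUE)[[1L]] else seq
  if (length(chars) == 0L) return(integer(0))
  bad <- which(!chars %in% rownames(matrix))
  if (length(bad) > 0L) {
    stop("residue '", chars[bad[1L]], "' at position ", bad[1L],
         " not in substitution matrix", call. = FALSE)
  }
  unname(matrix[chars, bias_type])
}

#' Maximal-scoring contiguous segment
#'
#' Finds the contiguous interval maximising the sum of `values`.  Ties are
#' broken by leftmost start, then shortest length.  If all values are
#' negative the best segment is the (leftmost) maximum single value.
#'
#' @param values Numeric or integer vector, non-empty.
#' @return A list with elements `score`, `start`, `end` (1-based closed).
#' @export
#' @examples
#' max_scoring_segment(c(5, -3, 5, 5))  # score 12 over [1, 4]
max_scoring_segment <- function(values) {
  n <- length(values)
  if (n == 0L) stop("empty vector", call. = FALSE)
  S <- cumsum(as.numeric(values))
  pre <- c(0, S[-n])                      # prefix sums S_0 .. S_{n-1}
  M <- cummin(pre)                        # running minimum prefix
  ## first index (1-based, = segment start) attaining the running minimum;
  ## strict improvement keeps the earliest argmin on prefix ties
  new_min <- c(TRUE, pre[-1L] < M[-n])
  fm <- cummax(ifelse(new_min, seq_len(n), 0L))
  sums <- S - M
  best <- max(sums)
  cand <- which(sums == best)
  j <- cand[order(fm[cand], cand)][1L]
  score <- best
  if (is.integer(values)) score <- as.integer(round(score))
  list(score = score, start = as.integer(fm[j]), end = as.integer(j))
}

#' Detect compositionally biased regions in one protein
#'
#' For each bias type independently: score positions against the type's
#' homopolymer, take the maximal-scoring segment, and accept it as a CBR
#' when its score meets the threshold; then mask the occurrences of the
#' bias type inside the accepted segment to the neutral token `X`
#' (scoring 0 against everything) and repeat until the best segment falls
#' below the threshold.  If an accepted segment contains no residue of
#' the bias type (its score coming entirely from similar residues), the
#' iteration for that type stops after recording it, since masking could
#' not reduce the attainable score.  CBRs of different types may overlap;
#' same-type CBRs from successive iterations are reported as found.
#'
#' @param seq Residue string.
#' @param protein_id Optional protein identifier stored in the result.
#' @param threshold Minimum segment score, default 40 (compared with `>=`).
#' @param types Bias types to scan; default all 20 standard letters.
#' @param matrix Substitution matrix, default [disevo_blosum62()].
#' @return A data frame with columns `protein_id`, `bias_type`, `start`,
#'   `end`, `score`, sorted by (`start`, `bias_type`).
#' @export
#' @examples
#' detect_cbrs(paste0(strrep("P", 4), strrep("Q", 8), strrep("P", 4)))
detect_cbrs <- function(seq, protein_id = NA_character_, threshold = 40L,
                        types = NULL, matrix = disevo_blosum62()) {
  if (is.null(types)) types <- .AA20
  chars0 <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars0) == 0L) stop("empty sequence", call. = FALSE)
  res <- list()
  for (tp in types) {
    chars <- chars0
    repeat {
      ps <- position_scores(chars, tp, matrix)
      seg <- max_scoring_segment(ps)
      if (seg$score < threshold) break
      res[[length(res) + 1L]] <- data.frame(
        protein_id = protein_id, bias_type = tp,
        start = seg$start, end = seg$end, score = as.integer(seg$score),
        stringsAsFactors = FALSE)
      occ <- seg$start:seg$end
      occ <- occ[chars[occ] == tp]
      if (length(occ) == 0L) break   # termination guard, see description
      chars[occ] <- "X"
    }
  }
  out <- if (length(res) > 0L) do.call(rbind, res) else {
    data.frame(protein_id = character(0), bias_type = character(0),
               start = integer(0), end = integer(0), score = integer(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$bias_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect CBRs across many proteins
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams detect_cbrs
#' @return A data frame as from [detect_cbrs()], rows for all proteins.
#' @export
detect_cbrs_proteome <- function(seqs, threshold = 40L, types = NULL,
                                 matrix = disevo_blosum62()) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  out <- do.call(rbind, lapply(names(seqs), function(id)
    detect_cbrs(seqs[[id]], protein_id = id, threshold = threshold,
                types = types, matrix = matrix)))
  rownames(out) <- NULL
  out
}

#' Bias types present in a protein's CBR set
#'
#' Presence is position- and count-insensitive: a type is present when at
#' least one CBR of that type was detected.
#'
#' @param cbrs Data frame of CBRs for one protein (from [detect_cbrs()]).
#' @return Sorted character vector of distinct bias-type letters.
#' @export
cbr_type_presence <- function(cbrs) {
  sort(unique(cbrs$bias_type))
}
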