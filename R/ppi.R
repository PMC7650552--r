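## Monte-Carlo enrichment of protein-protein interactions within node
## sets.  The observed count of network edges internal to a set is
## compared with the counts obtained for equally sized sets drawn
## uniformly without replacement from a background node list; the null
## mean and standard deviation standardise the observation into a
## z-score, with a one-sided upper-tail normal p-value and an empirical
## p-value computed alongside.

#' Count network edges internal to a node set
#'
#' @param network A [ppi_network()] object.
#' @param node_set Character vector of node ids (non-empty).  Members
#'   absent from the network simply contribute no edges.
#' @return Integer count of edges with both endpoints in `node_set`.
#' @export
count_internal_edges <- function(network, node_set) {
  stopifnot(inherits(network, "ppi_network"))
  if (length(node_set) == 0L) stop("empty node set", call. = FALSE)
  sum(network$edges$a %in% node_set & network$edges$b %in% node_set)
}

#' Simulate the null distribution of internal edge counts
#'
#' Draws `n_samples` sets of `set_size` nodes uniformly without
#' replacement from `background` and counts the network edges internal
#' to each.  Draws are independent of each other.  Reproducible given
#' `seed`.
#'
#' @param network A [ppi_network()] object.
#' @param background Character vector of background node ids to draw from.
#' @param set_size Size of each random set.
#' @param n_samples Number of random draws (>= 100), default 10000.
#' @param seed Optional integer seed.
#' @return A list with elements `mean`, `sd` (sample standard deviation,
#'   n-1 denominator), `samples` (integer vector) and `degenerate`
#'   (`TRUE` when `sd` is 0).
#' @export
simulate_null <- function(network, background, set_size, n_samples = 10000L,
                          seed = NULL) {
  stopifnot(inherits(network, "ppi_network"))
  background <- unique(as.character(background))
  if (set_size > length(background)) {
    stop("set_size exceeds background size", call. = FALSE)
  }
  if (n_samples < 100L) stop("n_samples must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nb <- length(background)
  ## integer-indexed edges restricted to the background
  ia <- match(network$edges$a, background)
  ib <- match(network$edges$b, background)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  samples <- integer(n_samples)
  member <- logical(nb)
  for (i in seq_len(n_samples)) {
    idx <- sample.int(nb, set_size)
    member[idx] <- TRUE
    samples[i] <- sum(member[ia] & member[ib])
    member[idx] <- FALSE
  }
  m <- mean(samples)
  s <- stats::sd(samples)
  list(mean = m, sd = s, samples = samples, degenerate = s == 0)
}

#' Enrichment statistics for an observed internal edge count
#'
#' Standardises the observed count against the null:
#' `z = (observed - mean) / sd`, `p_normal` is the one-sided upper-tail
#' standard-normal probability at the unrounded z, and `p_empirical` is
#' `(1 + #\{sample >= observed\}) / (1 + n_samples)` when null samples
#' are supplied.  A null with zero standard deviation yields a flagged
#' degenerate result with `NA` z-score.
#'
#' @param observed Observed internal edge count.
#' @param null_mean,null_sd Null mean and standard deviation (e.g. from
#'   [simulate_null()], or externally tabulated).
#' @param samples Optional integer vector of null samples for the
#'   empirical p-value.
#' @return A one-row data frame with columns `observed_ppi`, `null_mean`,
#'   `null_sd`, `z_score`, `p_normal`, `p_empirical`, `n_samples`,
#'   `degenerate`.
#' @export
#' @examples
#' enrichment_stats(68, 35.76, 10.90)  # z = 2.96, p ~ 0.0015
enrichment_stats <- function(observed, null_mean, null_sd, samples = NULL) {
  degenerate <- is.na(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else (observed - null_mean) / null_sd
  p_norm <- if (degenerate) NA_real_ else stats::pnorm(z, lower.tail = FALSE)
  p_emp <- if (is.null(samples)) NA_real_ else {
    (1 + sum(samples >= observed)) / (1 + length(samples))
  }
  data.frame(observed_ppi = observed, null_mean = null_mean,
             null_sd = null_sd, z_score = z, p_normal = p_norm,
             p_empirical = p_emp,
             n_samples = if (is.null(samples)) NA_integer_ else length(samples),
             degenerate = degenerate)
}

#' PPI enrichment of several node sets against one background
#'
#' Runs [simulate_null()] and [enrichment_stats()] for each set (e.g.
#' the reference-species members of each conservation cluster).  Set
#' members absent from the background are kept for set-size purposes but
#' cannot form edges.
#'
#' @param network A [ppi_network()] object.
#' @param sets Named list of character node-id vectors.
#' @param background Character vector of background node ids.
#' @param n_samples Random draws per set, default 10000.
#' @param seed Optional integer seed; per-set seeds are derived from it.
#' @return A data frame with one row per set, the columns of
#'   [enrichment_stats()] plus `cluster` and `seed`.
#' @export
ppi_enrichment <- function(network, sets, background, n_samples = 10000L,
                           seed = NULL) {
  stopifnot(is.list(sets), length(sets) > 0L, !is.null(names(sets)))
  rows <- lapply(seq_along(sets), function(i) {
    set_i <- unique(as.character(sets[[i]]))
    obs <- count_internal_edges(network, set_i)
    seed_i <- if (is.null(seed)) NULL else seed + i
    null <- simulate_null(network, background, set_size = length(set_i),
                          n_samples = n_samples, seed = seed_i)
    st <- enrichment_stats(obs, null$mean, null$sd, samples = null$samples)
    cbind(data.frame(cluster = names(sets)[i], stringsAsFactors = FALSE),
          st,
          data.frame(seed = if (is.null(seed_i)) NA_integer_ else seed_i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
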