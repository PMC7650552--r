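## Disorder annotation: per-residue score thresholding, IDR calling,
## IDP classification and proteome-level aggregation.
##
## Definitions used throughout:
##   IDR: a maximal run of >= min_len consecutive residues whose disorder
##        score meets the cutoff (default 0.5, compared with >=).
##   IDP: a protein with at least one IDR.
##   IDP fraction: IDPs / proteins in a proteome.
##   IDR fraction: disordered residues / residues in a proteome, where by
##        default "disordered residues" means residues inside called IDRs.

#' Threshold a disorder score track into a per-residue mask
#'
#' A residue is disordered when its score meets the cutoff.  The default
#' comparison is `score >= cutoff` (the convention of per-residue disorder
#' predictors whose 0.5 score is the decision boundary); set
#' `strict = TRUE` for `>`.
#'
#' @param scores Numeric vector of per-residue scores in \[0, 1\].
#' @param cutoff Disorder cutoff, default 0.5.
#' @param strict Use strict `>` instead of `>=`?
#' @return A logical vector, one flag per residue.
#' @export
#' @examples
#' call_disorder_mask(c(0.6, 0.4, 0.5))
call_disorder_mask <- function(scores, cutoff = 0.5, strict = FALSE) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) stop("empty score track", call. = FALSE)
  if (anyNA(scores) || any(scores < 0) || any(scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  if (strict) scores > cutoff else scores >= cutoff
}

#' Call IDRs from a per-residue disorder mask
#'
#' Returns the maximal runs of `TRUE` flags of length at least `min_len`
#' as sorted, disjoint 1-based closed intervals.
#'
#' @param flags Logical vector of per-residue disorder flags.
#' @param min_len Minimum IDR length in residues, default 30.
#' @return A data frame with integer columns `start`, `end` and `length`.
#' @export
#' @examples
#' call_idrs(rep(c(TRUE, FALSE), c(40, 10)), min_len = 30)
call_idrs <- function(flags, min_len = 30L) {
  stopifnot(is.logical(flags), min_len >= 1L)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]),
             length = as.integer(r$lengths[keep]))
}

#' Is a protein an IDP?
#'
#' A protein is an intrinsically disordered protein if it contains at
#' least one IDR.
#'
#' @param idrs IDR table from [call_idrs()].
#' @return `TRUE` iff at least one IDR was called.
#' @export
is_idp <- function(idrs) {
  nrow(idrs) > 0L
}

#' Build a disorder mask object for one protein
#'
#' Convenience wrapper combining [call_disorder_mask()] and [call_idrs()].
#'
#' @param scores Numeric score vector (e.g. one element of
#'   [read_score_track()] output).
#' @param protein_id Protein identifier.
#' @inheritParams call_disorder_mask
#' @inheritParams call_idrs
#' @return A list of class `disorder_mask` with elements `protein_id`,
#'   `flags`, `idrs` and `is_idp`.
#' @export
disorder_mask <- function(scores, protein_id, cutoff = 0.5, min_len = 30L,
                          strict = FALSE) {
  flags <- call_disorder_mask(scores, cutoff = cutoff, strict = strict)
  idrs <- call_idrs(flags, min_len = min_len)
  structure(list(protein_id = protein_id, flags = flags, idrs = idrs,
                 is_idp = is_idp(idrs)),
            class = "disorder_mask")
}

#' Annotate a whole proteome of score tracks
#'
#' @param tracks Named list of score vectors (see [read_score_track()]).
#' @inheritParams disorder_mask
#' @return A named list of [disorder_mask()] objects.
#' @export
annotate_proteome <- function(tracks, cutoff = 0.5, min_len = 30L,
                              strict = FALSE) {
  stopifnot(length(tracks) > 0L, !is.null(names(tracks)))
  out <- lapply(names(tracks), function(id)
    disorder_mask(tracks[[id]], id, cutoff = cutoff, min_len = min_len,
                  strict = strict))
  names(out) <- names(tracks)
  out
}

#' Collect called IDRs into a table
#'
#' @param masks Named list of [disorder_mask()] objects.
#' @return Data frame with columns `protein_id`, `start`, `end`, `length`
#'   (1-based inclusive coordinates).
#' @export
idr_table <- function(masks) {
  rows <- lapply(masks, function(m) {
    if (nrow(m$idrs) == 0L) return(NULL)
    cbind(data.frame(protein_id = m$protein_id, stringsAsFactors = FALSE),
          m$idrs)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Summarise disorder content of one proteome
#'
#' Computes the IDP fraction (proteins with at least one IDR / proteins)
#' and the IDR fraction (disordered residues / residues).  By default a
#' residue counts as disordered when it lies inside a called IDR
#' (`residue_counting = "idr"`), so that both measures are consistent with
#' the minimum-length rule; `residue_counting = "flag"` instead counts all
#' above-cutoff residues.  The counting mode used is recorded in the
#' returned row.
#'
#' @param masks Named list of [disorder_mask()] objects for one species.
#' @param species_id Species identifier.
#' @param residue_counting `"idr"` (default) or `"flag"`.
#' @return A one-row data frame with columns `species_id`, `n_proteins`,
#'   `n_idps`, `idp_fraction`, `n_residues`, `n_disordered_residues`,
#'   `idr_fraction`, `residue_counting`.
#' @export
summarize_proteome <- function(masks, species_id,
                               residue_counting = c("idr", "flag")) {
  residue_counting <- match.arg(residue_counting)
  if (length(masks) == 0L) stop("empty proteome", call. = FALSE)
  n_proteins <- length(masks)
  n_idps <- sum(vapply(masks, function(m) m$is_idp, logical(1L)))
  n_residues <- sum(vapply(masks, function(m) length(m$flags), integer(1L)))
  n_dis <- if (residue_counting == "idr") {
    sum(vapply(masks, function(m) sum(m$idrs$length), integer(1L)))
  } else {
    sum(vapply(masks, function(m) sum(m$flags), integer(1L)))
  }
  data.frame(species_id = species_id,
             n_proteins = n_proteins,
             n_idps = n_idps,
             idp_fraction = n_idps / n_proteins,
             n_residues = n_residues,
             n_disordered_residues = n_dis,
             idr_fraction = n_dis / n_residues,
             residue_counting = residue_counting,
             stringsAsFactors = FALSE)
}

#' Filter proteome summaries by proteome size
#'
#' Keeps species with at least `min_proteins` proteins (default 300),
#' removing very small proteomes that would bias cross-species
#' comparisons.  Reports how many species were removed.
#'
#' @param summaries Data frame of rows from [summarize_proteome()].
#' @param min_proteins Minimum proteome size, default 300.
#' @return The filtered data frame.
#' @export
filter_proteomes <- function(summaries, min_proteins = 300L) {
  if (nrow(summaries) == 0L) return(summaries)
  keep <- summaries$n_proteins >= min_proteins
  if (any(!keep)) {
    message("filter_proteomes: removed ", sum(!keep), " species with fewer than ",
            min_proteins, " proteins")
  }
  summaries[keep, , drop = FALSE]
}

#' Pearson correlation with two-sided p-value
#'
#' Thin validated wrapper around [stats::cor.test()] (product-moment
#' correlation; p-value from the t transform).
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return A list with elements `r`, `p` and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate proteome disorder content with number of cell types
#'
#' Joins proteome disorder summaries to a species metadata table and
#' computes the Pearson correlation of the IDP fraction and of the IDR
#' fraction with the annotated number of cell types, optionally within a
#' taxon subset (e.g. bony vertebrates).
#'
#' @param summaries Data frame of [summarize_proteome()] rows.
#' @param species_table Data frame from [read_species_table()].
#' @param taxa Optional character vector of `taxon_label` values to keep.
#' @return A list with elements `r_idp`, `p_idp`, `r_idr`, `p_idr`, `n`.
#' @export
correlate_disorder_with_celltypes <- function(summaries, species_table,
                                              taxa = NULL) {
  df <- merge(summaries, species_table, by = "species_id")
  if (!is.null(taxa)) df <- df[df$taxon_label %in% taxa, , drop = FALSE]
  df <- df[!is.na(df$n_cell_types), , drop = FALSE]
  if (nrow(df) < 3L) {
    stop("need at least 3 species with annotated cell-type numbers",
         call. = FALSE)
  }
  idp <- pearson_r(df$idp_fraction, df$n_cell_types)
  idr <- pearson_r(df$idr_fraction, df$n_cell_types)
  list(r_idp = idp$r, p_idp = idp$p, r_idr = idr$r, p_idr = idr$p,
       n = nrow(df))
}

#' Per-taxon quartile summaries of disorder content
#'
#' Box-plot statistics (quartiles and 1.5 x interquartile-range whiskers)
#' of a disorder measure per taxon, for tabular or graphical comparison
#' across taxonomic divisions.
#'
#' @param summaries Data frame of [summarize_proteome()] rows.
#' @param species_table Data frame mapping `species_id` to `taxon_label`.
#' @param measure `"idp_fraction"` (default) or `"idr_fraction"`.
#' @return A data frame with one row per taxon: `taxon_label`, `n`,
#'   `min`, `whisker_low`, `q1`, `median`, `q3`, `whisker_high`, `max`.
#' @export
taxon_quartiles <- function(summaries, species_table,
                            measure = c("idp_fraction", "idr_fraction")) {
  measure <- match.arg(measure)
  df <- merge(summaries, species_table, by = "species_id")
  groups <- split(df[[measure]], df$taxon_label)
  rows <- lapply(names(groups), function(tx) {
    x <- groups[[tx]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    data.frame(taxon_label = tx, n = length(x),
               min = min(x),
               whisker_low = min(x[x >= q[1L] - 1.5 * iqr]),
               q1 = q[1L], median = q[2L], q3 = q[3L],
               whisker_high = max(x[x <= q[3L] + 1.5 * iqr]),
               max = max(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
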