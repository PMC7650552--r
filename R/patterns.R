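## Binary cross-species conservation patterns of compositionally biased
## regions.  For an ortholog group and a bias type, the pattern is a bit
## string with one character per species in the configured order: '1'
## when that species' ortholog has at least one CBR of the type,
## irrespective of position and number of regions.  Patterns of all '0'
## (type absent everywhere) are excluded from reported counts by
## default.

#' Encode one presence vector as a conservation pattern
#'
#' @param present Named logical vector: does each species have at least
#'   one CBR of the type?  Must cover every configured species.
#' @param species Ordered character vector of species ids (bit order).
#' @return A pattern string over `{0,1}`, one character per species.
#' @export
#' @examples
#' encode_pattern(c(human = TRUE, mouse = TRUE, fish = FALSE,
#'                  fly = FALSE, yeast = FALSE),
#'                default_species()$species_id)  # "11000"
encode_pattern <- function(present, species) {
  missing_sp <- setdiff(species, names(present))
  if (length(missing_sp) > 0L) {
    stop("presence not defined for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  paste(ifelse(present[species], "1", "0"), collapse = "")
}

#' Encode conservation patterns for all groups and bias types
#'
#' Joins per-protein CBR calls to ortholog-group membership and encodes,
#' for every (group, bias type) with the type present in at least one
#' species (or all scanned types when `include_absent = TRUE`), the
#' binary cross-species pattern.  Only complete groups (all configured
#' species present) are encoded; incomplete groups are dropped with a
#' message.
#'
#' @param cbrs CBR data frame (`protein_id`, `bias_type`, ...), e.g. from
#'   [detect_cbrs_proteome()] or a generator truth table.
#' @param orthologs Ortholog membership data frame (`group_id`,
#'   `species_id`, `protein_id`).
#' @param species Ordered character vector of species ids (bit order).
#' @param include_absent Also emit all-zero patterns for scanned types?
#'   Requires `types`.
#' @param types Bias types scanned (needed only for `include_absent`).
#' @return A data frame with columns `group_id`, `bias_type`, `pattern`.
#' @export
encode_patterns <- function(cbrs, orthologs, species,
                            include_absent = FALSE, types = NULL) {
  by_group <- split(orthologs[c("species_id", "protein_id")],
                    orthologs$group_id)
  complete <- vapply(by_group, function(g) all(species %in% g$species_id),
                     logical(1L))
  if (any(!complete)) {
    message("encode_patterns: dropped ", sum(!complete),
            " incomplete group(s)")
  }
  by_group <- by_group[complete]
  ## presence lookup: protein -> distinct bias types
  pres <- unique(cbrs[c("protein_id", "bias_type")])
  pres_by_protein <- split(pres$bias_type, pres$protein_id)
  rows <- lapply(names(by_group), function(gid) {
    g <- by_group[[gid]]
    pid_of <- stats::setNames(g$protein_id, g$species_id)
    types_by_sp <- lapply(pid_of[species], function(p)
      pres_by_protein[[p]])
    names(types_by_sp) <- species
    tps <- if (include_absent) {
      if (is.null(types)) {
        stop("include_absent = TRUE requires 'types'", call. = FALSE)
      }
      types
    } else {
      sort(unique(unlist(types_by_sp)))
    }
    if (length(tps) == 0L) return(NULL)
    pats <- vapply(tps, function(tp) {
      present <- vapply(species, function(sp) tp %in% types_by_sp[[sp]],
                        logical(1L))
      encode_pattern(present, species)
    }, character(1L))
    data.frame(group_id = gid, bias_type = tps, pattern = unname(pats),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group_id = character(0), bias_type = character(0),
                      pattern = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "species_order") <- species
  out
}

#' Tabulate conservation-pattern counts
#'
#' Counts each (bias type, pattern) combination over groups.  All-zero
#' patterns are excluded unless they were emitted by
#' [encode_patterns()] with `include_absent = TRUE` and
#' `include_absent = TRUE` is passed here too.
#'
#' @param patterns Data frame from [encode_patterns()].
#' @param include_absent Keep all-zero patterns?
#' @return A data frame with columns `bias_type`, `pattern`, `count`,
#'   carrying the species order as attribute `species_order`.
#' @export
pattern_table <- function(patterns, include_absent = FALSE) {
  df <- patterns
  if (!include_absent && nrow(df) > 0L) {
    df <- df[grepl("1", df$pattern, fixed = TRUE), , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    out <- data.frame(bias_type = character(0), pattern = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            by = df[c("bias_type", "pattern")], FUN = sum)
    out <- agg[order(agg$bias_type, -agg$count, agg$pattern), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "species_order") <- attr(patterns, "species_order")
  out
}

#' Marginal pattern counts over all bias types
#'
#' @param table A [pattern_table()] result.
#' @return A data frame with columns `pattern`, `count`, summed over
#'   bias types and sorted by decreasing count.
#' @export
pattern_marginal <- function(table) {
  if (nrow(table) == 0L) {
    return(data.frame(pattern = character(0), count = integer(0)))
  }
  agg <- stats::aggregate(list(count = table$count),
                          by = table["pattern"], FUN = sum)
  agg <- agg[order(-agg$count, agg$pattern), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Classify a conservation pattern
#'
#' `"conserved"`: a contiguous run of 1s from the reference end covering
#' all but at most the two most distant species (for five species:
#' `11111`, `11110`, `11100`) -- one ancient gain, kept since.
#' `"species-specific"`: exactly one 1.  Everything else: `"other"`.
#'
#' @param pattern Pattern string over `{0,1}`.
#' @return One of `"conserved"`, `"species-specific"`, `"other"`.
#' @export
classify_pattern <- function(pattern) {
  ones <- nchar(gsub("0", "", pattern, fixed = TRUE))
  if (ones == 1L) return("species-specific")
  if (grepl("^1+0*$", pattern) && ones >= nchar(pattern) - 2L) {
    return("conserved")
  }
  "other"
}

#' Most frequent patterns for one bias type
#'
#' @param table A [pattern_table()] result.
#' @param bias_type Bias-type letter present in the table.
#' @param n Number of patterns to return, default 5.
#' @return A data frame with columns `pattern`, `count`, `label`
#'   (from [classify_pattern()]), ordered by decreasing count with ties
#'   broken by pattern string.
#' @export
top_patterns <- function(table, bias_type, n = 5L) {
  sub <- table[table$bias_type == bias_type, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("bias type '", bias_type, "' not present in table", call. = FALSE)
  }
  sub <- sub[order(-sub$count, sub$pattern), , drop = FALSE]
  sub <- utils::head(sub, n)
  sub$label <- vapply(sub$pattern, classify_pattern, character(1L))
  rownames(sub) <- NULL
  sub[c("pattern", "count", "label")]
}
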