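## Readers and writers for the plain-text formats the pipeline consumes:
## FASTA proteomes and alignments, per-residue disorder score tracks,
## ortholog membership tables, PPI edge lists and species metadata tables.
## All coordinates in files are 1-based inclusive; internal intervals are
## 1-based closed integer (start, end) pairs.

.validate_residues <- function(seq, id, allow_gap = FALSE) {
  allowed <- if (allow_gap) c(.AA_ALPHABET, .GAP) else .AA_ALPHABET
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L) {
    stop("illegal character '", chars[bad[1L]], "' at position ", bad[1L],
         " in sequence '", id, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file of protein sequences
#'
#' Sequences are case-normalised to upper case, a single terminal stop
#' character (`*`) is stripped, and the header token before the first
#' whitespace becomes the sequence identifier.  Only the 20 standard
#' amino-acid letters plus `X` are accepted (plus `-` when
#' `gaps = TRUE`, for aligned FASTA).
#'
#' @param path Path to a FASTA file.
#' @param gaps Allow the alignment gap character `-`?
#' @return A named character vector of sequences (names are protein ids).
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path, gaps = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  names(seqs) <- ids
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id '", ids[!nzchar(seqs)][1L], "'", call. = FALSE)
  }
  for (i in seq_along(seqs)) .validate_residues(seqs[[i]], ids[i], allow_gap = gaps)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read per-residue disorder score tracks
#'
#' The track format holds one record per protein: a header line
#' `# <protein_id>` (a `#` followed by exactly one token) followed by one
#' line per residue with fields `position`, `residue`, `score`, separated
#' by whitespace.  Positions must be 1-based and consecutive; scores must
#' lie in \[0, 1\].  `#`-prefixed lines whose remainder is not a single
#' token are treated as comments and skipped.
#'
#' @param path Path to a score-track file.
#' @return A named list of numeric score vectors, one per protein, each
#'   carrying the residue letters as a `residues` attribute (a single
#'   string) for cross-checking against the FASTA sequence.
#' @seealso [write_score_track()], [call_disorder_mask()]
#' @export
read_score_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty score-track file: ", path, call. = FALSE)
  out <- list()
  cur_id <- NULL
  cur_pos <- integer(0)
  cur_res <- character(0)
  cur_score <- numeric(0)
  flush <- function() {
    if (is.null(cur_id)) return(invisible(NULL))
    if (length(cur_score) == 0L) {
      stop("empty score track for protein '", cur_id, "'", call. = FALSE)
    }
    if (!identical(cur_pos, seq_along(cur_pos))) {
      stop("non-consecutive positions in track for protein '", cur_id, "'",
           call. = FALSE)
    }
    track <- cur_score
    attr(track, "residues") <- paste(cur_res, collapse = "")
    out[[cur_id]] <<- track
    invisible(NULL)
  }
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      tok <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1L]]
      tok <- tok[nzchar(tok)]
      if (length(tok) == 1L) {       # record header
        flush()
        if (tok %in% names(out)) {
          stop("duplicate protein id in score track: ", tok, call. = FALSE)
        }
        cur_id <- tok
        cur_pos <- integer(0); cur_res <- character(0); cur_score <- numeric(0)
      }                               # else: comment line, skip
      next
    }
    if (is.null(cur_id)) {
      stop("score line before any '# protein_id' header in ", path, call. = FALSE)
    }
    fields <- strsplit(ln, "\\s+")[[1L]]
    if (length(fields) < 3L) {
      stop("malformed score line (need position, residue, score): '", ln, "'",
           call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(fields[3L]))
    if (is.na(s) || s < 0 || s > 1) {
      stop("score out of [0,1] for protein '", cur_id, "' at position ",
           fields[1L], ": ", fields[3L], call. = FALSE)
    }
    cur_pos <- c(cur_pos, as.integer(fields[1L]))
    cur_res <- c(cur_res, toupper(fields[2L]))
    cur_score <- c(cur_score, s)
  }
  flush()
  out
}

#' Write per-residue disorder score tracks
#'
#' @param tracks Named list of numeric score vectors; each element may carry
#'   a `residues` attribute (otherwise `residues` must be supplied).
#' @param path Output path.
#' @param sequences Optional named character vector supplying the residue
#'   letters for proteins whose track lacks a `residues` attribute.
#' @return The path, invisibly.
#' @export
write_score_track <- function(tracks, path, sequences = NULL) {
  stopifnot(length(tracks) > 0L, !is.null(names(tracks)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(tracks)) {
    sc <- tracks[[id]]
    res <- attr(sc, "residues")
    if (is.null(res)) {
      if (is.null(sequences) || is.na(sequences[id])) {
        stop("no residues available for protein '", id, "'", call. = FALSE)
      }
      res <- sequences[[id]]
    }
    if (nchar(res) != length(sc)) {
      stop("residue/score length mismatch for protein '", id, "'", call. = FALSE)
    }
    writeLines(paste("#", id), con)
    writeLines(sprintf("%d\t%s\t%.4f", seq_along(sc),
                       strsplit(res, "", fixed = TRUE)[[1L]], as.numeric(sc)), con)
  }
  invisible(path)
}

#' Read an ortholog-group membership table
#'
#' Tab-separated file with a header line and columns `group_id`,
#' `species_id`, `protein_id`; one row per group member.  Groups must be
#' one-to-one: at most one protein per species per group.
#'
#' @param path Path to the table.
#' @param species Optional character vector of the configured species; when
#'   given, groups missing any of these species are flagged (kept, but
#'   listed in the `incomplete_groups` attribute and marked in the
#'   `complete` column).
#' @return A data frame with columns `group_id`, `species_id`,
#'   `protein_id` and logical `complete`.
#' @export
read_ortholog_table <- function(path, species = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_id", "species_id", "protein_id")
  if (!all(need %in% names(df))) {
    stop("ortholog table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  key <- paste(df$group_id, df$species_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    stop("ortholog groups are not one-to-one; duplicated (group, species): ",
         paste(gsub("\r", "/", dup), collapse = ", "), call. = FALSE)
  }
  incomplete <- character(0)
  if (!is.null(species)) {
    by_group <- split(df$species_id, df$group_id)
    incomplete <- names(by_group)[!vapply(by_group, function(s)
      all(species %in% s), logical(1L))]
  }
  df$complete <- !(df$group_id %in% incomplete)
  attr(df, "incomplete_groups") <- incomplete
  df
}

#' Write an ortholog-group membership table
#'
#' @param orthologs Data frame with columns `group_id`, `species_id`,
#'   `protein_id`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ortholog_table <- function(orthologs, path) {
  utils::write.table(orthologs[c("group_id", "species_id", "protein_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an undirected PPI network
#'
#' Edges are stored in canonical (sorted endpoint) order, deduplicated
#' regardless of orientation; self-loops are dropped and counted.
#'
#' @param edges Two-column character matrix or data frame of endpoint pairs.
#' @param nodes Optional additional node ids (isolated nodes).
#' @return An object of class `ppi_network`: a list with elements `nodes`
#'   (character), `edges` (data frame with columns `a`, `b`) and
#'   `n_self_loops`.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L && nrow(edges) > 0L) {
    stop("edges must have two columns", call. = FALSE)
  }
  if (nrow(edges) > 0L) {
    a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
    loop <- a == b
    n_loops <- sum(loop)
    a2 <- pmin(a[!loop], b[!loop]); b2 <- pmax(a[!loop], b[!loop])
    key <- paste(a2, b2, sep = "\r")
    keep <- !duplicated(key)
    ed <- data.frame(a = a2[keep], b = b2[keep], stringsAsFactors = FALSE)
    all_nodes <- sort(unique(c(a, b, nodes)))
  } else {
    n_loops <- 0L
    ed <- data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
    all_nodes <- sort(unique(as.character(nodes)))
  }
  structure(list(nodes = all_nodes, edges = ed, n_self_loops = n_loops),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read an undirected edge list
#'
#' One edge per line, two whitespace-separated node ids; further columns
#' are ignored.  `(a, b)` and `(b, a)` are the same edge; self-loops are
#' dropped with a warning giving their count.
#'
#' @param path Path to the edge-list file.
#' @return A [ppi_network()] object.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  toks <- strsplit(lines[keep], "\\s+")
  short <- which(vapply(toks, length, integer(1L)) < 2L)
  if (length(short) > 0L) {
    stop("edge list line ", which(keep)[short[1L]],
         " has fewer than two node ids", call. = FALSE)
  }
  a <- vapply(toks, `[[`, character(1L), 1L)
  b <- vapply(toks, `[[`, character(1L), 2L)
  net <- ppi_network(data.frame(a, b, stringsAsFactors = FALSE))
  if (net$n_self_loops > 0L) {
    warning("dropped ", net$n_self_loops, " self-loop(s) from ", path,
            call. = FALSE)
  }
  net
}

#' Write a PPI network as an edge list
#'
#' @param network A [ppi_network()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  writeLines(paste(network$edges$a, network$edges$b, sep = "\t"), path)
  invisible(path)
}

#' Read a species metadata table
#'
#' Tab-separated file with a header and columns `species_id`,
#' `taxon_label`, `n_proteins` and optionally `n_cell_types` (empty or
#' `NA` when unknown).
#'
#' @param path Path to the table.
#' @return A data frame; `n_cell_types` is `NA` where not annotated.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "taxon_label", "n_proteins")
  if (!all(need %in% names(df))) {
    stop("species table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$species_id)) {
    stop("duplicate species_id in species table", call. = FALSE)
  }
  if (any(df$n_proteins < 1L)) stop("n_proteins must be >= 1", call. = FALSE)
  if (!"n_cell_types" %in% names(df)) df$n_cell_types <- NA_integer_
  if (any(!is.na(df$n_cell_types) & df$n_cell_types < 1L)) {
    stop("n_cell_types must be >= 1 when present", call. = FALSE)
  }
  df
}

#' Write a species metadata table
#'
#' @param species_table Data frame as returned by [read_species_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_species_table <- function(species_table, path) {
  utils::write.table(species_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' All rows must have identical length.  When the ungapped member
#' sequences are supplied, each degapped row is checked against them
#' (gap-strip consistency).
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @param sequences Optional named character vector of ungapped sequences
#'   to validate against.
#' @return A named character vector of aligned rows.
#' @export
read_alignment <- function(path, sequences = NULL) {
  rows <- read_fasta(path, gaps = TRUE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths in ", path, call. = FALSE)
  }
  if (!is.null(sequences)) {
    for (id in names(rows)) {
      degapped <- gsub("-", "", rows[[id]], fixed = TRUE)
      if (!id %in% names(sequences)) next
      if (!identical(degapped, unname(sequences[[id]]))) {
        stop("degapped alignment row for '", id,
             "' does not match its sequence", call. = FALSE)
      }
    }
  }
  rows
}
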