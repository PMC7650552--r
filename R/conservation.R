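## Disorder conservation across ortholog groups.
##
## Per-residue disorder flags are projected through the group's multiple
## sequence alignment, labelling each alignment column of each row as
## disordered, ordered or gap.  Conservation between the reference
## species and each ortholog is the Jaccard index over alignment columns:
## columns disordered in both / columns disordered in at least one.  A
## disordered residue aligned to a gap counts in the union but never in
## the intersection.  Conservation profiles (one row per group, one
## column per comparison species) are clustered with complete-linkage
## hierarchical clustering on Euclidean distances.

#' Project a per-residue disorder mask onto alignment columns
#'
#' @param aligned_row Aligned sequence string (residues and `-` gaps).
#' @param flags Logical per-residue disorder flags for the ungapped
#'   sequence; its length must equal the number of non-gap characters.
#' @return A character vector over alignment columns with values
#'   `"disordered"`, `"ordered"` or `"gap"`.
#' @export
#' @examples
#' project_mask("A-C", c(TRUE, FALSE))
project_mask <- function(aligned_row, flags) {
  chars <- strsplit(aligned_row, "", fixed = TRUE)[[1L]]
  is_res <- chars != .GAP
  if (sum(is_res) != length(flags)) {
    stop("mask length (", length(flags), ") does not match ungapped row length (",
         sum(is_res), ")", call. = FALSE)
  }
  out <- rep("gap", length(chars))
  out[is_res] <- ifelse(flags, "disordered", "ordered")
  out
}

#' Jaccard index of disorder between two aligned column masks
#'
#' Columns disordered in both rows divided by columns disordered in at
#' least one row.  When neither row has any disordered column the score
#' is defined as 1 (identical, empty disorder); in reference-vs-IDP
#' analyses this degenerate case cannot arise because the reference
#' protein always has at least one IDR.
#'
#' @param a,b Column masks from [project_mask()] over the same alignment.
#' @return A number in \[0, 1\].
#' @export
jaccard_disorder <- function(a, b) {
  if (length(a) != length(b)) {
    stop("column-count mismatch between masks", call. = FALSE)
  }
  da <- a == "disordered"
  db <- b == "disordered"
  union <- sum(da | db)
  if (union == 0L) return(1)
  sum(da & db) / union
}

#' Pairwise sequence identity over mutually ungapped columns
#'
#' Identical residue columns divided by columns where both rows carry a
#' residue; columns with a gap in either row are excluded from the
#' denominator.
#'
#' @param row_a,row_b Aligned sequence strings of equal length.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' pairwise_identity("A-CD", "AG-D")  # 1: shared columns {A, D} both match
pairwise_identity <- function(row_a, row_b) {
  ca <- strsplit(row_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(row_b, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) stop("row length mismatch", call. = FALSE)
  shared <- ca != .GAP & cb != .GAP
  if (!any(shared)) {
    stop("no mutually ungapped columns; identity undefined", call. = FALSE)
  }
  sum(ca[shared] == cb[shared]) / sum(shared)
}

#' Build the disorder-conservation and identity matrices
#'
#' For every complete ortholog group, computes the Jaccard
#' disorder-conservation score and the pairwise sequence identity between
#' the reference species and each comparison species, and the per-species
#' Pearson correlation between conservation and identity across groups
#' (a check that sequence similarity does not drive the conservation
#' signal).
#'
#' @param alignments Named list (by `group_id`) of alignments, each a
#'   named character vector of aligned rows keyed by `species_id`.
#' @param masks Named list (by `protein_id`) of logical per-residue
#'   disorder flag vectors, or of [disorder_mask()] objects.
#' @param orthologs Ortholog membership data frame (`group_id`,
#'   `species_id`, `protein_id`), as from [read_ortholog_table()].
#' @param reference Reference species id, default `"human"`.
#' @param species Ordered character vector of all species in the panel;
#'   defaults to the species present in `orthologs`, reference first.
#' @return A list of class `conservation_matrix` with elements `jaccard`
#'   (groups x comparison-species matrix), `identity` (same shape),
#'   `identity_correlation` (named per-species r, `NA` when degenerate),
#'   `reference` and `species`.
#' @export
build_conservation_matrix <- function(alignments, masks, orthologs,
                                      reference = "human", species = NULL) {
  if (is.null(species)) {
    sp <- unique(orthologs$species_id)
    species <- c(reference, setdiff(sp, reference))
  }
  if (!reference %in% species) {
    stop("reference species '", reference, "' not in species list", call. = FALSE)
  }
  comparison <- setdiff(species, reference)
  get_flags <- function(pid) {
    m <- masks[[pid]]
    if (is.null(m)) stop("no disorder mask for protein '", pid, "'", call. = FALSE)
    if (inherits(m, "disorder_mask")) m$flags else m
  }
  groups <- intersect(names(alignments), unique(orthologs$group_id))
  groups <- sort(groups)
  member <- function(gid, sp) {
    pid <- orthologs$protein_id[orthologs$group_id == gid &
                                orthologs$species_id == sp]
    if (length(pid) != 1L) {
      stop("group '", gid, "' has no unique member for species '", sp, "'",
           call. = FALSE)
    }
    pid
  }
  jac <- matrix(NA_real_, nrow = length(groups), ncol = length(comparison),
                dimnames = list(groups, comparison))
  idm <- jac
  for (gid in groups) {
    aln <- alignments[[gid]]
    missing_sp <- setdiff(species, names(aln))
    if (length(missing_sp) > 0L) {
      stop("alignment for group '", gid, "' lacks species: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
    ref_pid <- member(gid, reference)
    ref_cols <- project_mask(aln[[reference]], get_flags(ref_pid))
    for (sp in comparison) {
      pid <- member(gid, sp)
      sp_cols <- project_mask(aln[[sp]], get_flags(pid))
      jac[gid, sp] <- jaccard_disorder(ref_cols, sp_cols)
      idm[gid, sp] <- pairwise_identity(aln[[reference]], aln[[sp]])
    }
  }
  idc <- vapply(comparison, function(sp) {
    x <- jac[, sp]; y <- idm[, sp]
    if (length(x) < 3L || stats::var(x) == 0 || stats::var(y) == 0) {
      return(NA_real_)
    }
    pearson_r(x, y)$r
  }, numeric(1L))
  structure(list(jaccard = jac, identity = idm, identity_correlation = idc,
                 reference = reference, species = species),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("conservation_matrix:", nrow(x$jaccard), "groups x",
      ncol(x$jaccard), "comparison species (reference:", x$reference, ")\n")
  invisible(x)
}

#' Cluster conservation profiles
#'
#' Complete-linkage agglomerative clustering on the Euclidean distance
#' matrix between row vectors, cut either at a requested number of
#' clusters `k` or at a height `h`.  Rows are sorted lexicographically by
#' id before clustering so the result does not depend on input order.
#'
#' @param x A `conservation_matrix` (its Jaccard matrix is used) or a
#'   numeric matrix with row names.
#' @param k Number of clusters to cut at (default 7).
#' @param h Alternative: cut height (overrides `k` when given).
#' @return A list of class `cluster_assignment` with elements `labels`
#'   (named integer vector), `hclust`, `k`, `h`.
#' @export
cluster_rows <- function(x, k = 7L, h = NULL) {
  mat <- if (inherits(x, "conservation_matrix")) x$jaccard else as.matrix(x)
  if (nrow(mat) < 2L) stop("need at least 2 rows to cluster", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (is.null(h) && (is.null(k) || k > nrow(mat))) {
    stop("k must be between 1 and the number of rows", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  labels <- if (!is.null(h)) stats::cutree(hc, h = h) else stats::cutree(hc, k = k)
  structure(list(labels = labels, hclust = hc,
                 k = length(unique(labels)), h = h),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$labels), "rows in", x$k, "clusters\n")
  print(table(x$labels))
  invisible(x)
}

#' Per-cluster, per-species IDP fractions
#'
#' For each cluster of ortholog groups and each species, the fraction of
#' member orthologs that are IDPs.  High disorder conservation to the
#' reference should coincide with high IDP fraction of the corresponding
#' species in the cluster.
#'
#' @param assignment A [cluster_rows()] result over ortholog groups.
#' @param idp_status Logical matrix (groups x species, with dimnames):
#'   is the species' ortholog in that group an IDP?
#' @return A numeric matrix clusters x species of IDP fractions.
#' @export
cluster_disorder_profile <- function(assignment, idp_status) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  groups <- names(assignment$labels)
  missing_g <- setdiff(groups, rownames(idp_status))
  if (length(missing_g) > 0L) {
    stop("idp_status lacks groups: ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  }
  m <- idp_status[groups, , drop = FALSE]
  cl <- assignment$labels
  out <- t(vapply(sort(unique(cl)), function(k)
    colMeans(m[cl == k, , drop = FALSE]), numeric(ncol(m))))
  rownames(out) <- sort(unique(cl))
  out
}
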