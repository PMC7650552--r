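## Synthetic-data generators.  Every input the pipeline consumes can be
## generated with planted, parameterised structure: proteomes with a
## controlled IDP fraction, ortholog groups whose disorder conservation
## to the reference follows planted archetypes, sequences with planted
## compositionally biased segments, and PPI networks with one planted
## dense module on a sparse random background.  All draws are controlled
## by a single integer seed.

## Average amino-acid frequencies of well-curated protein databases,
## normalised; used when composition = "natural".
.AA_NATURAL_FREQ <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93, E = 6.72,
  G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80, M = 2.41, F = 3.86,
  P = 4.74, S = 6.65, T = 5.36, W = 1.10, Y = 2.92, V = 6.86
) / 100

.random_aa <- function(n, composition = c("uniform", "natural")) {
  composition <- match.arg(composition)
  if (composition == "uniform") {
    sample(.AA20, n, replace = TRUE)
  } else {
    sample(names(.AA_NATURAL_FREQ), n, replace = TRUE,
           prob = .AA_NATURAL_FREQ)
  }
}

.clip01 <- function(x) pmin(1, pmax(0, x))

## Per-residue scores: ordered baseline well below the cutoff, disordered
## baseline well above, plus clipped Gaussian noise.  With the default
## noise level a baseline residue crossing the 0.5 boundary would be a
## > 5 sigma event, so planted masks survive thresholding.
.plant_scores <- function(len, idr_start, idr_len, noise_sd) {
  sc <- stats::runif(len, 0.03, 0.32)
  if (!is.na(idr_start) && idr_len > 0L) {
    sc[idr_start:(idr_start + idr_len - 1L)] <- stats::runif(idr_len, 0.68, 0.97)
  }
  .clip01(sc + stats::rnorm(len, 0, noise_sd))
}

#' Generate a synthetic proteome with planted IDRs
#'
#' Each protein is a random sequence with a per-residue disorder score
#' track.  A protein becomes an IDP with probability `idp_fraction`, in
#' which case one contiguous IDR of random length is planted: its scores
#' are drawn above the cutoff and all other scores below, with clipped
#' Gaussian noise added on top.
#'
#' @param n_proteins Number of proteins.
#' @param idp_fraction Probability that a protein carries a planted IDR.
#' @param length_range Protein length range (uniform integer draw).
#' @param idr_length_range Planted IDR length range; the minimum must not
#'   exceed the shortest possible protein.
#' @param noise_sd Standard deviation of the Gaussian score noise.
#' @param composition `"uniform"` or `"natural"` amino-acid composition.
#' @param species_id Species identifier used in ids.
#' @param seed Optional integer seed.
#' @return A list with elements `sequences` (named character),
#'   `tracks` (named list of score vectors with `residues` attributes),
#'   `truth` (data frame: `protein_id`, `is_idp`, `idr_start`,
#'   `idr_end`) and `species_id`.
#' @export
simulate_proteome <- function(n_proteins = 1000L, idp_fraction = 0.3,
                              length_range = c(120L, 400L),
                              idr_length_range = c(30L, 90L),
                              noise_sd = 0.03,
                              composition = c("uniform", "natural"),
                              species_id = "synthetic", seed = NULL) {
  composition <- match.arg(composition)
  if (idp_fraction < 0 || idp_fraction > 1) {
    stop("idp_fraction must be in [0, 1]", call. = FALSE)
  }
  if (idr_length_range[1L] > length_range[1L]) {
    stop("planted IDR length exceeds minimum protein length", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("%s_p%05d", species_id, seq_len(n_proteins))
  seqs <- character(n_proteins)
  tracks <- vector("list", n_proteins)
  is_idp <- stats::runif(n_proteins) < idp_fraction
  idr_start <- rep(NA_integer_, n_proteins)
  idr_end <- rep(NA_integer_, n_proteins)
  for (i in seq_len(n_proteins)) {
    len <- sample(length_range[1L]:length_range[2L], 1L)
    chars <- .random_aa(len, composition)
    seqs[i] <- paste(chars, collapse = "")
    if (is_idp[i]) {
      ilen <- sample(idr_length_range[1L]:min(idr_length_range[2L], len), 1L)
      istart <- sample.int(len - ilen + 1L, 1L)
      idr_start[i] <- istart
      idr_end[i] <- istart + ilen - 1L
      sc <- .plant_scores(len, istart, ilen, noise_sd)
    } else {
      sc <- .plant_scores(len, NA_integer_, 0L, noise_sd)
    }
    attr(sc, "residues") <- seqs[i]
    tracks[[i]] <- sc
  }
  names(seqs) <- ids
  names(tracks) <- ids
  list(sequences = seqs, tracks = tracks,
       truth = data.frame(protein_id = ids, is_idp = is_idp,
                          idr_start = idr_start, idr_end = idr_end,
                          stringsAsFactors = FALSE),
       species_id = species_id)
}

#' Generate a panel of synthetic species with disorder tied to cell types
#'
#' Emulates a set of related species whose proteome disorder content
#' increases linearly with the number of cell types, for testing the
#' disorder-vs-organismal-complexity correlation analysis.
#'
#' @param n_species Number of species.
#' @param n_proteins Proteins per species.
#' @param cell_type_range Range of cell-type numbers (linearly spaced).
#' @param idp_fraction_range Planted IDP fraction at the two ends of the
#'   cell-type range.
#' @param fraction_noise_sd Gaussian noise on the planted fraction.
#' @param seed Optional integer seed.
#' @return A list with `proteomes` (list of [simulate_proteome()] results)
#'   and `species_table` (data frame with `n_cell_types` annotated).
#' @export
simulate_taxon_panel <- function(n_species = 12L, n_proteins = 400L,
                                 cell_type_range = c(20L, 220L),
                                 idp_fraction_range = c(0.15, 0.55),
                                 fraction_noise_sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cts <- round(seq(cell_type_range[1L], cell_type_range[2L],
                   length.out = n_species))
  frac <- seq(idp_fraction_range[1L], idp_fraction_range[2L],
              length.out = n_species) +
    stats::rnorm(n_species, 0, fraction_noise_sd)
  frac <- pmin(0.95, pmax(0.05, frac))
  ids <- sprintf("sp%02d", seq_len(n_species))
  proteomes <- lapply(seq_len(n_species), function(i)
    simulate_proteome(n_proteins = n_proteins, idp_fraction = frac[i],
                      species_id = ids[i]))
  names(proteomes) <- ids
  tab <- data.frame(species_id = ids,
                    taxon_label = "synthetic_vertebrate",
                    n_proteins = n_proteins,
                    n_cell_types = cts,
                    stringsAsFactors = FALSE)
  list(proteomes = proteomes, species_table = tab,
       planted_fraction = frac)
}

#' Default disorder-conservation archetypes
#'
#' Four archetypal conservation profiles (expected Jaccard score to the
#' reference per comparison species): conserved in all species, conserved
#' in the near relatives only, low everywhere, and conserved in the
#' closest relative only.
#'
#' @param comparison Character vector of comparison species ids.
#' @return A numeric matrix, one archetype per row.
#' @export
default_archetypes <- function(comparison = c("mouse", "fish", "fly", "yeast")) {
  m <- rbind(
    conserved_all = rep(0.9, length(comparison)),
    conserved_near = c(rep(0.9, ceiling(length(comparison) / 2)),
                       rep(0.2, floor(length(comparison) / 2))),
    low_all = rep(0.2, length(comparison)),
    nearest_only = c(0.9, rep(0.2, length(comparison) - 1L))
  )
  colnames(m) <- comparison
  m
}

#' Generate ortholog groups with planted disorder-conservation archetypes
#'
#' Each group has one protein per species.  The reference protein carries
#' one planted IDR; each ortholog's IDR is a block of the same length
#' shifted so that the column Jaccard index against the reference equals
#' a target value drawn from the group's archetype (Gaussian noise with
#' `archetype_sd`, clipped to \[0.02, 1\]).  Ortholog sequences are the
#' reference with per-species point substitutions, so sequence identity
#' is governed by `sub_rates` independently of the planted conservation.
#' With probability `indel_rate` a non-reference species receives an
#' insertion in the tail region (past all disorder blocks), realised as
#' gap columns in every other row.
#'
#' @param n_groups Number of ortholog groups (archetypes are assigned
#'   round-robin).
#' @param archetypes Numeric matrix of target Jaccard values, one row per
#'   archetype, one column per comparison species; default
#'   [default_archetypes()].
#' @param archetype_sd Gaussian noise on the target values.
#' @param species Ordered species panel (reference first).
#' @param reference Reference species id.
#' @param ref_length Protein length; must leave room for the disorder
#'   block at any shift plus a tail for insertions.
#' @param idr_length Planted IDR length (>= the IDR calling minimum).
#' @param idr_start Start of the reference disorder block.
#' @param sub_rates Named per-species substitution rates (comparison
#'   species); default increases with distance from the reference.
#' @param indel_rate Per-species probability of one tail insertion.
#' @param indel_length_range Insertion length range.
#' @param noise_sd Score-track noise, as in [simulate_proteome()].
#' @param seed Optional integer seed.
#' @return A list with `orthologs` (membership data frame), `alignments`
#'   (list by group of named aligned rows), `group_sequences` (list by
#'   group of named ungapped sequences), `sequences` (flat named
#'   character vector), `tracks` (flat named list), `groups` (data
#'   frame: `group_id`, `archetype`) and `truth` (data frame per group x
#'   comparison species: target and realised Jaccard).
#' @export
simulate_ortholog_set <- function(n_groups = 200L, archetypes = NULL,
                                  archetype_sd = 0.05,
                                  species = default_species()$species_id,
                                  reference = "human",
                                  ref_length = 300L, idr_length = 120L,
                                  idr_start = 21L,
                                  sub_rates = NULL, indel_rate = 0.3,
                                  indel_length_range = c(5L, 15L),
                                  noise_sd = 0.02, seed = NULL) {
  comparison <- setdiff(species, reference)
  if (is.null(archetypes)) archetypes <- default_archetypes(comparison)
  archetypes <- as.matrix(archetypes)
  if (ncol(archetypes) != length(comparison)) {
    stop("archetypes must have one column per comparison species",
         call. = FALSE)
  }
  if (any(archetypes < 0) || any(archetypes > 1)) {
    stop("archetype values must lie in [0, 1]", call. = FALSE)
  }
  colnames(archetypes) <- comparison
  if (is.null(rownames(archetypes))) {
    rownames(archetypes) <- sprintf("archetype%d", seq_len(nrow(archetypes)))
  }
  if (is.null(sub_rates)) {
    sub_rates <- stats::setNames(
      seq(0.05, 0.45, length.out = length(comparison)), comparison)
  }
  n_groups <- as.integer(n_groups)
  ref_length <- as.integer(ref_length)
  idr_length <- as.integer(idr_length)
  idr_start <- as.integer(idr_start)
  indel_length_range <- as.integer(indel_length_range)
  tail_start <- idr_start + 2L * idr_length
  if (tail_start + 10L > ref_length) {
    stop("ref_length too short for idr_length at any shift", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  D <- idr_length
  gids <- sprintf("g%04d", seq_len(n_groups))
  arch_of <- rownames(archetypes)[((seq_len(n_groups) - 1L) %%
                                   nrow(archetypes)) + 1L]
  orth_rows <- vector("list", n_groups)
  truth_rows <- vector("list", n_groups)
  alignments <- vector("list", n_groups)
  group_sequences <- vector("list", n_groups)
  all_tracks <- list()

  for (g in seq_len(n_groups)) {
    gid <- gids[g]
    arch <- archetypes[arch_of[g], ]
    ref_chars <- .random_aa(ref_length)
    rows <- list()     # per-species char vectors (alignment coordinates)
    scores <- list()   # per-species numeric, NA at gap columns
    block_of <- list()
    rows[[reference]] <- ref_chars
    scores[[reference]] <- .plant_scores(ref_length, idr_start, D, noise_sd)
    block_of[[reference]] <- c(idr_start, idr_start + D - 1L)
    targets <- numeric(0)
    for (sp in comparison) {
      t_sp <- min(1, max(0.02, stats::rnorm(1L, arch[[sp]], archetype_sd)))
      targets[[sp]] <- t_sp
      shift <- as.integer(round(D * (1 - t_sp) / (1 + t_sp)))
      chars <- ref_chars
      sub_at <- which(stats::runif(ref_length) < sub_rates[[sp]])
      if (length(sub_at) > 0L) chars[sub_at] <- .random_aa(length(sub_at))
      rows[[sp]] <- chars
      scores[[sp]] <- .plant_scores(ref_length, idr_start + shift, D, noise_sd)
      block_of[[sp]] <- c(idr_start + shift, idr_start + shift + D - 1L)
    }
    ## tail insertions: gap columns in every row except the inserting one
    ins_sp <- comparison[stats::runif(length(comparison)) < indel_rate]
    if (length(ins_sp) > 0L) {
      pos_pool <- tail_start:(ref_length - 1L)
      pos <- sort(sample(pos_pool, length(ins_sp)), decreasing = TRUE)
      for (k in seq_along(ins_sp)) {
        sp <- ins_sp[k]
        glen <- sample(indel_length_range[1L]:indel_length_range[2L], 1L)
        for (q in names(rows)) {
          at <- pos[k]
          if (q == sp) {
            ins_chars <- .random_aa(glen)
            ins_sc <- .clip01(stats::runif(glen, 0.03, 0.32) +
                              stats::rnorm(glen, 0, noise_sd))
          } else {
            ins_chars <- rep(.GAP, glen)
            ins_sc <- rep(NA_real_, glen)
          }
          rows[[q]] <- append(rows[[q]], ins_chars, after = at)
          scores[[q]] <- append(scores[[q]], ins_sc, after = at)
        }
      }
    }
    pids <- stats::setNames(paste(gid, species, sep = "_"), species)
    aln <- vapply(species, function(sp) paste(rows[[sp]], collapse = ""),
                  character(1L))
    names(aln) <- species
    seqs_g <- vapply(species, function(sp)
      paste(rows[[sp]][rows[[sp]] != .GAP], collapse = ""), character(1L))
    names(seqs_g) <- species
    for (sp in species) {
      sc <- scores[[sp]][!is.na(scores[[sp]])]
      attr(sc, "residues") <- seqs_g[[sp]]
      all_tracks[[pids[[sp]]]] <- sc
    }
    alignments[[g]] <- aln
    group_sequences[[g]] <- seqs_g
    orth_rows[[g]] <- data.frame(group_id = gid, species_id = species,
                                 protein_id = unname(pids[species]),
                                 stringsAsFactors = FALSE)
    shift_of <- vapply(comparison, function(sp)
      block_of[[sp]][1L] - idr_start, integer(1L))
    truth_rows[[g]] <- data.frame(
      group_id = gid, species_id = comparison,
      archetype = arch_of[g],
      target_jaccard = unname(unlist(targets[comparison])),
      realized_jaccard = (D - shift_of) / (D + shift_of),
      stringsAsFactors = FALSE)
  }
  names(alignments) <- gids
  names(group_sequences) <- gids
  sequences <- unlist(lapply(seq_len(n_groups), function(g) {
    s <- group_sequences[[g]]
    stats::setNames(unname(s), paste(gids[g], names(s), sep = "_"))
  }))
  orthologs <- do.call(rbind, orth_rows)
  orthologs$complete <- TRUE
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(orthologs = orthologs, alignments = alignments,
       group_sequences = group_sequences, sequences = sequences,
       tracks = all_tracks,
       groups = data.frame(group_id = gids, archetype = arch_of,
                           stringsAsFactors = FALSE),
       truth = truth, species = species, reference = reference)
}

## Clades of the ladder species tree implied by the panel order
## ((((s1, s2), s3), s4), s5): each terminal branch plus each internal
## prefix.  A single gain on one branch makes the clade's species
## present.
.lineage_clades <- function(species) {
  n <- length(species)
  c(lapply(seq_len(n), function(i) species[i]),
    lapply(2L:(n - 1L), function(k) species[seq_len(k)]),
    list(species))
}

#' Plant compositionally biased segments into ortholog sequences
#'
#' For each group and bias type, decides which species carry the bias --
#' independently with probability `prob` per species, or by a single
#' gain event on a random branch of the ladder lineage implied by the
#' species order (`mode = "lineage"`, which can never produce a pattern
#' with an absence surrounded by presences) -- and replaces a window of
#' the carrier sequence with a biased segment.  The segment contains
#' enough of the target residue that its score against the target
#' homopolymer is at least `threshold + 2` by construction, with the
#' remaining positions random (impure tracts test detector robustness).
#' Replacement (rather than insertion) keeps companion alignments valid;
#' when `alignments` is supplied the corresponding row is patched.
#'
#' @param sequences Named character vector of sequences.
#' @param orthologs Ortholog membership data frame (`group_id`,
#'   `species_id`, `protein_id`).
#' @param species Ordered species panel.
#' @param types Bias types to plant, default `"Q"`.
#' @param prob Per-species presence probability (scalar or named by
#'   species); used in independent mode.
#' @param mode `"independent"` or `"lineage"`.
#' @param insert_length Length of the planted segment.
#' @param purity Minimum fraction of target residues in the segment.
#' @param threshold Detection threshold the segment must exceed.
#' @param alignments Optional list of alignments (by group) to patch.
#' @param seed Optional integer seed.
#' @return A list with `sequences` (modified), `alignments` (patched or
#'   `NULL`) and `truth` (data frame: `group_id`, `species_id`,
#'   `protein_id`, `bias_type`, `start`, `end`).
#' @export
plant_cbrs <- function(sequences, orthologs, species,
                       types = "Q", prob = 0.5,
                       mode = c("independent", "lineage"),
                       insert_length = 12L, purity = 0.8, threshold = 40L,
                       alignments = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(types %in% .AA20))
  if (mode == "independent") {
    if (is.null(names(prob))) {
      prob <- stats::setNames(rep(prob[1L], length(species)), species)
    }
    if (any(prob < 0) || any(prob > 1)) {
      stop("presence probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  blos <- disevo_blosum62()
  clades <- if (mode == "lineage") .lineage_clades(species) else NULL
  gids <- unique(orthologs$group_id)
  truth <- list()
  m <- as.integer(insert_length)
  used <- new.env(parent = emptyenv())   # per-protein occupied windows
  for (gid in gids) {
    sub <- orthologs[orthologs$group_id == gid, ]
    pid_of <- stats::setNames(sub$protein_id, sub$species_id)
    for (tp in types) {
      diag_sc <- blos[tp, tp]
      n_own <- max(ceiling(purity * m),
                   ceiling((threshold + 2 + 3 * m) / (diag_sc + 3)))
      if (n_own > m) {
        stop("insert_length ", m, " too short to guarantee a ", tp,
             "-rich segment scoring >= ", threshold, call. = FALSE)
      }
      present_sp <- if (mode == "independent") {
        species[stats::runif(length(species)) < prob[species]]
      } else {
        clades[[sample.int(length(clades), 1L)]]
      }
      present_sp <- intersect(present_sp, names(pid_of))
      for (sp in present_sp) {
        pid <- pid_of[[sp]]
        s <- sequences[[pid]]
        if (m > nchar(s)) {
          stop("planted segment longer than host sequence '", pid, "'",
               call. = FALSE)
        }
        ## place the window clear of segments already planted in this
        ## protein (other types), so earlier plants are not overwritten
        occupied <- if (is.null(used[[pid]])) {
          matrix(integer(0), ncol = 2L)
        } else {
          used[[pid]]
        }
        start <- NA_integer_
        for (try in seq_len(200L)) {
          cand <- sample.int(nchar(s) - m + 1L, 1L)
          if (nrow(occupied) == 0L ||
              all(cand > occupied[, 2L] | cand + m - 1L < occupied[, 1L])) {
            start <- cand
            break
          }
        }
        if (is.na(start)) {
          stop("could not place a non-overlapping ", tp,
               "-rich segment in '", pid, "'", call. = FALSE)
        }
        used[[pid]] <- rbind(occupied, c(start, start + m - 1L))
        seg <- .random_aa(m)
        seg[sample.int(m, n_own)] <- tp
        substr(s, start, start + m - 1L) <- paste(seg, collapse = "")
        sequences[[pid]] <- s
        if (!is.null(alignments) && gid %in% names(alignments)) {
          row <- alignments[[gid]][[sp]]
          chars <- strsplit(row, "", fixed = TRUE)[[1L]]
          res_idx <- which(chars != .GAP)
          chars[res_idx[start:(start + m - 1L)]] <- seg
          alignments[[gid]][[sp]] <- paste(chars, collapse = "")
        }
        truth[[length(truth) + 1L]] <- data.frame(
          group_id = gid, species_id = sp, protein_id = pid,
          bias_type = tp, start = start, end = start + m - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else {
    data.frame(group_id = character(0), species_id = character(0),
               protein_id = character(0), bias_type = character(0),
               start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  list(sequences = sequences, alignments = alignments, truth = truth)
}

#' Generate a random PPI network with one planted dense module
#'
#' Erdős–Rényi background: every unordered node pair is an edge with
#' probability `edge_prob`, except pairs inside the planted module,
#' which are edges with probability `module_prob`.
#'
#' @param n_nodes Number of nodes (ignored when `node_ids` is given).
#' @param edge_prob Background edge probability.
#' @param module_size Planted module size.
#' @param module_prob Internal edge probability of the module.
#' @param node_ids Optional character vector of node ids.
#' @param module_ids Optional explicit module members (overrides random
#'   choice; must be a subset of the nodes).
#' @param seed Optional integer seed.
#' @return A list with `network` (a [ppi_network()]), `background` (all
#'   node ids) and `module` (module member ids).
#' @export
simulate_ppi <- function(n_nodes = 984L, edge_prob = 0.005,
                         module_size = 20L, module_prob = 0.5,
                         node_ids = NULL, module_ids = NULL, seed = NULL) {
  if (!is.null(node_ids)) n_nodes <- length(node_ids)
  if (!is.null(module_ids)) module_size <- length(module_ids)
  if (module_size > n_nodes) {
    stop("module size exceeds node count", call. = FALSE)
  }
  if (edge_prob < 0 || edge_prob > 1 || module_prob < 0 || module_prob > 1) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- if (is.null(node_ids)) sprintf("prot%05d", seq_len(n_nodes)) else node_ids
  if (is.null(module_ids)) {
    module_ids <- if (module_size > 0L) sample(ids, module_size) else character(0)
  } else {
    stopifnot(all(module_ids %in% ids))
  }
  ut <- which(upper.tri(matrix(FALSE, n_nodes, n_nodes)))
  idx <- arrayInd(ut, c(n_nodes, n_nodes))
  in_mod <- ids[idx[, 1L]] %in% module_ids & ids[idx[, 2L]] %in% module_ids
  p <- ifelse(in_mod, module_prob, edge_prob)
  draw <- stats::runif(length(p)) < p
  edges <- data.frame(a = ids[idx[draw, 1L]], b = ids[idx[draw, 2L]],
                      stringsAsFactors = FALSE)
  list(network = ppi_network(edges, nodes = ids),
       background = ids, module = module_ids)
}
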