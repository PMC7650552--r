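## End-to-end orchestration.  `validate_config()` normalises a YAML (or
## list) configuration against the package defaults; `run_all()` executes
## simulate -> annotate -> summarize -> cbr -> conserve -> cluster ->
## enrich-ppi -> patterns, writing every intermediate as a plain-text
## file and finishing with a manifest of output digests, so that a rerun
## with the same configuration can be verified byte-for-byte.

#' Default pipeline configuration
#'
#' The analysis defaults: disorder cutoff 0.5 (>=), minimum IDR length
#' 30 residues, proteome filter at 300 proteins, CBR threshold 40 under
#' BLOSUM62, 7 conservation clusters, 10000 Monte-Carlo draws; plus the
#' default synthetic-data block used when no real inputs are supplied.
#'
#' @return A nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    species = default_species()$species_id,
    reference = "human",
    cutoff = 0.5,
    strict_cutoff = FALSE,
    min_idr_length = 30L,
    min_proteins = 300L,
    residue_counting = "idr",
    cast_threshold = 40L,
    n_clusters = 7L,
    ppi_samples = 10000L,
    simulate = list(
      n_groups = 60L,
      archetype_sd = 0.05,
      ref_length = 220L,
      idr_length = 60L,
      indel_rate = 0.3,
      cbr_types = "Q",
      cbr_prob = 0.5,
      cbr_mode = "independent",
      ppi = list(
        edge_prob = 0.01,
        module_size = 12L,
        module_prob = 0.5
      )
    )
  )
}

.check_range <- function(cfg, key, lo, hi, path = key) {
  v <- cfg[[key]]
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi) {
    stop("config key '", path, "' must be a number in [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  invisible(TRUE)
}

.merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key", if (length(unknown) > 1L) "s", ": ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) {
        stop("config key '", path, k, "' must be a mapping", call. = FALSE)
      }
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     path = paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults from
#' [default_config()], rejects unknown keys (naming them) and checks
#' value ranges.
#'
#' @param config `NULL` (all defaults), a path to a YAML file, or a list.
#' @return The normalised configuration, class `disevo_config`.
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_config()
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config, call. = FALSE)
    y <- yaml::read_yaml(config)
    if (is.null(y)) list() else y
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be NULL, a file path or a list", call. = FALSE)
  }
  cfg <- .merge_config(defaults, user)
  .check_range(cfg, "cutoff", 0, 1)
  .check_range(cfg, "min_idr_length", 1, Inf)
  .check_range(cfg, "min_proteins", 0, Inf)
  .check_range(cfg, "cast_threshold", 1, Inf)
  .check_range(cfg, "n_clusters", 1, Inf)
  .check_range(cfg, "ppi_samples", 100, Inf)
  .check_range(cfg$simulate, "n_groups", 2, Inf, "simulate.n_groups")
  .check_range(cfg$simulate, "archetype_sd", 0, 1, "simulate.archetype_sd")
  .check_range(cfg$simulate, "indel_rate", 0, 1, "simulate.indel_rate")
  .check_range(cfg$simulate, "cbr_prob", 0, 1, "simulate.cbr_prob")
  .check_range(cfg$simulate$ppi, "edge_prob", 0, 1, "simulate.ppi.edge_prob")
  .check_range(cfg$simulate$ppi, "module_prob", 0, 1, "simulate.ppi.module_prob")
  if (!cfg$residue_counting %in% c("idr", "flag")) {
    stop("config key 'residue_counting' must be 'idr' or 'flag'", call. = FALSE)
  }
  if (!cfg$simulate$cbr_mode %in% c("independent", "lineage")) {
    stop("config key 'simulate.cbr_mode' must be 'independent' or 'lineage'",
         call. = FALSE)
  }
  if (!cfg$reference %in% cfg$species) {
    stop("reference species must be in the species list", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("disevo_config", "list"))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' Generates a complete synthetic input set under the configuration's
#' `simulate` block, writes it to `out_dir/input` and `out_dir/truth`,
#' then reads the inputs back through the package's readers and executes
#' every analysis stage, writing each result as a TSV under
#' `out_dir/output`.  A `manifest.yaml` records the configuration, the
#' MD5 digest and row count of every file.  Outputs are pure functions
#' of (configuration, seed): rerunning with the same configuration
#' reproduces them byte-for-byte.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_all <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "disevo_config")) config else validate_config(config)
  stage <- local({
    current <- NA_character_
    function(name, expr) {
      current <<- name
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      })
    }
  })
  in_dir <- file.path(out_dir, "input")
  tr_dir <- file.path(out_dir, "truth")
  res_dir <- file.path(out_dir, "output")
  msa_dir <- file.path(in_dir, "msa")
  for (d in c(out_dir, in_dir, tr_dir, res_dir, msa_dir)) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  species <- cfg$species
  reference <- cfg$reference
  sim <- cfg$simulate
  seed <- cfg$seed

  ## ---- simulate ------------------------------------------------------
  written <- character(0)
  gen <- stage("simulate", {
    orth <- simulate_ortholog_set(
      n_groups = sim$n_groups, archetype_sd = sim$archetype_sd,
      species = species, reference = reference,
      ref_length = sim$ref_length, idr_length = sim$idr_length,
      indel_rate = sim$indel_rate, seed = seed)
    planted <- plant_cbrs(orth$sequences, orth$orthologs, species,
                          types = sim$cbr_types, prob = sim$cbr_prob,
                          mode = sim$cbr_mode,
                          threshold = cfg$cast_threshold,
                          alignments = orth$alignments, seed = seed + 1L)
    orth$sequences <- planted$sequences
    orth$alignments <- planted$alignments
    ## planted dense module: reference proteins of the first archetype
    ref_ids <- orth$orthologs$protein_id[orth$orthologs$species_id == reference]
    arch1 <- orth$groups$group_id[orth$groups$archetype ==
                                  orth$groups$archetype[1L]]
    mod_ids <- paste(arch1, reference, sep = "_")
    mod_ids <- mod_ids[seq_len(min(sim$ppi$module_size, length(mod_ids)))]
    ppi <- simulate_ppi(edge_prob = sim$ppi$edge_prob,
                        module_prob = sim$ppi$module_prob,
                        node_ids = ref_ids, module_ids = mod_ids,
                        seed = seed + 2L)
    ## write inputs
    for (sp in species) {
      pids <- orth$orthologs$protein_id[orth$orthologs$species_id == sp]
      write_fasta(orth$sequences[pids], file.path(in_dir, paste0(sp, ".fasta")))
      write_score_track(orth$tracks[pids],
                        file.path(in_dir, paste0(sp, "_scores.tsv")))
      written <- c(written, file.path(in_dir, paste0(sp, ".fasta")),
                   file.path(in_dir, paste0(sp, "_scores.tsv")))
    }
    for (gid in names(orth$alignments)) {
      write_fasta(stats::setNames(orth$alignments[[gid]],
                                  paste(gid, species, sep = "_")),
                  file.path(msa_dir, paste0(gid, ".fasta")))
    }
    write_ortholog_table(orth$orthologs, file.path(in_dir, "orthologs.tsv"))
    write_edge_list(ppi$network, file.path(in_dir, "ppi_edges.tsv"))
    writeLines(ppi$background, file.path(in_dir, "ppi_background.txt"))
    .write_tsv(orth$groups, file.path(tr_dir, "archetypes.tsv"))
    .write_tsv(orth$truth, file.path(tr_dir, "jaccard_truth.tsv"))
    .write_tsv(planted$truth, file.path(tr_dir, "cbr_truth.tsv"))
    writeLines(ppi$module, file.path(tr_dir, "module.txt"))
    list(orth = orth, ppi = ppi)
  })
  orth <- gen$orth

  ## ---- annotate ------------------------------------------------------
  masks_by_sp <- stage("annotate", {
    out <- list()
    for (sp in species) {
      tracks <- read_score_track(file.path(in_dir, paste0(sp, "_scores.tsv")))
      seqs <- read_fasta(file.path(in_dir, paste0(sp, ".fasta")))
      bad <- names(tracks)[vapply(names(tracks), function(id)
        length(tracks[[id]]) != nchar(seqs[[id]]), logical(1L))]
      if (length(bad) > 0L) {
        stop("track/sequence length mismatch for: ",
             paste(bad, collapse = ", "))
      }
      out[[sp]] <- annotate_proteome(tracks, cutoff = cfg$cutoff,
                                     min_len = cfg$min_idr_length,
                                     strict = cfg$strict_cutoff)
    }
    out
  })
  all_masks <- do.call(c, unname(masks_by_sp))
  stage("annotate", {
    idrs <- idr_table(all_masks)
    .write_tsv(idrs, file.path(res_dir, "idrs.tsv"))
  })

  ## ---- summarize -----------------------------------------------------
  summaries <- stage("summarize", {
    s <- do.call(rbind, lapply(species, function(sp)
      summarize_proteome(masks_by_sp[[sp]], sp,
                         residue_counting = cfg$residue_counting)))
    .write_tsv(s, file.path(res_dir, "summaries.tsv"))
    kept <- filter_proteomes(s, min_proteins = cfg$min_proteins)
    .write_tsv(kept, file.path(res_dir, "summaries_filtered.tsv"))
    s
  })

  ## ---- cbr -----------------------------------------------------------
  cbrs <- stage("cbr", {
    all_seqs <- unlist(lapply(species, function(sp)
      read_fasta(file.path(in_dir, paste0(sp, ".fasta")))))
    cb <- detect_cbrs_proteome(all_seqs, threshold = cfg$cast_threshold)
    .write_tsv(cb, file.path(res_dir, "cbrs.tsv"))
    cb
  })

  ## ---- conserve ------------------------------------------------------
  consv <- stage("conserve", {
    if (!dir.exists(msa_dir)) stop("missing MSA directory: ", msa_dir)
    orthologs <- read_ortholog_table(file.path(in_dir, "orthologs.tsv"),
                                     species = species)
    flat_seqs <- unlist(lapply(species, function(sp)
      read_fasta(file.path(in_dir, paste0(sp, ".fasta")))))
    gids <- unique(orthologs$group_id)
    alignments <- lapply(gids, function(gid) {
      rows <- read_alignment(file.path(msa_dir, paste0(gid, ".fasta")),
                             sequences = flat_seqs)
      stats::setNames(rows, sub(paste0("^", gid, "_"), "", names(rows)))
    })
    names(alignments) <- gids
    flags <- lapply(all_masks, function(m) m$flags)
    cm <- build_conservation_matrix(alignments, flags, orthologs,
                                    reference = reference, species = species)
    .write_tsv(data.frame(group_id = rownames(cm$jaccard), cm$jaccard,
                          check.names = FALSE),
               file.path(res_dir, "conservation.tsv"))
    .write_tsv(data.frame(group_id = rownames(cm$identity), cm$identity,
                          check.names = FALSE),
               file.path(res_dir, "identity.tsv"))
    .write_tsv(data.frame(species_id = names(cm$identity_correlation),
                          r = unname(cm$identity_correlation)),
               file.path(res_dir, "identity_correlation.tsv"))
    cm
  })

  ## ---- cluster -------------------------------------------------------
  assignment <- stage("cluster", {
    k <- min(cfg$n_clusters, nrow(consv$jaccard))
    a <- cluster_rows(consv, k = k)
    .write_tsv(data.frame(group_id = names(a$labels),
                          cluster = unname(a$labels)),
               file.path(res_dir, "clusters.tsv"))
    idp_status <- do.call(cbind, lapply(species, function(sp) {
      pid <- stats::setNames(orth$orthologs$protein_id,
                             paste(orth$orthologs$group_id,
                                   orth$orthologs$species_id))
      vapply(rownames(consv$jaccard), function(gid)
        all_masks[[pid[[paste(gid, sp)]]]]$is_idp, logical(1L))
    }))
    colnames(idp_status) <- species
    prof <- cluster_disorder_profile(a, idp_status)
    .write_tsv(data.frame(cluster = rownames(prof), prof, check.names = FALSE),
               file.path(res_dir, "cluster_profiles.tsv"))
    a
  })

  ## ---- enrich-ppi ----------------------------------------------------
  stage("enrich-ppi", {
    net <- read_edge_list(file.path(in_dir, "ppi_edges.tsv"))
    background <- readLines(file.path(in_dir, "ppi_background.txt"))
    sets <- split(paste(names(assignment$labels), reference, sep = "_"),
                  assignment$labels)
    enr <- ppi_enrichment(net, sets, background,
                          n_samples = cfg$ppi_samples, seed = seed + 3L)
    .write_tsv(enr, file.path(res_dir, "enrichment.tsv"))
  })

  ## ---- patterns ------------------------------------------------------
  stage("patterns", {
    pats <- encode_patterns(cbrs, orth$orthologs, species)
    tab <- pattern_table(pats)
    .write_tsv(tab, file.path(res_dir, "patterns.tsv"))
    .write_tsv(pattern_marginal(tab), file.path(res_dir, "patterns_marginal.tsv"))
  })

  ## ---- manifest ------------------------------------------------------
  files <- sort(c(list.files(in_dir, recursive = TRUE, full.names = TRUE),
                  list.files(tr_dir, recursive = TRUE, full.names = TRUE),
                  list.files(res_dir, recursive = TRUE, full.names = TRUE)))
  rel <- sub(paste0("^", gsub("([.\\\\|()^$*+?{}\\[\\]])", "\\\\\\1", out_dir),
                    "/?"), "", files)
  manifest <- list(
    tool = paste("disevo", as.character(utils::packageVersion("disevo"))),
    seed = cfg$seed,
    config = unclass(cfg),
    files = lapply(seq_along(files), function(i) {
      list(path = rel[i],
           md5 = unname(tools::md5sum(files[i])),
           lines = length(readLines(files[i], warn = FALSE)))
    })
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
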