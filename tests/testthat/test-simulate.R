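test_that("planted IDP fractions are recovered at the boundary values", {
  p0 <- simulate_proteome(n_proteins = 50, idp_fraction = 0, seed = 1)
  m0 <- annotate_proteome(p0$tracks)
  expect_equal(summarize_proteome(m0, "s")$idp_fraction, 0)

  p1 <- simulate_proteome(n_proteins = 50, idp_fraction = 1, seed = 2)
  m1 <- annotate_proteome(p1$tracks)
  expect_equal(summarize_proteome(m1, "s")$idp_fraction, 1)

  expect_error(simulate_proteome(10, 0.5, length_range = c(20, 40),
                                 idr_length_range = c(30, 60)),
               "exceeds minimum protein length")
})

test_that("recovered IDP fraction sits within the binomial bound", {
  q <- 0.3; n <- 1000
  p <- simulate_proteome(n_proteins = n, idp_fraction = q, seed = 33)
  m <- annotate_proteome(p$tracks)
  s <- summarize_proteome(m, "s")
  expect_lt(abs(s$idp_fraction - q), 3 * sqrt(q * (1 - q) / n))
  # the generator's own truth matches the annotation exactly
  called <- vapply(m, `[[`, logical(1), "is_idp")
  expect_equal(unname(called[p$truth$protein_id]), p$truth$is_idp)
})

test_that("generated files pass every reader without warnings", {
  dir <- withr::local_tempdir()
  o <- simulate_ortholog_set(n_groups = 6, ref_length = 220,
                             idr_length = 60, seed = 5)
  sp <- o$species
  expect_no_warning({
    write_fasta(o$sequences, file.path(dir, "all.fasta"))
    seqs <- read_fasta(file.path(dir, "all.fasta"))
    write_score_track(o$tracks, file.path(dir, "scores.tsv"))
    tracks <- read_score_track(file.path(dir, "scores.tsv"))
    write_ortholog_table(o$orthologs, file.path(dir, "orth.tsv"))
    orth <- read_ortholog_table(file.path(dir, "orth.tsv"), species = sp)
    for (gid in names(o$alignments)) {
      write_fasta(o$alignments[[gid]], file.path(dir, "aln.fasta"))
      rows <- read_alignment(file.path(dir, "aln.fasta"))
    }
    g <- simulate_ppi(n_nodes = 50, edge_prob = 0.1, module_size = 5,
                      seed = 6)
    write_edge_list(g$network, file.path(dir, "edges.tsv"))
    net <- read_edge_list(file.path(dir, "edges.tsv"))
  })
  expect_identical(seqs, o$sequences)
  expect_equal(length(tracks), length(o$tracks))
  expect_equal(attr(orth, "incomplete_groups"), character(0))
})

test_that("ortholog generator hits archetype targets and keeps rows consistent", {
  o <- simulate_ortholog_set(n_groups = 50,
                             archetypes = rbind(c(0.9, 0.9, 0.5, 0.2)),
                             archetype_sd = 0.05,
                             ref_length = 300, idr_length = 120, seed = 77)
  # degapped alignment rows equal the member sequences
  for (gid in names(o$alignments)[1:10]) {
    for (s in names(o$alignments[[gid]])) {
      expect_identical(gsub("-", "", o$alignments[[gid]][[s]], fixed = TRUE),
                       unname(o$group_sequences[[gid]][[s]]))
    }
  }
  # mean realised Jaccard per species within 0.05 of the archetype target
  agg <- tapply(o$truth$realized_jaccard, o$truth$species_id, mean)
  expect_lt(abs(agg[["mouse"]] - 0.9), 0.05)
  expect_lt(abs(agg[["fish"]] - 0.9), 0.05)
  expect_lt(abs(agg[["fly"]] - 0.5), 0.05)
  expect_lt(abs(agg[["yeast"]] - 0.2), 0.05)

  # archetype extremes are exact with zero noise
  hi <- simulate_ortholog_set(n_groups = 4,
                              archetypes = rbind(c(1, 1, 1, 1)),
                              archetype_sd = 0, ref_length = 300,
                              idr_length = 120, indel_rate = 0, seed = 8)
  expect_true(all(hi$truth$realized_jaccard == 1))
  expect_error(simulate_ortholog_set(n_groups = 4,
                                     archetypes = rbind(c(1.2, 1, 1, 1))),
               "\\[0, 1\\]")
  expect_error(simulate_ortholog_set(n_groups = 4, ref_length = 100,
                                     idr_length = 60),
               "too short")
})

test_that("near-disjoint archetypes produce near-zero measured Jaccard", {
  o <- simulate_ortholog_set(n_groups = 4,
                             archetypes = rbind(c(0.02, 0.02, 0.02, 0.02)),
                             archetype_sd = 0, ref_length = 300,
                             idr_length = 120, indel_rate = 0, seed = 12)
  masks <- annotate_proteome(o$tracks)
  cm <- build_conservation_matrix(o$alignments,
                                  lapply(masks, `[[`, "flags"),
                                  o$orthologs)
  expect_true(all(cm$jaccard < 0.05))
})

test_that("CBR planting respects presence probabilities and stays detectable", {
  sp <- default_species()$species_id
  orth <- do.call(rbind, lapply(1:20, function(g)
    data.frame(group_id = sprintf("g%02d", g), species_id = sp,
               protein_id = sprintf("g%02d_%s", g, sp))))
  seqs <- setNames(vapply(orth$protein_id, function(p) random_aa_string(60),
                          character(1)), orth$protein_id)

  all_in <- plant_cbrs(seqs, orth, sp, types = "Q", prob = 1, seed = 3)
  pats <- encode_patterns(all_in$truth[c("protein_id", "bias_type")],
                          orth, sp)
  expect_true(all(pats$pattern == "11111"))

  none <- plant_cbrs(seqs, orth, sp, types = "Q", prob = 0, seed = 3)
  expect_equal(nrow(none$truth), 0L)

  # every planted segment is detected as a CBR of its type
  with_q <- plant_cbrs(seqs, orth, sp, types = c("Q", "A"), prob = 0.5,
                       seed = 4)
  for (r in seq_len(nrow(with_q$truth))) {
    tr <- with_q$truth[r, ]
    hits <- detect_cbrs(with_q$sequences[[tr$protein_id]],
                        types = tr$bias_type)
    expect_gte(nrow(hits), 1L)
  }
  expect_error(plant_cbrs(setNames("MKT", "g01_human"), orth[1, ], "human",
                          insert_length = 12),
               "longer than host")
})

test_that("planting into aligned groups keeps alignments consistent", {
  o <- simulate_ortholog_set(n_groups = 8, ref_length = 220,
                             idr_length = 60, seed = 21)
  planted <- plant_cbrs(o$sequences, o$orthologs, o$species, types = "Q",
                        prob = 0.7, alignments = o$alignments, seed = 22)
  for (gid in names(planted$alignments)) {
    for (s in names(planted$alignments[[gid]])) {
      pid <- paste(gid, s, sep = "_")
      expect_identical(
        gsub("-", "", planted$alignments[[gid]][[s]], fixed = TRUE),
        unname(planted$sequences[[pid]]))
    }
  }
})

test_that("PPI generator plants exact modules and calibrated backgrounds", {
  g <- simulate_ppi(n_nodes = 30, edge_prob = 0, module_size = 5,
                    module_prob = 1, seed = 14)
  expect_equal(nrow(g$network$edges), 10L)   # complete graph on 5
  expect_equal(count_internal_edges(g$network, g$module), 10L)

  g1 <- simulate_ppi(n_nodes = 30, edge_prob = 0, module_size = 1,
                     module_prob = 1, seed = 15)
  expect_equal(nrow(g1$network$edges), 0L)

  n <- 984; p <- 0.005
  g2 <- simulate_ppi(n_nodes = n, edge_prob = p, module_size = 0, seed = 16)
  npairs <- n * (n - 1) / 2
  expect_lt(abs(nrow(g2$network$edges) - p * npairs),
            3 * sqrt(npairs * p * (1 - p)))
  expect_error(simulate_ppi(n_nodes = 10, module_size = 11), "exceeds")
})

test_that("the generator is byte-reproducible under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    o <- simulate_ortholog_set(n_groups = 5, ref_length = 220,
                               idr_length = 60, seed = 123)
    write_fasta(o$sequences, file.path(d, "seqs.fasta"))
    write_score_track(o$tracks, file.path(d, "scores.tsv"))
  }
  expect_identical(readLines(file.path(d1, "seqs.fasta")),
                   readLines(file.path(d2, "seqs.fasta")))
  expect_identical(readLines(file.path(d1, "scores.tsv")),
                   readLines(file.path(d2, "scores.tsv")))
})

test_that("taxon panels plant a disorder-complexity gradient", {
  pan <- simulate_taxon_panel(n_species = 6, n_proteins = 150, seed = 31)
  summaries <- do.call(rbind, lapply(names(pan$proteomes), function(s)
    summarize_proteome(annotate_proteome(pan$proteomes[[s]]$tracks), s)))
  got <- correlate_disorder_with_celltypes(summaries, pan$species_table)
  expect_gt(got$r_idp, 0.8)
})
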