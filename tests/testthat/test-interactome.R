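test_that("gene mapping picks the longest canonical accession", {
  proteins <- tibble::tibble(accession = c("P1", "P2", "P3"),
                             sequence = c(strrep("A", 100), strrep("A", 250),
                                          strrep("A", 50)))
  id_map <- tibble::tibble(gene = c("g1", "g1", "g2"),
                           accession = c("P1", "P2", "P3"))
  expect_warning(
    mapped <- map_gene_to_protein(c("g1", "g2", "g3"), id_map, proteins),
    "dropped")
  expect_identical(mapped$accession[mapped$gene == "g1"], "P2")
  expect_identical(mapped$accession[mapped$gene == "g2"], "P3")
  expect_false("g3" %in% mapped$gene)
})

test_that("reference-edge filtering applies type, evidence and self-edge rules", {
  proteins <- tibble::tibble(accession = c("P1", "P2", "P3"),
                             sequence = strrep("A", 50))
  edges <- tibble::tibble(
    acc_a = c("P1", "P1", "P1", "P2", "P1"),
    acc_b = c("P2", "P2", "P1", "P3", "P9"),
    interaction_type = c("direct", "direct", "direct", "colocalization",
                         "association"),
    evidence_count = c(1, 2, 5, 9, 4))
  kept <- filter_reference_edges(edges, proteins, dialect = "intact")
  # single-evidence edge, self-edge, non-physical type, non-canonical
  # endpoint all excluded
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$acc_a, "P1")
  expect_identical(kept$acc_b, "P2")

  # screening dialect keeps canonical non-self pairs as-is
  hi <- filter_reference_edges(tibble::tibble(acc_a = c("P2", "P3"),
                                              acc_b = c("P1", "P3")),
                               proteins, dialect = "hi_union")
  expect_identical(hi, tibble::tibble(acc_a = "P1", acc_b = "P2"))
})

test_that("alignment filtering keeps the smallest E-value below threshold", {
  hits <- tibble::tibble(
    qacc = c("P1", "P1", "P1", "P2"),
    structure_id = c("1abc", "1abc", "1abc", "1abc"),
    chain = c("A", "A", "B", "A"),
    evalue = c(1e-8, 1e-10, 1e-4, 1e-20),
    bitscore = c(60, 55, 80, 90),
    qstart = 1L, qend = 10L, sstart = 1L, send = 10L,
    qseq = "AAAAAAAAAA", sseq = "AAAAAAAAAA")
  out <- filter_alignments(hits)
  expect_identical(nrow(out), 2L)                       # 1e-4 hit removed
  expect_identical(out$evalue[out$qacc == "P1"], 1e-10) # smallest kept
  expect_identical(nrow(filter_alignments(hits[0, ])), 0L)
})

test_that("interface detection matches the brute-force oracle and is monotone", {
  set.seed(77)
  for (rep in 1:8) {
    a <- random_chain_atoms(12, "A", spread = 15)
    b <- random_chain_atoms(12, "B", spread = 15)
    b$x <- b$x + runif(1, 0, 10)
    got <- compute_interfacial_residues(a, b, cutoff = 5)
    want <- brute_force_interface(a, b, cutoff = 5)
    expect_identical(got, want)
    # monotone in the cutoff
    wider <- compute_interfacial_residues(a, b, cutoff = 7)
    expect_true(all(got$a %in% wider$a))
    expect_true(all(got$b %in% wider$b))
  }
  # far-apart chains and boundary-inside-cutoff single pair
  a1 <- tibble::tibble(resno = 1L, x = 0, y = 0, z = 0)
  b1 <- tibble::tibble(resno = 7L, x = 4.9, y = 0, z = 0)
  expect_identical(compute_interfacial_residues(a1, b1), list(a = 1L, b = 7L))
  b2 <- tibble::tibble(resno = 7L, x = 100, y = 0, z = 0)
  expect_identical(compute_interfacial_residues(a1, b2),
                   list(a = integer(0), b = integer(0)))
  expect_identical(compute_interfacial_residues(a1[0, ], b1),
                   list(a = integer(0), b = integer(0)))
})

test_that("template selection honours filters, ranking, and tie-breaks", {
  cand <- tibble::tibble(
    structure_id = c("s1", "s2", "s3", "s4"),
    chain_a = "A", chain_b = "B",
    resolution = c(4.0, 2.0, 2.0, 2.0),
    bitscore_a = c(200, 30, 60, 80),
    bitscore_b = c(200, 70, 60, 80),
    n_iface = c(50, 40, 12, 20))
  # 4.0 A excluded by resolution, s2 excluded by one-sided bitscore < 50
  sel <- select_template(cand)
  expect_identical(sel$structure_id, "s4")
  # bitscore tie: larger interface preferred
  cand2 <- cand[3:4, ]
  cand2$bitscore_a <- c(80, 80); cand2$bitscore_b <- c(80, 80)
  expect_identical(select_template(cand2)$structure_id, "s4")
  cand2$n_iface <- c(20, 20)
  expect_identical(select_template(cand2)$structure_id, "s3") # lexicographic
  # missing resolution excluded by default, kept on request
  cand3 <- cand[4, ]; cand3$resolution <- NA_real_
  expect_identical(nrow(select_template(cand3)), 0L)
  expect_identical(nrow(select_template(cand3,
                                        keep_missing_resolution = TRUE)), 1L)
  # selection is a pure ranking: dropping a non-selected candidate never
  # changes the outcome
  full <- select_template(cand)
  for (i in seq_len(nrow(cand))) {
    if (cand$structure_id[i] == full$structure_id) next
    expect_identical(select_template(cand[-i, ])$structure_id,
                     full$structure_id)
  }
})

test_that("position maps and threading follow the aligned strings", {
  pm <- alignment_position_map("AC-DEF", "ACWD-F", qstart = 5, sstart = 11)
  expect_identical(pm$qpos, c(5L, 6L, 7L, 9L))
  expect_identical(pm$spos, c(11L, 12L, 14L, 15L))
  expect_true(all(diff(pm$qpos) > 0) && all(diff(pm$spos) > 0))

  # gap-opposed and coordinate-less template positions are unmodeled
  model <- thread_model(pm, chain_resnos = c(11L, 12L, 15L))
  expect_identical(model$position, c(5L, 6L, 9L))
  expect_identical(nrow(thread_model(pm, integer(0))), 0L)

  # identity alignment over a fully resolved template models everything;
  # hand count of r on a 12-residue toy
  pm2 <- alignment_position_map(strrep("A", 12), strrep("A", 12))
  model2 <- thread_model(pm2, 1:10)
  expect_identical(nrow(model2), 10L)
  expect_identical(nrow(model2) / 12, 10 / 12)
})

test_that("structural interactome assembly annotates and threads the synthetic study", {
  study <- tiny_study(seed = 1)
  si <- build_structural_interactome(
    edges = study$ppis[, c("ppi_id", "acc_a", "acc_b")],
    proteins = study$proteome$canonical,
    alignments = study$alignments,
    atoms = study$dimers$atoms,
    structures = study$dimers$structures)

  # SI is a subgraph of the reference edge list
  expect_true(all(si$ppis$ppi_id %in% study$ppis$ppi_id))
  expect_identical(nrow(si$ppis), nrow(study$ppis))

  # identity alignments: interfaces in protein coordinates equal the
  # detector's chain-coordinate output
  expect_identical(
    si$interfaces |> dplyr::arrange(ppi_id, accession, position),
    study$interfaces |> dplyr::arrange(ppi_id, accession, position))

  # fully modeled: model length equals protein length
  lens <- setNames(study$proteome$canonical$length,
                   study$proteome$canonical$accession)
  expect_identical(si$ppis$model_len_a, unname(lens[si$ppis$acc_a]))

  # resolution above threshold drops every candidate
  si_none <- build_structural_interactome(
    edges = study$ppis[, c("ppi_id", "acc_a", "acc_b")],
    proteins = study$proteome$canonical,
    alignments = study$alignments,
    atoms = study$dimers$atoms,
    structures = study$dimers$structures |> dplyr::mutate(resolution = 4.0))
  expect_identical(nrow(si_none$ppis), 0L)
})

test_that("structural proteome covers a superset of SI proteins and obeys tie rules", {
  study <- tiny_study(seed = 1)
  sp <- build_structural_proteome(
    proteins = study$proteome$canonical,
    alignments = study$alignments,
    atoms = study$dimers$atoms,
    structures = study$dimers$structures)
  si_proteins <- unique(c(study$ppis$acc_a, study$ppis$acc_b))
  expect_true(all(si_proteins %in% sp$proteins$accession))

  # chosen template maximises bitscore among passers (exhaustive check)
  hits <- filter_alignments(study$alignments)
  for (i in seq_len(nrow(sp$proteins))) {
    acc <- sp$proteins$accession[i]
    best <- max(hits$bitscore[hits$qacc == acc])
    chosen <- hits$bitscore[hits$qacc == acc &
                              hits$structure_id == sp$proteins$structure_id[i] &
                              hits$chain == sp$proteins$chain[i]]
    expect_identical(chosen, best)
  }

  # equal bitscores: first in input order wins
  aln <- tibble::tibble(
    qacc = "P1", structure_id = c("zz", "aa"), chain = "A",
    evalue = 1e-20, bitscore = 99, qstart = 1L, qend = 8L,
    sstart = 1L, send = 8L, qseq = "AAAAAAAA", sseq = "AAAAAAAA")
  atoms <- tibble::tibble(structure_id = rep(c("zz", "aa"), each = 8),
                          chain = "A", resno = rep(1:8, 2),
                          resname = "ALA", elety = "CA", elem = "C",
                          x = rep(3.8 * (1:8), 2), y = 0, z = 0)
  sp2 <- build_structural_proteome(
    proteins = tibble::tibble(accession = "P1", sequence = "AAAAAAAA"),
    alignments = aln, atoms = atoms,
    structures = tibble::tibble(structure_id = c("zz", "aa"),
                                resolution = 2))
  expect_identical(sp2$proteins$structure_id, "zz")
})
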