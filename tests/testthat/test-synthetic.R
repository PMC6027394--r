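test_that("default scenario bookkeeping matches its parameters", {
  sc <- synthetic_scenario()
  expect_equal(sc$n_regulons * sc$operons_per_regulon +
                 sc$background_operons, 300L)
  gen <- generate_synthetic(synthetic_scenario(
    rng_seed = 2, n_regulons = 4, operons_per_regulon = 6,
    background_operons = 10, genome_length = 40000))
  expect_equal(nrow(gen$operons), 34L)
  expect_length(gen$truth$regulons, 4L)
  members <- unlist(purrr::map(gen$truth$regulons, "member_operons"))
  expect_equal(length(members), 24L)
  expect_equal(anyDuplicated(members), 0L)
  expect_setequal(c(members, gen$truth$background_operons),
                  gen$operons$operon_id)
  # every planted PWM is column-stochastic at the requested IC
  for (tr in gen$truth$regulons) {
    expect_equal(colSums(tr$pwm), rep(1, 12), tolerance = 1e-9,
                 ignore_attr = TRUE)
    percol <- 2 + colSums(ifelse(tr$pwm > 0, tr$pwm * log2(tr$pwm), 0))
    expect_equal(percol, rep(1.5, 12), tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("site_rate 1 and de_regulon_fraction 1 saturate their features", {
  gen <- generate_synthetic(synthetic_scenario(
    rng_seed = 3, n_regulons = 3, operons_per_regulon = 5,
    background_operons = 5, genome_length = 30000,
    site_rate = 1, de_regulon_fraction = 1))
  for (tr in gen$truth$regulons) {
    expect_true(tr$de)
    expect_equal(sort(tr$sites$operon_id), sort(tr$member_operons))
  }
  dirs <- gen$truth$true_direction
  member_genes <- regulonr:::operon_gene_map(gen$operons) |>
    dplyr::filter(.data$operon_id %in%
                    unlist(purrr::map(gen$truth$regulons, "member_operons")))
  expect_true(all(dirs$direction[dirs$gene_id %in%
                                   member_genes$locus_tag] == "up"))
})

test_that("planted sites really are in the promoters where claimed", {
  gen <- generate_synthetic(synthetic_scenario(
    rng_seed = 6, n_regulons = 2, operons_per_regulon = 6,
    background_operons = 4, genome_length = 30000))
  proms <- extract_promoters(gen$operons, gen$genome, 300)
  for (tr in gen$truth$regulons) {
    s <- tr$sites
    for (j in seq_len(nrow(s))) {
      prom <- proms$sequence[proms$operon_id == s$operon_id[j]]
      frag <- substr(prom, s$offset[j] + 1, s$offset[j] + 12)
      want <- if (s$strand[j] == "fwd") s$site[j] else revcomp(s$site[j])
      expect_equal(frag, want,
                   label = paste("site", tr$regulon, s$operon_id[j]))
    }
  }
})

test_that("generation is deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sc <- synthetic_scenario(rng_seed = 9, n_regulons = 2,
                           operons_per_regulon = 4, background_operons = 4,
                           genome_length = 20000)
  generate_synthetic(sc, dir = d1)
  generate_synthetic(sc, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  generate_synthetic(synthetic_scenario(
    rng_seed = 10, n_regulons = 2, operons_per_regulon = 4,
    background_operons = 4, genome_length = 20000), dir = d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("generated files round-trip through the package readers", {
  d <- withr::local_tempdir()
  gen <- generate_synthetic(synthetic_scenario(
    rng_seed = 14, n_regulons = 2, operons_per_regulon = 4,
    background_operons = 4, genome_length = 20000), dir = d)
  g <- read_genome(file.path(d, "genome.fa"))
  expect_identical(g$sequence, gen$genome$sequence)
  ops <- read_operons(file.path(d, "operons.tsv"), g)
  expect_equal(ops$operon_id, gen$operons$operon_id)
  expect_equal(ops$first_start, gen$operons$first_start)
  expr <- read_expression(file.path(d, "expression.tsv"),
                          file.path(d, "design.tsv"), ops)
  expect_equal(expr$values, gen$expr$values, tolerance = 1e-12)
  expect_true(all(expr$genes$in_operons))
  lib <- read_motifs_meme(file.path(d, "tfbs_library.meme"))
  expect_equal(nrow(lib), nrow(gen$tfbs_library))
  expect_lt(max(abs(lib$pwm[[1]] - gen$tfbs_library$pwm[[1]])), 1e-6)
})

test_that("operons refuse to overflow the genome", {
  expect_error(generate_synthetic(synthetic_scenario(
    rng_seed = 1, genome_length = 5000)), "increase genome_length")
})

test_that("recovery scoring handles perfect, empty and random partitions", {
  gen <- generate_synthetic(synthetic_scenario(
    rng_seed = 20, n_regulons = 3, operons_per_regulon = 5,
    background_operons = 5, genome_length = 30000))
  truth <- gen$truth
  perfect <- tibble::tibble(
    regulon_id = 1:3, tier = "highly_reliable",
    motif_ids = purrr::map(1:3, ~ character()),
    operon_ids = purrr::map(truth$regulons, "member_operons"),
    gene_ids = purrr::map(1:3, ~ character()),
    source_cems = purrr::map(1:3, ~ character()),
    n_operons = 5L, n_genes = 0L,
    t1_children = purrr::map(1:3, ~ integer()))
  class(perfect) <- c("regulon_set", class(perfect))
  ev <- evaluate_recovery(truth, perfect)
  expect_equal(ev$per_regulon$jaccard, rep(1, 3))
  expect_equal(ev$recovered_fraction, 1)

  none <- evaluate_recovery(truth, perfect[0, ])
  expect_equal(none$recovered_fraction, 0)

  # random partition: jaccard equals a brute-force set computation
  set.seed(20)
  shuffled <- split(sample(gen$operons$operon_id),
                    rep(1:3, length.out = nrow(gen$operons)))
  random <- dplyr::mutate(perfect,
                          operon_ids = unname(shuffled),
                          n_operons = lengths(shuffled))
  ev_r <- evaluate_recovery(truth, random)
  for (r in 1:3) {
    true_ops <- truth$regulons[[r]]$member_operons
    brute <- max(purrr::map_dbl(shuffled, function(ops)
      length(intersect(ops, true_ops)) / length(union(ops, true_ops))))
    expect_equal(ev_r$per_regulon$jaccard[r], brute)
  }
})

test_that("consensus distance is shift- and strand-aware", {
  expect_equal(consensus_distance("ACGTACGTACGT", "ACGTACGTACGT"), 0L)
  expect_equal(consensus_distance("ACGTACGTACGT",
                                  revcomp("ACGTACGTACGT")), 0L)
  expect_equal(consensus_distance("AAAAAAAAAAAA", "AAAAAAAAAAAT"), 1L)
  # shift by one costs one plus any overlap mismatches
  expect_equal(consensus_distance("ACGTACGTACGT", "CGTACGTACGTA"), 1L)
})
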