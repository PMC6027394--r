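mk_regulon_set <- function(ids, motif_ids, gene_ids) {
  out <- tibble::tibble(
    regulon_id = ids, tier = "highly_reliable",
    motif_ids = motif_ids, operon_ids = purrr::map(gene_ids, ~ .x),
    gene_ids = gene_ids, source_cems = purrr::map(ids, ~ "C1"),
    n_operons = lengths(gene_ids), n_genes = lengths(gene_ids),
    t1_children = purrr::map(ids, ~ integer()))
  class(out) <- c("regulon_set", class(out))
  out
}

test_that("a library-identical motif is matched with minimal E-value", {
  set.seed(61)
  pwm <- regulonr:::sample_planted_pwm(12, 1.5)
  motifs <- tibble::tibble(motif_id = "m1", cem_id = "C1", pwm = list(pwm),
                           sites = list(tibble::tibble(operon_id = "o1")))
  regs <- mk_regulon_set(1L, list("m1"), list("g1"))
  library_tab <- tibble::tibble(
    motif_id = c("L1", "L2"), tf_name = c("tfX", "tfY"),
    organism = "synthetic",
    pwm = list(pwm, regulonr:::sample_planted_pwm(12, 1.5)))
  hits <- match_tfbs(regs, motifs, library_tab, regulon_config())
  expect_gte(nrow(hits), 1L)
  best <- hits[1, ]
  expect_equal(best$library_motif_id, "L1")
  expect_equal(best$similarity, 1)
  expect_equal(best$p_value, 1 / 1001)
  expect_equal(best$e_value, 2 / 1001)

  expect_warning(none <- match_tfbs(regs, motifs, library_tab[0, ],
                                    regulon_config()), "empty")
  expect_equal(nrow(none), 0L)
})

test_that("random libraries produce few shuffle-null matches", {
  set.seed(67)
  reports <- 0L
  n_rep <- 10L
  lib <- tibble::tibble(
    motif_id = sprintf("L%02d", 1:20), tf_name = sprintf("tf%02d", 1:20),
    organism = "synthetic",
    pwm = purrr::map(1:20, ~ regulonr:::sample_planted_pwm(12, 1.5)))
  for (rep in seq_len(n_rep)) {
    pwm <- regulonr:::sample_planted_pwm(12, 1.5)
    motifs <- tibble::tibble(motif_id = "m1", cem_id = "C1",
                             pwm = list(pwm),
                             sites = list(tibble::tibble(operon_id = "o1")))
    regs <- mk_regulon_set(1L, list("m1"), list("g1"))
    cfg <- regulon_config(rng_seed = rep)
    reports <- reports + nrow(match_tfbs(regs, motifs, lib, cfg))
  }
  # 200 pairs, each reportable only when p < 0.0025 (E = p * 20 < 0.05):
  # expected reports ~ 0.5; 3 is far beyond 3 binomial SDs
  expect_lte(reports, 3L)
})

test_that("protein mapping finds self and rejects shuffles", {
  set.seed(71)
  prot <- stats::setNames(
    vapply(1:30, function(i) regulonr:::random_protein(150), character(1)),
    sprintf("p%02d", 1:30))
  hit <- map_tf("tpl", prot[["p07"]], prot, evalue_max = 1e-10)
  expect_equal(hit$target_gene, "p07")
  expect_lt(hit$e_value, 1e-10)

  shuffled <- paste(sample(strsplit(prot[["p07"]], "")[[1]]), collapse = "")
  miss <- map_tf("shuf", shuffled, prot, evalue_max = 1e-10)
  expect_equal(nrow(miss), 0L)

  # diverged ortholog still maps, and two templates may share a target
  tpl <- tibble::tibble(
    name = c("a", "b"),
    sequence = c(regulonr:::mutate_protein(prot[["p03"]], 0.2),
                 regulonr:::mutate_protein(prot[["p03"]], 0.2)))
  hits <- map_tfs(tpl, prot)
  expect_equal(hits$target_gene, c("p03", "p03"))
})

test_that("tabular alignment adapter substitutes for the built-in scan", {
  tab <- tibble::tibble(
    query = c("tpl", "tpl", "other"), subject = c("gA", "gB", "gC"),
    identity = 90, length = 100, mismatches = 10, gap_opens = 0,
    qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = c(1e-30, 1e-5, 1e-40), bitscore = c(200, 50, 300))
  hit <- map_tf("tpl", "IRRELEVANT", character(), evalue_max = 1e-10,
                alignment_table = tab)
  expect_equal(hit$target_gene, "gA")
  expect_equal(hit$e_value, 1e-30)
})

test_that("hypergeometric upper tail is exact", {
  expect_equal(hypergeom_test(0, 10, 5, 100), 1)
  expect_equal(hypergeom_test(5, 100, 5, 100), 1)  # regulon = universe
  expect_equal(hypergeom_test(5, 10, 10, 100), brute_hyper(5, 10, 10, 100),
               tolerance = 1e-12)
  expect_error(hypergeom_test(6, 5, 10, 100), "inconsistent")
  set.seed(73)
  for (i in 1:50) {
    N <- sample(2:30, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    ks <- max(0, n + K - N):min(n, K)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(hypergeom_test(k, n, K, N), brute_hyper(k, n, K, N),
                 tolerance = 1e-12, label = sprintf("N=%d K=%d n=%d k=%d",
                                                    N, K, n, k))
  }
})

test_that("the published 14-regulon table sieves to the five verified regulons", {
  tab <- regulon_tf_table()
  expect_equal(nrow(tab), 14L)
  ann <- tibble::tibble(regulon_id = tab$regulon_id,
                        has_tfbs_match = TRUE,
                        has_deg = tab$has_deg,
                        mapped_tf = tab$mapped_tf_gene)
  v <- regulon_verdicts(ann)
  verified <- sort(v$regulon_id[v$verdict == "computationally_verified"])
  expect_equal(verified, c(2L, 7L, 12L, 15L, 31L))
  sieve <- attr(v, "sieve")
  expect_equal(unname(sieve[c("deg_containing", "tf_mapped", "verified")]),
               c(10L, 8L, 5L))
  # regulon #10 has a mapped TF but no differential expression: candidate
  expect_equal(v$verdict[v$regulon_id == 10], "candidate")
  # with no DEGs at all nothing is verified
  v0 <- regulon_verdicts(dplyr::mutate(ann, has_deg = FALSE))
  expect_equal(sum(v0$verdict == "computationally_verified"), 0L)
})

test_that("literature mapping assigns genes to regulons and tolerates orphans", {
  set.seed(79)
  prot <- stats::setNames(
    vapply(1:20, function(i) regulonr:::random_protein(130), character(1)),
    sprintf("g%02d", 1:20))
  regs <- mk_regulon_set(1:2, list("m1", "m2"),
                         list(c("g01", "g02"), c("g03", "g04")))
  lit <- tibble::tibble(
    template_gene = c("litA", "litB", "litC"),
    template_organism = "other",
    functional_module = c("LDH", "LDH", "GAD"),
    sequence = c(regulonr:::mutate_protein(prot[["g01"]], 0.15),
                 regulonr:::mutate_protein(prot[["g03"]], 0.15),
                 regulonr:::random_protein(130)))
  mapped <- map_literature_genes(lit, prot, regs, 1e-10)
  expect_equal(mapped$mapped_locus_tag[1:2], c("g01", "g03"))
  expect_equal(mapped$regulons_hit[[1]], 1L)
  expect_equal(mapped$regulons_hit[[2]], 2L)
  expect_true(is.na(mapped$mapped_locus_tag[3]))
  expect_length(mapped$regulons_hit[[3]], 0L)
  empty <- map_literature_genes(lit[0, ], prot, regs)
  expect_equal(nrow(empty), 0L)
})

test_that("set comparison reproduces the published error rates and a brute oracle", {
  all_ids <- 1:51
  significant <- regulon_tf_table()$regulon_id
  computational <- c(2L, 7L, 12L, 15L, 31L)
  literature <- sort(unique(c(regulon_ids_for_names(
    c("llrA", "llrC", "hllA", "NHP6A")), 8L, 39L)))
  cmp <- compare_regulon_sets(computational, literature, significant, all_ids)
  expect_equal(cmp$fp_fraction, 1 / 5)
  expect_equal(cmp$fp_ids, 15L)
  expect_equal(cmp$insignificant_supported_fraction, 2 / 37)
  expect_equal(sort(cmp$insignificant_supported_ids), c(8L, 39L))

  expect_equal(compare_regulon_sets(1:3, 1:3, 1:5, 1:10)$fp_fraction, 0)
  expect_true(is.na(compare_regulon_sets(integer(), 1:3, 1:5,
                                         1:10)$fp_fraction))
  set.seed(83)
  for (i in 1:20) {
    comp <- sample(all_ids, sample(0:10, 1))
    lit <- sample(all_ids, sample(0:10, 1))
    sig <- sample(all_ids, 14)
    got <- compare_regulon_sets(comp, lit, sig, all_ids)
    expect_equal(got$fp_fraction,
                 if (length(comp) == 0) NA_real_ else
                   length(setdiff(comp, lit)) / length(comp))
    expect_equal(got$insignificant_supported_fraction,
                 length(intersect(lit, setdiff(all_ids, sig))) / 37)
  }
})

test_that("annotation sieve is monotone on a synthetic run", {
  gen <- generate_synthetic(synthetic_scenario(
    rng_seed = 10, n_regulons = 3, operons_per_regulon = 10,
    background_operons = 10, genome_length = 40000))
  run <- suppressMessages(suppressWarnings(run_pipeline(
    gen$genome, gen$operons, gen$expr, regulon_config(rng_seed = 10),
    tfbs_library = gen$tfbs_library, proteome = gen$proteome,
    tf_templates = gen$tf_templates)))
  sieve <- attr(run$annotated, "sieve")
  expect_true(sieve[["tfbs_matched"]] <= sieve[["total"]])
  expect_true(sieve[["deg_containing"]] <= sieve[["tfbs_matched"]])
  expect_true(sieve[["verified"]] <= sieve[["deg_containing"]])
  expect_true(sieve[["verified"]] <= sieve[["tf_mapped"]])
  expect_true(all(run$annotated$hypergeom_p >= 0 &
                    run$annotated$hypergeom_p <= 1))
})
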