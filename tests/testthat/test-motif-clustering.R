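test_that("pwm similarity is 1 for identical PWMs and symmetric", {
  set.seed(41)
  a <- regulonr:::sample_planted_pwm(12, 1.5)
  b <- regulonr:::sample_planted_pwm(12, 1.5)
  expect_equal(pwm_similarity(a, a)$similarity, 1)
  ab <- pwm_similarity(a, b)
  ba <- pwm_similarity(b, a)
  expect_equal(ab$similarity, ba$similarity, tolerance = 1e-12)
  expect_gte(ab$similarity, 0)
  expect_lte(ab$similarity, 1)
})

test_that("all-A versus all-T scores 0 forward but 1 after reverse complement", {
  a <- word_pwm(strrep("A", 12), dominant = 1)
  t <- word_pwm(strrep("T", 12), dominant = 1)
  s <- pwm_similarity(a, t)
  expect_equal(s$similarity, 1)
  expect_equal(s$orientation, "rc")
  # forward orientation alone really is 0: compare against all-C instead,
  # whose reverse complement (all-G) is equally distant
  c_ <- word_pwm(strrep("C", 12), dominant = 1)
  expect_equal(pwm_similarity(a, c_)$similarity, 0)
})

test_that("shifted PWMs find the true offset against a brute-force scan", {
  set.seed(43)
  core <- regulonr:::sample_planted_pwm(12, 2)
  shift <- 3L
  b <- cbind(matrix(0.25, 4, shift), core[, 1:(12 - shift)])
  rownames(b) <- rownames(core)
  s <- pwm_similarity(core, b)
  expect_equal(s$best_offset, -shift)

  # exhaustive offset/orientation oracle
  brute <- -Inf
  for (orient in 1:2) {
    bb <- if (orient == 2) regulonr:::revcomp_pwm(b) else b
    for (off in -6:6) {
      a_cols <- max(1, 1 + off):min(12, 12 + off)
      if (length(a_cols) < 6) next
      cs <- vapply(seq_along(a_cols), function(k)
        1 - sqrt(sum((core[, a_cols[k]] - bb[, a_cols[k] - off])^2)) /
          sqrt(2), numeric(1))
      brute <- max(brute, mean(cs))
    }
  }
  expect_equal(s$similarity, brute, tolerance = 1e-12)
  expect_error(pwm_similarity(core[, 1:5], core[, 1:5]), "6-column")
})

test_that("kruskal clustering equals thresholded connected components", {
  ids <- c("a", "b", "c", "d")
  edges <- tibble::tibble(motif_a = c("a", "b", "c"),
                          motif_b = c("b", "c", "d"),
                          similarity = c(0.9, 0.85, 0.5))
  part <- kruskal_cluster(ids, edges, 0.8)
  expect_equal(part$cluster[part$motif_id %in% c("a", "b", "c")],
               rep(part$cluster[part$motif_id == "a"], 3))
  expect_false(part$cluster[part$motif_id == "d"] %in%
                 part$cluster[part$motif_id == "a"])

  # no edge reaches the threshold -> all singletons
  lone <- kruskal_cluster(ids, edges, 0.95)
  expect_equal(length(unique(lone$cluster)), 4L)

  # complete graph at similarity 1 -> one cluster
  full <- tidyr::expand_grid(motif_a = ids, motif_b = ids) |>
    dplyr::filter(.data$motif_a < .data$motif_b) |>
    dplyr::mutate(similarity = 1)
  expect_equal(length(unique(kruskal_cluster(ids, full, 0.8)$cluster)), 1L)
})

test_that("clustering matches a brute-force component oracle on random graphs", {
  set.seed(47)
  for (rep in 1:30) {
    n <- sample(3:20, 1)
    ids <- sprintf("m%02d", seq_len(n))
    pairs <- utils::combn(n, 2)
    edges <- tibble::tibble(motif_a = ids[pairs[1, ]],
                            motif_b = ids[pairs[2, ]],
                            similarity = runif(ncol(pairs)))
    thr <- runif(1, 0.3, 0.9)
    got <- kruskal_cluster(ids, edges, thr)$cluster
    want <- brute_components(ids, edges, thr)
    # same partition up to label names
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1))
  }
})

test_that("lower thresholds coarsen the partition monotonically", {
  set.seed(53)
  n <- 25L
  ids <- sprintf("m%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  edges <- tibble::tibble(motif_a = ids[pairs[1, ]],
                          motif_b = ids[pairs[2, ]],
                          similarity = runif(ncol(pairs)))
  thresholds <- seq(0.95, 0.2, by = -0.05)
  sizes <- vapply(thresholds, function(t)
    length(unique(kruskal_cluster(ids, edges, t)$cluster)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # refinement: every T1 cluster sits inside exactly one T2 cluster
  p1 <- kruskal_cluster(ids, edges, 0.8)$cluster
  p2 <- kruskal_cluster(ids, edges, 0.6)$cluster
  expect_true(all(tapply(p2, p1, function(x) length(unique(x))) == 1))
})

test_that("regulon assembly unions operons and records tiers deterministically", {
  mk_motif <- function(id, cem, ops, pwm) tibble::tibble(
    motif_id = id, cem_id = cem, rank = 1L, consensus = "X", n_sites = length(ops),
    score = 1, p_value = 1e-9, adjusted_p = 1e-6, information_content = 10,
    pwm = list(pwm),
    sites = list(tibble::tibble(operon_id = ops, offset = 0L,
                                strand = "fwd", sequence = "")))
  pwm_a <- word_pwm("ACGTACGTACGT")
  pwm_b <- word_pwm("ACGTACGTACGA")   # 1 mismatch: very similar
  pwm_c <- word_pwm("TTTTTGGGGGCC")   # unrelated
  motifs <- dplyr::bind_rows(
    mk_motif("m1", "C1", c("o1", "o2"), pwm_a),
    mk_motif("m2", "C2", "o3", pwm_b),
    mk_motif("m3", "C3", c("o4", "o5", "o6"), pwm_c))
  class(motifs) <- c("motif_set", class(motifs))
  ops <- toy_operons(purrr::map(1:6, ~ list(
    id = paste0("o", .x), strand = "+",
    starts = 1000 * .x, ends = 1000 * .x + 50)))
  edges <- motif_similarity_edges(motifs)
  regs <- assemble_regulons(motifs, edges, ops,
                            regulon_config(t1 = 0.8, t2 = 0.3))
  t1 <- regs[regs$tier == "highly_reliable", ]
  expect_equal(nrow(t1), 2L)
  # union contract: m1+m2 cluster carries o1,o2,o3
  merged <- t1[purrr::map_lgl(t1$motif_ids, ~ "m1" %in% .x), ]
  expect_equal(merged$operon_ids[[1]], c("o1", "o2", "o3"))
  expect_equal(merged$gene_ids[[1]], c("o1_g1", "o2_g1", "o3_g1"))
  # tier-1 ids ordered by descending operon count
  expect_equal(t1$n_operons[1], max(t1$n_operons))
  # T2 merges reference their T1 children
  t2 <- regs[regs$tier == "relatively_reliable", ]
  if (nrow(t2)) {
    expect_true(all(purrr::map_int(t2$t1_children, length) >= 2))
  }
})

test_that("T1 partition refines T2 over random motif sets", {
  set.seed(59)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    ids <- sprintf("m%02d", seq_len(n))
    pairs <- utils::combn(n, 2)
    edges <- tibble::tibble(motif_a = ids[pairs[1, ]],
                            motif_b = ids[pairs[2, ]],
                            similarity = runif(ncol(pairs)))
    p1 <- kruskal_cluster(ids, edges, 0.8)$cluster
    p2 <- kruskal_cluster(ids, edges, 0.6)$cluster
    expect_true(all(tapply(p2, p1, function(x) length(unique(x))) == 1))
  }
})
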