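test_that("fixture tables produce the published network dimensions", {
  lit <- literature_gene_table()
  expect_equal(length(unique(lit$locus_tag)), 33L)
  expect_equal(length(unique(lit$functional_module)), 9L)
  reg_names <- unique(unlist(lit$regulons_hit))
  expect_equal(length(reg_names), 6L)

  tab1 <- regulon_tf_table()
  verified_rows <- tab1[tab1$has_deg & !is.na(tab1$mapped_tf_gene), ]
  verified <- tibble::tibble(regulon = unique(verified_rows$mapped_tf_gene),
                             tf_locus = verified_rows$mapped_tf_locus[
                               match(unique(verified_rows$mapped_tf_gene),
                                     verified_rows$mapped_tf_gene)])
  net <- build_grn(lit, verified = verified,
                   curation = network_curation_table())
  counts <- table(net$nodes$type)
  expect_equal(unname(counts["regulon"]), 8L)
  expect_equal(unname(counts["functional_module"]), 9L)
  expect_equal(unname(counts["gene"]), 33L)
  expect_equal(unname(counts["transmembrane_protein"]), 2L)
  expect_equal(unname(counts["sensor"]), 1L)

  # GAD and urea degradation remain orphans: no regulates edge targets them
  reg_edges <- net$edges[net$edges$type == "regulates", ]
  expect_false("GAD" %in% reg_edges$to)
  expect_false("Urea degradation" %in% reg_edges$to)

  # regulates edges equal the brute-force module-regulon incidence
  want <- lit |>
    dplyr::select("functional_module", "regulons_hit") |>
    tidyr::unnest_longer("regulons_hit") |>
    dplyr::distinct()
  got <- reg_edges[reg_edges$provenance == "literature",
                   c("from", "to")]
  expect_true(all(paste(want$regulons_hit, want$functional_module) %in%
                    paste(got$from, got$to)))
  # only the curated global-initiator edge is extra
  expect_equal(nrow(got), nrow(want) + 1L)
})

test_that("empty inputs give an empty network", {
  net <- build_grn(literature_gene_table()[0, ])
  expect_equal(nrow(net$nodes), 0L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("network validation rejects broken graphs", {
  nodes <- tibble::tibble(id = c("r1", "mod"), type = c("regulon",
                                                        "functional_module"))
  edges <- tibble::tibble(from = "r1", to = "ghost", type = "regulates",
                          provenance = "computational")
  expect_error(regulonr:::validate_grn(
    structure(list(nodes = nodes, edges = edges),
              class = "regulatory_network")), "unknown node")
  edges2 <- tibble::tibble(from = "mod", to = "r1", type = "regulates",
                           provenance = "computational")
  expect_error(regulonr:::validate_grn(
    structure(list(nodes = nodes, edges = edges2),
              class = "regulatory_network")), "non-regulatory")
})

test_that("JSON export round-trips and GraphML carries typed nodes", {
  lit <- literature_gene_table()
  net <- build_grn(lit, curation = network_curation_table())
  json <- withr::local_tempfile(fileext = ".json")
  export_network(net, json, "json")
  back <- read_network_json(json)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  xml_nodes <- xml2::xml_find_all(doc, ".//d1:node", ns)
  expect_equal(length(xml_nodes), nrow(net$nodes))
  expect_true(any(grepl("regulon", as.character(doc))))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge-tsv")
  flat <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(flat), nrow(net$edges))
  expect_true(all(c("from_type", "to_type") %in% names(flat)))

  expect_error(export_network(net, tsv, "dot"))
})

test_that("three-node toy network exports typed GraphML", {
  lit <- tibble::tibble(functional_module = "LDH", locus_tag = "g1",
                        regulons_hit = list("R1"))
  net <- build_grn(lit)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(sort(net$edges$type), c("contains", "regulates"))
  g <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, g, "graphml")
  expect_equal(length(xml2::xml_find_all(xml2::read_xml(g), ".//d1:node")),
               3L)
})

test_that("every literature-provenance edge traces to a fixture row", {
  lit <- literature_gene_table()
  net <- build_grn(lit, curation = network_curation_table())
  contains <- net$edges[net$edges$type == "contains", ]
  for (i in seq_len(nrow(contains))) {
    expect_true(any(lit$functional_module == contains$from[i] &
                      lit$locus_tag == contains$to[i]))
  }
})
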