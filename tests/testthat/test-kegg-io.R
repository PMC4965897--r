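fixture <- function(name) system.file("extdata", name, package = "ecoseed")

test_that("equation arrows map to reversibility and coefficients are stripped", {
  cases <- list(
    list(eq = "C00031 => C00022", subs = "C00031", prods = "C00022", rev = FALSE),
    list(eq = "C00022 + C00003 <=> C00024 + C00004",
         subs = c("C00003", "C00022"), prods = c("C00004", "C00024"), rev = TRUE),
    list(eq = "C00111 -> C00022", subs = "C00111", prods = "C00022", rev = FALSE),
    list(eq = "2 C00031 => C00118 + 3 C00111",
         subs = "C00031", prods = c("C00111", "C00118"), rev = FALSE),
    list(eq = "(n) C00718 => (n+1) C00369", subs = "C00718", prods = "C00369",
         rev = FALSE),
    list(eq = "C00267[c] => C00221[e]", subs = "C00267", prods = "C00221",
         rev = FALSE))
  for (cs in cases) {
    recs <- parse_reaction_flatfile(
      text = c("ENTRY       R00001  Reaction",
               paste0("EQUATION    ", cs$eq), "///"))
    expect_length(recs, 1)
    expect_equal(recs[[1]]$substrates, cs$subs, info = cs$eq)
    expect_equal(recs[[1]]$products, cs$prods, info = cs$eq)
    expect_identical(recs[[1]]$reversible, cs$rev, info = cs$eq)
  }
})

test_that("the packaged 10-entry fixture matches its hand enumeration", {
  # hand enumeration written down from the fixture file before parsing it
  manifest <- list(
    R00001 = list(s = "C00031", p = "C00022", rev = FALSE),
    R00002 = list(s = c("C00003", "C00022"), p = c("C00004", "C00024"), rev = TRUE),
    R00003 = list(s = "C00031", p = c("C00111", "C00118"), rev = FALSE),
    R00004 = list(s = "C00111", p = "C00022", rev = FALSE),
    R00005 = list(s = c("C00009", "C00024"), p = c("C00010", "C00033"), rev = TRUE),
    R00006 = list(s = "C00033", p = "C00084", rev = FALSE),
    R00007 = list(s = c("C00003", "C00084"), p = c("C00004", "C00033"), rev = TRUE),
    R00008 = list(s = "C00718", p = "C00369", rev = FALSE),
    R00009 = list(s = "C00267", p = "C00221", rev = FALSE),
    R00010 = list(s = c("C00002", "C00668"), p = c("C00008", "C05345"), rev = FALSE))
  recs <- parse_reaction_flatfile(fixture("toy_reactions.txt"))
  expect_length(recs, 10)
  for (r in recs) {
    exp <- manifest[[r$reaction_id]]
    expect_false(is.null(exp), info = r$reaction_id)
    expect_equal(r$substrates, exp$s, info = r$reaction_id)
    expect_equal(r$products, exp$p, info = r$reaction_id)
    expect_identical(r$reversible, exp$rev, info = r$reaction_id)
  }
})

test_that("malformed entries raise errors naming the entry, empty stream is empty", {
  expect_identical(parse_reaction_flatfile(text = character(0)), list())
  expect_error(parse_reaction_flatfile(
    text = c("ENTRY       R00077", "///")), "R00077.*EQUATION")
  expect_error(parse_reaction_flatfile(
    text = c("EQUATION    A => B", "///")), "missing ENTRY")
  expect_error(parse_reaction_flatfile(
    text = c("ENTRY       R00088", "EQUATION    C00001 C00002", "///")),
    "R00088.*arrow")
})

test_that("flat-format round trip preserves records (order-insensitive)", {
  set.seed(42)
  for (rep in 1:5) {
    recs <- random_reaction_set(25, 12, reversible_prob = 0.5,
                                rng_seed = 100 + rep)
    path <- withr::local_tempfile(fileext = ".txt")
    write_reaction_flatfile(recs, path)
    back <- parse_reaction_flatfile(path)
    key <- function(rs) {
      srt <- vapply(rs, function(r) paste(r$reaction_id,
                                          paste(r$substrates, collapse = ","),
                                          paste(r$products, collapse = ","),
                                          r$reversible), character(1))
      sort(srt)
    }
    expect_identical(key(back), key(recs))
  }
})

test_that("parser never emits empty substrate or product sets", {
  recs <- parse_reaction_flatfile(fixture("toy_reactions.txt"))
  for (r in recs) {
    expect_gt(length(r$substrates), 0)
    expect_gt(length(r$products), 0)
  }
  expect_error(reaction_record("RX", character(0), "C00001"), "substrates")
  expect_error(reaction_record("RX", "C00001", ""), "products")
})

test_that("records with a compound on both sides are flagged, not dropped", {
  r <- reaction_record("RX", c("C00001", "C00002"), c("C00002", "C00003"))
  expect_true(flagged(r))
  expect_warning(net <- reconstruct_network(
    list(r, reaction_record("RY", "C00001", "C00003", FALSE)), "org"),
    "flagged")
  expect_identical(network_nodes(net), c("C00001", "C00003"))
})

test_that("annotation profiles collapse duplicates and refuse missing KO column", {
  prof <- parse_annotation_profile(
    text = c("gene_id\tko_id", "g1\tK00001", "g2\tK00001"), organism_id = "o")
  expect_identical(prof$ko_terms, "K00001")
  expect_identical(prof$gene_count, 2L)

  empty <- parse_annotation_profile(text = "gene_id\tko_id", organism_id = "o")
  expect_length(empty$ko_terms, 0)
  catalogue <- parse_reaction_flatfile(fixture("toy_reactions.txt"))
  komap <- parse_ko_reaction_map(fixture("toy_ko_reaction_map.tsv"))
  expect_error(reactions_for_profile(catalogue, empty, komap), "no KO terms")

  expect_error(parse_annotation_profile(
    text = c("gene_id\tfoo", "g1\tx"), organism_id = "o"), "KO column")
})

test_that("the 20-row annotation fixture yields exactly its 12 distinct KO terms", {
  prof <- parse_annotation_profile(fixture("toy_annotation.tsv"), "toy")
  expect_identical(prof$ko_terms, sprintf("K%05d", 1:12))
  expect_identical(prof$gene_count, 20L)
})

test_that("KO mapping selects exactly the reactions the profile supports", {
  catalogue <- parse_reaction_flatfile(fixture("toy_reactions.txt"))
  komap <- parse_ko_reaction_map(fixture("toy_ko_reaction_map.tsv"))
  prof <- parse_annotation_profile(
    text = c("gene_id\tko_id", "g1\tK00001", "g2\tK00003", "g3\tK00099"),
    organism_id = "o")
  sel <- reactions_for_profile(catalogue, prof, komap)
  expect_setequal(vapply(sel, `[[`, "", "reaction_id"), c("R00001", "R00003"))
})

test_that("fetch uses the cache when present and is idempotent", {
  cache <- withr::local_tempdir()
  dir.create(file.path(cache, "toyorg"))
  file.copy(fixture("toy_reactions.txt"),
            file.path(cache, "toyorg", "reactions.txt"))
  recs1 <- fetch_org_metabolic_data("toyorg", cache)
  recs2 <- fetch_org_metabolic_data("toyorg", cache)
  expect_identical(recs1, recs2)
  expect_identical(recs1, parse_reaction_flatfile(fixture("toy_reactions.txt")))
})

test_that("fetch rejects empty organism codes and fails loudly without cache", {
  cache <- withr::local_tempdir()
  expect_error(fetch_org_metabolic_data("", cache), "empty")
  suppressWarnings(
    expect_error(fetch_org_metabolic_data("nosuchorg", cache,
                                          base_url = "http://127.0.0.1:1"),
                 "KEGG REST request failed"))
})
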