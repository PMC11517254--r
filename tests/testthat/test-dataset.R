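valid_complexes <- function() data.frame(
  peptide = c("SIINFEKLV", "GILGFVFTL", "NLVPMVATV", "GLCTLVAML", "ELAGIGILTV"),
  hla = "HLA-A*02:01",
  cdr3b = c("CASSLGFF", "CASSQETQYF", "CAWSVGFF", "CASSIRSSYEQYF", "CASSPGQGFF"),
  label = c("immunogenic", "immunogenic", "non_immunogenic",
            "non_immunogenic", "immunogenic"),
  source = "unit_test",
  stringsAsFactors = FALSE
)

test_that("load_complexes keeps valid rows and drops invariant violations", {
  p <- write_tsv_tmp(valid_complexes())
  cx <- load_complexes(p)
  expect_equal(nrow(cx), 5L)

  bad <- valid_complexes()
  bad$peptide[1] <- "SHRTPEP"          # 7-mer -> dropped
  bad$peptide[2] <- "B1ADPEPTIDE"      # bad alphabet + 11 chars
  p2 <- write_tsv_tmp(bad)
  cx2 <- load_complexes(p2)
  expect_equal(nrow(cx2), 3L)
  dropped <- attr(cx2, "dropped")
  expect_equal(unname(dropped[["peptide length"]]), 1L)

  # duplicates across two files both load; dedup is separate
  cx3 <- load_complexes(c(p, p))
  expect_equal(nrow(cx3), 10L)

  bad2 <- valid_complexes(); bad2$label[1] <- "maybe"
  expect_error(load_complexes(write_tsv_tmp(bad2)), "unknown immunogenicity label")
  expect_error(load_complexes(write_tsv_tmp(valid_complexes()[, -2])), "hla")
})

test_that("normalize_hla canonicalizes allele spellings", {
  expect_equal(normalize_hla(c("A0201", "hla-a*02:01", "HLA-B07:02")),
               c("HLA-A*02:01", "HLA-A*02:01", "HLA-B*07:02"))
  expect_equal(normalize_hla("A0201", resolution = "two-digit"), "HLA-A*02")
})

test_that("make_negatives pairs each positive pHLA with k pool TCRs", {
  pos <- valid_complexes()[valid_complexes()$label == "immunogenic", ]
  pool <- sprintf("CASSP%sF", strrep(LETTERS[2:21], 2))
  pool <- pool[neoprior:::is_valid_aa(pool)]
  cfg <- assembly_config(negatives_per_phla = 10, seed = 7)
  neg <- make_negatives(pos, pool, cfg)
  expect_equal(nrow(neg), 3L * 10L)      # 3 distinct pHLAs x 10
  expect_true(all(neg$label == "non_immunogenic"))
  # per-pHLA counts exactly k, drawn without replacement
  per <- table(paste(neg$peptide, neg$hla))
  expect_true(all(per == 10))
  expect_false(any(duplicated(paste(neg$peptide, neg$hla, neg$cdr3b))))
  # known-positive partners are excluded
  expect_false(any(paste(neg$peptide, neg$cdr3b) %in%
                     paste(pos$peptide, pos$cdr3b)))
  # determinism
  expect_identical(neg, make_negatives(pos, pool, cfg))
  # pool consisting only of the positive partners -> explicit error
  expect_error(
    make_negatives(pos[1, ], pos$cdr3b[1],
                   assembly_config(negatives_per_phla = 1, seed = 1)),
    "pool"
  )
  expect_error(make_negatives(pos, pool[1:5], cfg), "smaller")
})

test_that("deduplicate_complexes collapses triples, immunogenic wins conflicts", {
  cx <- valid_complexes()
  expect_equal(nrow(deduplicate_complexes(rbind(cx, cx))), 5L)
  conflict <- rbind(cx[1, ], cx[1, ])
  conflict$label <- c("immunogenic", "non_immunogenic")
  dd <- deduplicate_complexes(conflict)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$label, "immunogenic")
  expect_equal(attr(dd, "n_label_conflicts"), 1L)
  expect_equal(nrow(deduplicate_complexes(cx)), 5L)
})

test_that("split_discovery_validation stratifies and never leaks", {
  set.seed(33)
  n_pos <- 10; n_neg <- 90
  recs <- data.frame(
    peptide = replicate(100, paste(sample(neoprior:::AA_ALPHABET, 9,
                                          replace = TRUE), collapse = "")),
    hla = "HLA-A*02:01",
    cdr3b = replicate(100, paste(sample(neoprior:::AA_ALPHABET, 12,
                                        replace = TRUE), collapse = "")),
    label = rep(c("immunogenic", "non_immunogenic"), c(n_pos, n_neg)),
    source = "t", stringsAsFactors = FALSE
  )
  cfg <- assembly_config(split_fraction = 0.7, split_unit = "complex", seed = 5)
  sp <- split_discovery_validation(recs, cfg)
  expect_equal(nrow(sp$discovery), 70L)
  expect_equal(sum(sp$discovery$label == "immunogenic"), 7L)
  # disjoint by complex key
  k <- function(df) paste(df$peptide, df$hla, df$cdr3b)
  expect_length(intersect(k(sp$discovery), k(sp$validation)), 0L)
  # determinism
  sp2 <- split_discovery_validation(recs, cfg)
  expect_identical(sp$discovery, sp2$discovery)

  # 10 records -> discovery size 7
  sp10 <- split_discovery_validation(
    recs[c(1:5, 11:15), ],
    assembly_config(split_unit = "complex", seed = 2)
  )
  expect_equal(nrow(sp10$discovery), 7L)

  # peptide mode: no peptide on both sides
  spp <- split_discovery_validation(recs, assembly_config(seed = 5))
  expect_length(intersect(spp$discovery$peptide, spp$validation$peptide), 0L)

  # stratified class proportions within 2 points of the whole
  for (s in list(sp, spp)) {
    whole <- mean(recs$label == "immunogenic")
    expect_lt(abs(mean(s$discovery$label == "immunogenic") - whole), 0.02 + 1e-9)
    expect_lt(abs(mean(s$validation$label == "immunogenic") - whole), 0.05)
  }

  one_class <- recs[1:11, ]; one_class$label <- "immunogenic"
  one_class$label[1] <- "non_immunogenic"
  expect_error(
    split_discovery_validation(one_class,
                               assembly_config(split_unit = "complex", seed = 1)),
    "stratified"
  )
})

test_that("split manifest records counts and checksum", {
  sim <- simulate_complexes(n_positive = 20, seed = 3)
  cfg <- assembly_config(seed = 9)
  sp <- split_discovery_validation(sim$complexes, cfg)
  path <- tempfile(fileext = ".json")
  write_split_manifest(sp, cfg, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$n_discovery, nrow(sp$discovery))
  expect_equal(m$unit, "peptide")
  expect_true(is.numeric(m$key_checksum))
})
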