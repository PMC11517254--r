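test_that("read_airr_table reads, merges duplicate keys, and skips invalid rows", {
  p <- write_tsv_tmp(airr_df(
    c("CASSLGF", "CASSQETQYF", "CAWSVGF"),
    c("TRBV5", "TRBV6", "TRBV7"), c("TRBJ1", "TRBJ2", "TRBJ1"), c(3, 1, 2)
  ))
  tab <- read_airr_table(p)
  expect_s3_class(tab, "clonotype_table")
  expect_equal(nrow(tab$clonotypes), 3L)
  expect_equal(tab$total_reads, 6)
  expect_equal(attr(tab, "n_skipped"), 0L)

  # identical keys merge by summing counts; empty CDR3 row is skipped
  p2 <- write_tsv_tmp(airr_df(
    c("CASSLGF", "CASSLGF", ""),
    c("TRBV5", "TRBV5", "TRBV9"), c("TRBJ1", "TRBJ1", "TRBJ1"), c(2, 3, 4)
  ))
  tab2 <- read_airr_table(p2)
  expect_equal(nrow(tab2$clonotypes), 1L)
  expect_equal(tab2$clonotypes$count, 5)
  expect_equal(tab2$total_reads, 5)   # merge preserves total reads
  expect_equal(attr(tab2, "n_skipped"), 1L)

  # missing required column -> error naming the column
  p3 <- write_tsv_tmp(data.frame(junction_aa = "CASS", v_call = "V",
                                 duplicate_count = 1))
  expect_error(read_airr_table(p3), "j_call")

  # everything filtered -> empty-input error
  p4 <- write_tsv_tmp(airr_df("", "V", "J", 1))
  expect_error(read_airr_table(p4), "no valid clonotype rows")
})

test_that("generic dialect and gzip transparency work", {
  df <- data.frame(aa = c("CASSF", "CAWXX"), v = "V1", j = "J1", n = c(2, 1))
  df$aa[2] <- "CAWSF"
  path <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "wt")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  tab <- read_airr_table(path, dialect = "generic",
                         columns = list(cdr3_aa = "aa", v_call = "v",
                                        j_call = "j", count = "n"))
  expect_equal(nrow(tab$clonotypes), 2L)
  expect_equal(tab$total_reads, 3)
  expect_error(read_airr_table(tempfile(), dialect = "generic"),
               "columns")
})

test_that("filter_by_count thresholds and renormalizes", {
  tab <- clonotype_table("S", data.frame(
    cdr3_aa = c("CASA", "CASD", "CASC"), v_call = "V", j_call = "J",
    count = c(1, 2, 5)
  ))
  f2 <- filter_by_count(tab, 2)
  expect_equal(f2$clonotypes$count, c(2, 5))
  expect_equal(filter_by_count(tab, 1)$clonotypes, tab$clonotypes)

  tab2 <- clonotype_table("S", data.frame(
    cdr3_aa = c("CASA", "CASD"), v_call = "V", j_call = "J", count = c(3, 4)
  ))
  expect_equal(clone_frequencies(filter_by_count(tab2, 2)), c(3 / 7, 4 / 7))
  expect_error(filter_by_count(tab2, 10), "all clonotypes removed")
  expect_error(filter_by_count(tab2, 0), ">= 1")
})

test_that("shannon_entropy and clonality match worked values and validate input", {
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_equal(shannon_entropy(1.0), 0.0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.039721, tolerance = 1e-6)
  expect_equal(clonality(rep(0.25, 4)), 0.0)
  expect_equal(clonality(c(0.5, 0.25, 0.25)), 0.05360537, tolerance = 1e-6)
  expect_equal(clonality(c(0.97, 0.01, 0.01, 0.01)), 0.879, tolerance = 1e-3)
  expect_error(shannon_entropy(c(0.5, 0.5, 0.1)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "positive")
  expect_error(clonality(1.0), "fewer than 2")
})

test_that("entropy/clonality properties hold on random frequency vectors", {
  set.seed(401)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    p <- random_freqs(n)
    h <- shannon_entropy(p)
    expect_lte(h, log(n) + 1e-12)
    cl <- clonality(p)
    expect_gte(cl, -1e-12)
    expect_lte(cl, 1)
  }
  # equality iff uniform
  expect_equal(shannon_entropy(rep(1 / 7, 7)), log(7))
})

test_that("rarefaction_curve is correct at the boundaries and on the 2x50 toy", {
  tab <- clonotype_table("S", data.frame(
    cdr3_aa = c("CASA", "CASD", "CASC"), v_call = "V", j_call = "J",
    count = c(10, 5, 5)
  ))
  rc <- rarefaction_curve(tab, c(1, 10, 20), n_reps = 50, seed = 9)
  expect_equal(rc$mean_richness[1], 1)          # depth 1
  expect_equal(rc$mean_richness[3], 3)          # full depth = richness
  expect_equal(rc$sd_richness[3], 0)
  expect_true(all(diff(rc$mean_richness) >= 0)) # non-decreasing
  expect_error(rarefaction_curve(tab, 21), "total_reads")
  expect_error(rarefaction_curve(tab, c(10, 5)), "increasing")
  # reproducible given seed
  rc2 <- rarefaction_curve(tab, c(1, 10, 20), n_reps = 50, seed = 9)
  expect_identical(rc, rc2)

  # 2 clones of 50 reads each, depth 10: hypergeometric expectation
  toy <- clonotype_table("T", data.frame(
    cdr3_aa = c("CAAA", "CDDD"), v_call = "V", j_call = "J", count = c(50, 50)
  ))
  expected <- 2 * (1 - choose(50, 10) / choose(100, 10))
  rt <- rarefaction_curve(toy, 10, n_reps = 200, seed = 42)
  expect_gte(rt$mean_richness, 1.9)
  expect_lte(rt$mean_richness, 2.0)
  expect_lt(abs(rt$mean_richness - expected), 0.05)
})

test_that("clonotype_sharing counts private and shared clonotypes", {
  mk <- function(cdr3, v = "V", j = "J") clonotype_table("S", data.frame(
    cdr3_aa = cdr3, v_call = v, j_call = j, count = 1
  ))
  a <- mk(c("CAAA", "CDDD"))
  expect_equal(clonotype_sharing(list(a, a))$fraction_private, 0)
  b <- mk(c("CCCC", "CEEE"))
  expect_equal(clonotype_sharing(list(a, b))$fraction_private, 1)
  # 3 samples, union 10, exactly 1 clonotype in 2 samples
  s1 <- mk(c("CAAA", "CACC", "CADD", "CAEE"))
  s2 <- mk(c("CFAA", "CFCC", "CFDD"))
  s3 <- mk(c("CCAA", "CCCC", "CCDD", "CAAA"))  # CAAA shared with s1
  sh <- clonotype_sharing(list(s1, s2, s3))
  expect_equal(nrow(sh$per_clonotype), 10L)
  expect_equal(sh$fraction_shared, 0.1)
  expect_error(clonotype_sharing(list(a)), "at least 2")
  # cdr3-only mode collapses same CDR3 with different V
  x <- mk("CAAA", v = "V1"); y <- mk("CAAA", v = "V2")
  expect_equal(clonotype_sharing(list(x, y))$fraction_private, 1)
  expect_equal(clonotype_sharing(list(x, y), cdr3_only = TRUE)$fraction_shared, 1)
})

test_that("segment_usage fills the repertoire profile", {
  tab <- clonotype_table("S", data.frame(
    cdr3_aa = c("CASSLGFFFFFF", "CASSQETQYFFFFF", "CAWSVGFFFFFFFFFF"),
    v_call = c("V1", "V1", "V2"), j_call = c("J1", "J2", "J1"),
    count = c(1, 1, 4)
  ))
  prof <- segment_usage(tab)
  expect_equal(prof$v_usage, c(V1 = 2L, V2 = 1L))
  expect_equal(prof$j_usage, c(J1 = 2L, J2 = 1L))
  expect_equal(unname(prof$cdr3_length_summary), c(14, 12, 16))
  expect_equal(prof$n_singletons, 2L)
  expect_equal(prof$n_multi, 1L)
  # per-segment counts sum to n_clonotypes for each of V and J
  expect_equal(sum(prof$v_usage), prof$n_clonotypes)
  expect_equal(sum(prof$j_usage), prof$n_clonotypes)
  expect_equal(sum(prof$vj_pairing), prof$n_clonotypes)
  # JSON export round-trips
  path <- tempfile(fileext = ".json")
  write_profile_json(prof, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_clonotypes, prof$n_clonotypes)
  expect_equal(back$shannon, prof$shannon, tolerance = 1e-12)
})
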