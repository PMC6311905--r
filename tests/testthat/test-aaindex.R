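test_that("parse_aaindex reads well-formed entries and round-trips", {
  v1 <- sprintf("%.3f", seq(0.1, 2.0, by = 0.1))
  v2 <- sprintf("%.3f", seq(2.0, 0.1, by = -0.1))
  path <- write_aaindex_text(list(aaindex_entry_text("SYNT000001", v1),
                                  aaindex_entry_text("SYNT000002", v2)))
  tab <- parse_aaindex(path)
  expect_s3_class(tab, "property_table")
  expect_equal(length(tab), 2L)
  expect_equal(accessions(tab), c("SYNT000001", "SYNT000002"))
  expect_equal(unname(tab$values[, 1]), seq(0.1, 2.0, by = 0.1))

  out <- withr::local_tempfile(fileext = ".txt")
  write_aaindex(tab, out)
  tab2 <- parse_aaindex(out)
  expect_equal(tab2$values, tab$values)
})

test_that("parse_aaindex excludes NA-containing entries and reports them", {
  v1 <- sprintf("%.2f", 1:20)
  v2 <- c(sprintf("%.2f", 1:19), "NA")
  path <- write_aaindex_text(list(aaindex_entry_text("SYNT000001", v1),
                                  aaindex_entry_text("SYNT000011", v2)))
  expect_message(tab <- parse_aaindex(path), "SYNT000011")
  expect_equal(accessions(tab), "SYNT000001")
  expect_equal(attr(tab, "excluded"), "SYNT000011")
})

test_that("parse_aaindex names the accession on malformed entries", {
  bad <- aaindex_entry_text("SYNT000099", sprintf("%.2f", 1:20))
  bad <- bad[-3]                         # drop the I record
  expect_error(parse_aaindex(write_aaindex_text(list(bad))), "SYNT000099")
  short <- aaindex_entry_text("SYNT000098", sprintf("%.2f", 1:20))
  short[4] <- "   1.0  2.0"              # wrong value count
  expect_error(parse_aaindex(write_aaindex_text(list(short))),
               "SYNT000098.*expected 20")
})

test_that("the bundled default property set has 46 complete descriptors", {
  tab <- hotspot_properties()
  expect_equal(length(tab), 46L)
  expect_equal(dim(tab$values), c(20L, 46L))
  expect_false(anyNA(tab$values))
  expect_false(anyDuplicated(accessions(tab)) > 0)
  # minmax normalization: every descriptor spans exactly [0, 1]
  expect_equal(unname(apply(tab$values, 2, min)), rep(0, 46))
  expect_equal(unname(apply(tab$values, 2, max)), rep(1, 46))
})

test_that("pearson_correlation matches the textbook formula and its properties", {
  expect_equal(pearson_correlation(1:20, 1:20), 1.0)
  p <- rep(c(1, 2, 3, 4, 4, 3, 2, 1), length.out = 20)
  expect_equal(pearson_correlation(p, rev(p)), -1.0)

  set.seed(11)
  for (i in 1:20) {
    p <- rnorm(20); q <- rnorm(20)
    brute <- sum((p - mean(p)) * (q - mean(q))) /
      sqrt(sum((p - mean(p))^2) * sum((q - mean(q))^2))
    expect_equal(pearson_correlation(p, q), brute, tolerance = 1e-12)
    # symmetry and positive-affine invariance
    expect_equal(pearson_correlation(q, p), pearson_correlation(p, q))
    expect_equal(pearson_correlation(2.5 * p + 7, q), pearson_correlation(p, q))
  }
  expect_error(pearson_correlation(rep(1, 20), rnorm(20)), "zero-variance")
})

test_that("remove_redundant leaves independent tables unchanged and drops later duplicates", {
  set.seed(3)
  tab <- random_property_table(4, seed = 3)
  # random 20-vectors are weakly correlated at threshold 0.99
  expect_equal(accessions(remove_redundant(tab, 0.99)), accessions(tab))

  v <- tab$values[, c(1, 2, 1)]
  colnames(v) <- c("AAA000001", "BBB000001", "CCC000001")
  dup <- property_table(v)
  pruned <- remove_redundant(dup, 0.5)
  expect_equal(accessions(pruned), c("AAA000001", "BBB000001"))
  expect_equal(attr(pruned, "removed"), "CCC000001")
})

test_that("remove_redundant agrees with an independent brute-force greedy", {
  brute_greedy <- function(values, threshold) {
    alive <- seq_len(ncol(values))
    repeat {
      np <- sapply(alive, function(i)
        sum(sapply(setdiff(alive, i), function(j)
          abs(cor(values[, i], values[, j])) > threshold)))
      if (all(np == 0)) return(alive)
      alive <- setdiff(alive, alive[max(which(np == max(np)))])
    }
  }
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    base <- matrix(rnorm(20 * 4), nrow = 20)
    # mix shared components in so some pairs exceed the threshold
    v <- sapply(seq_len(n), function(i)
      base %*% rnorm(4) + rnorm(20, sd = 0.5))
    rownames(v) <- aa20
    colnames(v) <- sprintf("RND%07d", seq_len(n))
    tab <- property_table(v)
    got <- remove_redundant(tab, 0.5)
    expect_equal(accessions(got), colnames(v)[brute_greedy(v, 0.5)])
    # no surviving pair exceeds the threshold (exhaustive)
    cc <- abs(cor(got$values)); diag(cc) <- 0
    expect_true(all(cc <= 0.5))
    # deterministic
    expect_equal(accessions(remove_redundant(tab, 0.5)), accessions(got))
  }
})

test_that("minmax normalization is an idempotent affine map onto [0, 1]", {
  v <- matrix(seq(2, 80, by = 2), nrow = 20, ncol = 2,
              dimnames = list(aa20, c("AAA000001", "BBB000001")))
  v[, 2] <- rev(v[, 2])
  tab <- normalize_properties(property_table(v), "minmax")
  expect_equal(unname(apply(tab$values, 2, range)), matrix(c(0, 1, 0, 1), 2))
  expect_equal(normalize_properties(tab, "minmax")$values, tab$values)
  expect_equal(normalize_properties(property_table(v), "none")$values, v)
})

test_that("property tables round-trip through TSV", {
  tab <- random_property_table(6, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_property_tsv(tab, path)
  back <- read_property_tsv(path)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_equal(accessions(back), accessions(tab))
})

test_that("property_table rejects degenerate descriptors", {
  v <- matrix(rnorm(40), nrow = 20, dimnames = list(aa20, c("A1", "A2")))
  v[3, 2] <- NA
  expect_error(property_table(v), "A2")
  v[3, 2] <- 0; v[, 2] <- 5
  expect_error(property_table(v), "zero-variance")
})
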