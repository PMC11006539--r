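test_that("occupancy cleaning keeps columns at or above the threshold", {
  # 21 rows: 2/21 = 9.5% removed, 3/21 = 14.3% kept at the 10% default
  col2 <- c(rep("A", 2), rep("-", 19))
  col3 <- c(rep("A", 3), rep("-", 18))
  full <- rep("C", 21)
  m <- cbind(col2, col3, full)
  rownames(m) <- paste0("t", 1:21)
  out <- clean_columns(m)
  expect_equal(ncol(out), 2L)
  expect_equal(unname(out[1, ]), c("A", "C"))
  expect_equal(rownames(out), rownames(m))
})

test_that("occupancy cleaning is idempotent and never adds columns", {
  set.seed(91)
  for (rep in 1:10) {
    a <- random_alignment()
    once <- clean_columns(a, 0.3)
    expect_lte(ncol(once), ncol(a))
    expect_identical(clean_columns(once, 0.3), once)
  }
})

test_that("a gapless alignment passes occupancy cleaning unchanged", {
  a <- as_alignment(c(x = "ACGT", y = "TGCA"))
  expect_identical(clean_columns(a), a)
})

test_that("N is treated as missing by default but can be retained", {
  m <- matrix(c("N", "N", "A", rep("-", 7), rep("C", 2)), ncol = 1)
  m <- cbind(m, matrix("G", 12, 1))
  rownames(m) <- paste0("t", 1:12)
  # 3 informative chars of 12 = 25%... with N missing: 3/12 = 0.25
  expect_equal(ncol(clean_columns(m, 0.3)), 1L)
  expect_equal(ncol(clean_columns(m, 0.3, missing_chars = "-")), 2L)
})

test_that("concatenation tiles partitions and pads absent taxa with gaps", {
  g1 <- as_alignment(c(A = strrep("A", 100), B = strrep("C", 100)))
  g2 <- as_alignment(c(A = strrep("G", 200), C = strrep("T", 200)))
  res <- concatenate_alignments(list(gene1 = g1, gene2 = g2))
  expect_equal(ncol(res$alignment), 300L)
  expect_equal(res$partitions$start, c(1L, 101L))
  expect_equal(res$partitions$end, c(100L, 300L))
  expect_equal(paste(res$alignment["C", 1:100], collapse = ""),
               strrep("-", 100))
  expect_equal(paste(res$alignment["B", 101:300], collapse = ""),
               strrep("-", 200))
  expect_error(concatenate_alignments(list(g = g1, g = g2)), "unique")
})

test_that("concatenate then split reproduces the padded inputs exactly", {
  set.seed(92)
  for (rep in 1:10) {
    genes <- lapply(1:3, function(i) {
      a <- random_alignment(nrow_ = sample(3:6, 1))
      rownames(a) <- sample(paste0("t", 1:8), nrow(a))
      a
    })
    names(genes) <- paste0("g", 1:3)
    res <- concatenate_alignments(genes)
    back <- split_by_partitions(res$alignment, res$partitions)
    for (nm in names(genes)) {
      orig <- genes[[nm]]
      expect_identical(back[[nm]][rownames(orig), , drop = FALSE], orig)
      absent <- setdiff(rownames(res$alignment), rownames(orig))
      if (length(absent)) {
        expect_true(all(back[[nm]][absent, ] == "-"))
      }
    }
  }
})

test_that("single-alignment concatenation is the identity with one partition", {
  g <- as_alignment(c(A = "ACGT", B = "TTTT"))
  res <- concatenate_alignments(list(solo = g))
  expect_identical(res$alignment[rownames(g), ], g)
  expect_equal(res$partitions,
               data.frame(gene_id = "solo", start = 1L, end = 4L))
})

test_that("parsimony-informative columns need two states in two rows each", {
  a <- as_alignment(c(r1 = "AAA", r2 = "AAA", r3 = "CAC", r4 = "CCC"))
  # col1: A2/C2 informative; col2: A3/C1 not; col3: A2/C2 informative
  expect_equal(parsimony_informative_sites(a), 2L)
  gapped <- as_alignment(c(r1 = "A", r2 = "A", r3 = "-", r4 = "-",
                           r5 = "C", r6 = "C"))
  expect_equal(parsimony_informative_sites(gapped), 1L)
  expect_equal(parsimony_informative_sites(as_alignment(c(a = "A", b = "C"))),
               0L)
})

test_that("informative counts match the brute-force oracle", {
  set.seed(93)
  for (rep in 1:20) {
    a <- random_alignment()
    expect_identical(parsimony_informative_sites(a),
                     oracle_informative(a))
  }
})

test_that("tree length sums branches and ignores rooting", {
  tr <- parse_newick("(A:0.1,B:0.2,C:0.3);")
  expect_equal(tree_length(tr), 0.6)
  tr2 <- parse_newick("((A:0,B:0):0,C:0);")
  expect_equal(tree_length(tr2), 0)
  set.seed(94)
  tr3 <- ape::rtree(8)
  rerooted <- ape::root(tr3, outgroup = tr3$tip.label[1], resolve.root = TRUE)
  expect_equal(tree_length(tr3), tree_length(rerooted), tolerance = 1e-12)
})

test_that("partition text follows the RAxML convention", {
  parts <- data.frame(gene_id = c("gene1", "gene2"), start = c(1L, 101L),
                      end = c(100L, 300L))
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  write_partitions_raxml(parts, f)
  expect_equal(readLines(f), c("DNA, gene1 = 1-100", "DNA, gene2 = 101-300"))
})
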