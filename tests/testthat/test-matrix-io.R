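test_that("a hand-written triplet file is transcribed exactly", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 3", "2 2 5"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  cm <- read_count_matrix(dir, sample_id = "toy")
  expect_equal(as.matrix(cm$counts),
               matrix(c(3, 0, 0, 5), 2, 2, dimnames = list(c("gA", "gB"), c("c1", "c2"))))
})

test_that("an empty triplet body yields an all-zero matrix of the declared shape", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  cm <- read_count_matrix(dir)
  expect_equal(dim(cm$counts), c(3L, 2L))
  expect_equal(sum(cm$counts), 0)
})

test_that("count matrices round-trip through the 10x-style directory format", {
  co <- generate_cohort(tiny_config(seed = 61L))
  dir <- withr::local_tempdir()
  write_count_matrix(co$samples$S1, file.path(dir, "S1"))
  back <- read_count_matrix(file.path(dir, "S1"), sample_id = "S1")
  expect_identical(as.matrix(back$counts), as.matrix(co$samples$S1$counts))
  expect_identical(rownames(back$counts), rownames(co$samples$S1$counts))
  expect_identical(colnames(back$counts), colnames(co$samples$S1$counts))
})

test_that("sidecar/matrix dimension mismatches and invalid values are format errors", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "1 1 4"), file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  expect_error(read_count_matrix(dir), "features")
  writeLines(c("gA", "gB"), file.path(dir, "features.tsv"))
  writeLines("c1", file.path(dir, "barcodes.tsv"))
  expect_error(read_count_matrix(dir), "barcodes")
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 -4.0"), file.path(dir, "matrix.mtx"))
  expect_error(read_count_matrix(dir), "negative")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 2.5"), file.path(dir, "matrix.mtx"))
  expect_error(read_count_matrix(dir), "non-integer")
})

test_that("GMT collections round-trip and agree with an independent GMT reader", {
  sets <- do.call(rbind, lapply(1:4, function(i) {
    tibble::tibble(set = sprintf("MP%d", i), description = sprintf("set %d", i),
                   gene = sprintf("g%03d", seq_len(50) + 50 * i))
  }))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, path)
  expect_identical(read_gene_sets(path), sets)
  skip_if_not_installed("fgsea")
  ext <- fgsea::gmtPathways(path)
  expect_identical(names(ext), sprintf("MP%d", 1:4))
  expect_identical(ext$MP2, sets$gene[sets$set == "MP2"])
})

test_that("single-set and empty GMT edge cases hold", {
  path <- withr::local_tempfile(fileext = ".gmt")
  one <- tibble::tibble(set = "MP1", description = "d", gene = c("g1", "g2"))
  write_gene_sets(one, path)
  line <- readLines(path)
  expect_length(line, 1)
  expect_equal(strsplit(line, "\t")[[1]], c("MP1", "d", "g1", "g2"))
  empty <- one[0, ]
  write_gene_sets(empty, path)
  expect_equal(nrow(read_gene_sets(path)), 0)
  expect_error(write_gene_sets(
    tibble::tibble(set = "a", description = "b", gene = "g\t1"), path), "tab")
})

test_that("manifests round-trip through YAML and validate their paths", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "S1"))
  dir.create(file.path(dir, "S2"))
  m <- tibble::tibble(sample_id = c("S1", "S2"),
                      path = file.path(dir, c("S1", "S2")),
                      group = c("tumor", "tumor"))
  path <- file.path(dir, "manifest.yaml")
  write_manifest(m, path)
  expect_equal(read_manifest(path), m)
  m2 <- m; m2$path[2] <- file.path(dir, "missing")
  write_manifest(m2, path)
  expect_error(read_manifest(path), "not found")
  expect_error(write_manifest(m[c(1, 1), ], path), "unique")
})

test_that("score tables round-trip through CSV", {
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(sprintf("S1_c%d", 1:4), sprintf("P%d", 1:3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_csv(m, path)
  back <- read_score_csv(path)
  expect_equal(back, m, tolerance = 1e-12)
})

test_that("ground truth round-trips through JSON", {
  co <- generate_cohort(tiny_config(seed = 71L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(co$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$program_genes, co$truth$program_genes)
  expect_equal(back$program_info, co$truth$program_info)
  expect_equal(back$cell_activity, co$truth$cell_activity, tolerance = 1e-12)
})
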