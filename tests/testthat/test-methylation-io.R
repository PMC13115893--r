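test_that("beta matrices parse from TSV and validate their contract", {
  dirp <- tempfile(); dir.create(dirp)
  mpath <- file.path(dirp, "beta.tsv")
  spath <- file.path(dirp, "sheet.tsv")
  writeLines(c("cpg_id\tS1\tS2",
               "cg01\t0.1\t0.5",
               "cg02\t0.9\t0.3",
               "cg03\t0.2\t0.8"), mpath)
  writeLines(c("sample_id\tlabel\tbatch",
               "S1\t1\tA", "S2\t0\tB"), spath)
  bm <- read_beta_matrix(mpath, spath)
  expect_identical(bm$values["cg01", "S2"], 0.5)
  expect_identical(bm$labels, c(1L, 0L))

  # sheet missing a sample names the sample
  writeLines(c("sample_id\tlabel\tbatch", "S1\t1\tA"), spath)
  expect_error(read_beta_matrix(mpath, spath), "S2")

  # out-of-range value names probe and sample
  writeLines(c("sample_id\tlabel\tbatch", "S1\t1\tA", "S2\t0\tB"), spath)
  writeLines(c("cpg_id\tS1\tS2", "cg01\t1.2\t0.5"), mpath)
  expect_error(read_beta_matrix(mpath, spath), "cg01.*S1")

  # duplicate probe ids rejected
  writeLines(c("cpg_id\tS1\tS2", "cg01\t0.2\t0.5", "cg01\t0.3\t0.4"), mpath)
  expect_error(read_beta_matrix(mpath, spath), "duplicate")
})

test_that("write/read round-trips at the configured precision", {
  bm <- toy_beta(10, 6)
  path <- tempfile(fileext = ".tsv")
  write_beta_matrix(bm, path, precision = 4)
  back <- read_beta_matrix(path, paste0(path, ".sheet.tsv"))
  expect_equal(back$values, round(bm$values, 4), tolerance = 0)
  expect_identical(back$labels, bm$labels)
  expect_identical(back$batch, bm$batch)
  # writing the rounded matrix again is a fixed point
  write_beta_matrix(back, path, precision = 4)
  again <- read_beta_matrix(path, paste0(path, ".sheet.tsv"))
  expect_identical(again$values, back$values)
})

test_that("annotation CSV round-trips through the manifest-like format", {
  co <- generate_cohort(sim_config(n_cpg = 100, n_dm = 10, n_genes = 30,
                                   seed = 2))
  path <- tempfile(fileext = ".csv")
  write_cpg_annotation(co$annotation, path)
  back <- read_cpg_annotation(path)
  expect_identical(back$probes$cpg_id, co$annotation$probes$cpg_id)
  expect_identical(back$probes$pos, co$annotation$probes$pos)
  o1 <- co$annotation$links[order(co$annotation$links$cpg_id,
                                  co$annotation$links$gene), ]
  o2 <- back$links[order(back$links$cpg_id, back$links$gene), ]
  expect_identical(o1$gene, o2$gene)
  expect_identical(o1$tss, o2$tss)
})

test_that("harmonization intersects probes and drops missing values", {
  v1 <- matrix(0.5, 8, 3, dimnames = list(sprintf("cg%02d", 1:8),
                                          c("A1", "A2", "A3")))
  v2 <- matrix(0.4, 5, 3, dimnames = list(sprintf("cg%02d", 1:5),
                                          c("B1", "B2", "B3")))
  v2["cg03", "B2"] <- NA
  d1 <- beta_matrix(v1, labels = c(1L, 1L, 0L), batch = rep("D1", 3))
  d2 <- beta_matrix(v2, labels = c(1L, 0L, 0L), batch = rep("D2", 3))
  ann <- toy_annotation(sprintf("cg%02d", 1:8))
  h <- harmonize_datasets(list(d1, d2), ann)
  # 5 shared probes minus the one with a missing value
  expect_identical(nrow(h$values), 4L)
  expect_false("cg03" %in% h$cpg_ids)
  expect_identical(ncol(h$values), 6L)
})

test_that("harmonized probes follow the genomic total order", {
  ids <- c("p1", "p2", "p3", "p4", "p5")
  v <- matrix(0.5, 5, 4, dimnames = list(ids, sprintf("S%d", 1:4)))
  bm <- beta_matrix(v, labels = c(1L, 1L, 0L, 0L), batch = rep("A", 4))
  ann <- cpg_annotation(
    probes = data.frame(cpg_id = ids,
                        chrom = c("chr10", "chr2", "chrX", "chr2", "chr1"),
                        pos = c(50L, 900L, 10L, 100L, 99L)),
    links = data.frame(cpg_id = character(0), gene = character(0),
                       tss = integer(0), strand = character(0)))
  h <- harmonize_datasets(bm, ann)
  # chr1 < chr2 (numeric) < chr10 < chrX; within chr2 by position
  expect_identical(h$cpg_ids, c("p5", "p4", "p2", "p1", "p3"))
})

test_that("batch correction equalizes batch means and is idempotent", {
  set.seed(3)
  v <- matrix(runif(8 * 6, 0.3, 0.7), 8, 6,
              dimnames = list(sprintf("cg%02d", 1:8), sprintf("S%d", 1:6)))
  v[1, 1:3] <- v[1, 1:3] + 0.1
  v[1, 4:6] <- v[1, 4:6] - 0.1
  bm <- beta_matrix(v, labels = c(1L, 1L, 1L, 0L, 0L, 0L),
                    batch = c("A", "A", "A", "B", "B", "B"))
  ann <- toy_annotation(rownames(v))
  h <- harmonize_datasets(bm, ann, precision = 10)
  expect_lt(abs(mean(h$values[1, 1:3]) - mean(h$values[1, 4:6])), 1e-9)

  # idempotence on a full synthetic cohort (clipping active)
  co <- generate_cohort(sim_config(n_cases = 30, n_controls = 15,
                                   n_cpg = 300, n_dm = 20, seed = 9))
  h1 <- harmonize_datasets(co$beta, co$annotation)
  h2 <- harmonize_datasets(h1, co$annotation)
  expect_identical(h1$values, h2$values)
})

test_that("degenerate harmonization inputs raise errors", {
  v1 <- matrix(0.5, 3, 2, dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  v2 <- matrix(0.5, 3, 2, dimnames = list(c("x", "y", "z"), c("T1", "T2")))
  d1 <- beta_matrix(v1, labels = c(1L, 0L), batch = c("A", "A"))
  d2 <- beta_matrix(v2, labels = c(1L, 0L), batch = c("B", "B"))
  ann <- toy_annotation(c("a", "b", "c", "x", "y", "z"))
  expect_error(harmonize_datasets(list(d1, d2), ann), "common")
  expect_error(beta_matrix(matrix(numeric(0), 0, 0), integer(0), character(0)))
})
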