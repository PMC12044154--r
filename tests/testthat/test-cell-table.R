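test_that("cell_table enforces its invariants", {
  ct <- cell_table("s1", x = c(0, 1, 2), y = c(0, 0, 1),
                   celltype = c("A", "B", "B"))
  expect_s3_class(ct, "cell_table")
  expect_equal(ct$n, 3)
  expect_equal(levels(ct$celltype), c("A", "B"))

  expect_error(cell_table("s", x = 1:2, y = c(1, NA), celltype = c("A", "A")),
               "finite")
  expect_error(cell_table("s", x = 1:2, y = 1:2), "celltype or markers")
  expect_error(cell_table("s", x = 1:2, y = 1:2, celltype = c("A", "A"),
                          cell_id = c("c", "c")), "duplicated")
  expect_error(cell_table("s", x = 1:2, y = 1:2,
                          markers = matrix(c(-1, 1, 1, 1), 2,
                                           dimnames = list(NULL, c("a", "b")))),
               "nonnegative")
})

test_that("CSV round trip reproduces values bit-exactly", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.csv")
  # awkward doubles that lose precision under default formatting
  set.seed(1)
  M <- matrix(rgamma(30, 1) / 3, 10, 3,
              dimnames = list(NULL, c("M1", "M2", "M3")))
  ct <- cell_table("s1", x = runif(10) * 1000 / 3, y = runif(10),
                   celltype = sample(c("A", "B"), 10, TRUE), markers = M)
  write_cell_table(ct, p1)
  back <- read_cell_table(p1, sample_id = "s1",
                          columns = list(x = "x", y = "y",
                                         celltype = "celltype",
                                         markers = c("M1", "M2", "M3")))
  expect_identical(back$x, ct$x)
  expect_identical(back$y, ct$y)
  expect_identical(unname(back$markers), unname(ct$markers))
  expect_equal(as.character(back$celltype), as.character(ct$celltype))
  # writing what was read reproduces the file byte-for-byte
  p2 <- file.path(dir, "b.csv")
  write_cell_table(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("schema and mode errors are informative", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")
  write.csv(data.frame(x = 1:3, celltype = "A"), p, row.names = FALSE)
  expect_error(read_cell_table(p), "schema error.*'y'")

  p2 <- file.path(dir, "markers_only.csv")
  write.csv(data.frame(x = 1:3, y = 1:3, M1 = 1, M2 = 2), p2,
            row.names = FALSE)
  expect_error(read_cell_table(p2, mode = "celltype"), "mode error")
  ct <- read_cell_table(p2, columns = list(x = "x", y = "y",
                                           markers = c("M1", "M2")),
                        mode = "marker")
  expect_equal(colnames(ct$markers), c("M1", "M2"))
})

test_that("cohort assembly takes the lexicographic union of type levels", {
  s1 <- cell_table("s1", x = 1:3, y = 1:3, celltype = c("B", "A", "B"))
  s2 <- cell_table("s2", x = 1:3, y = 1:3, celltype = c("C", "C", "A"))
  coh <- as_cohort(list(s1, s2), c("g1", "g2"))
  expect_equal(coh$features, c("A", "B", "C"))
  # absent level yields a zero column downstream
  v <- build_celltype_views(coh$samples$s1, k = 1, levels = coh$features)
  expect_equal(unname(colSums(v$intraview)), c(1, 2, 0))
})

test_that("cohort loading reports unreadable samples and panel mismatches", {
  dir <- withr::local_tempdir()
  for (s in c("s1", "s2")) {
    write.csv(data.frame(x = runif(5), y = runif(5),
                         celltype = sample(c("A", "B"), 5, TRUE)),
              file.path(dir, paste0(s, ".csv")), row.names = FALSE)
  }
  man <- data.frame(sample_id = c("s1", "s2", "s3"),
                    path = paste0(c("s1", "s2", "missing"), ".csv"),
                    condition = c("g1", "g2", "g1"))
  mp <- file.path(dir, "manifest.csv")
  write.csv(man, mp, row.names = FALSE)
  expect_error(load_cohort(mp, columns = list(x = "x", y = "y")), "s3")

  man <- man[1:2, ]
  write.csv(man, mp, row.names = FALSE)
  coh <- load_cohort(mp, columns = list(x = "x", y = "y"))
  expect_length(coh$samples, 2)
  expect_equal(nlevels(coh$condition), 2)

  m1 <- cell_table("m1", 1:15, 1:15,
                   markers = matrix(1, 15, 2, dimnames = list(NULL, c("a", "b"))))
  m2 <- cell_table("m2", 1:15, 1:15,
                   markers = matrix(1, 15, 2, dimnames = list(NULL, c("a", "c"))))
  expect_error(as_cohort(list(m1, m2), c("g1", "g2"), mode = "marker"),
               "panel-mismatch")
})

test_that("config validates parameters and round-trips through YAML", {
  expect_error(winsig_config(overlap = 1), "overlap")
  expect_error(winsig_config(window_size = 0), "window_size")
  expect_error(winsig_config(similarity_cutoff = 1.2), "cutoff")
  cfg <- winsig_config(mode = "marker", paraview_l = 80, seed = 9)
  dir <- withr::local_tempdir()
  yp <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(mode = "marker", paraview_l = 80, seed = 9), yp)
  cfg2 <- read_config(yp)
  expect_equal(cfg2$paraview_l, 80)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$overlap, cfg$overlap)
})
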