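# Preprocessing: file I/O, present-call filtering, probe-to-gene
# summarization, z-scoring and fold changes.

write_study_fixture <- function(dir, m, info, present = NULL) {
  dir.create(dir, showWarnings = FALSE)
  ef <- file.path(dir, "expr.tsv")
  write.table(data.frame(probe_id = rownames(m), m, check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- file.path(dir, "meta.tsv")
  write.table(info, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  pf <- NULL
  if (!is.null(present)) {
    pf <- file.path(dir, "present.tsv")
    write.table(data.frame(probe_id = rownames(present), present,
                           check.names = FALSE),
                pf, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(expr = ef, meta = mf, present = pf)
}

demo_info <- function(sample_ids) {
  data.frame(sample_id = sample_ids,
             animal_id = paste0("m", seq_along(sample_ids)),
             region = "dorsal", treatment = "CORT",
             fst_immobility_s = 100 + seq_along(sample_ids),
             nsf_latency_s = 200 + seq_along(sample_ids))
}

test_that("load_expression parses a well-formed study and validates inputs", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1.5, 2, 3, 4, 5.25, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("bdnf_a", "bdnf_b", "gapdh"), c("S1", "S2")))
  pres <- matrix(c("P", "A", "P", "P", "A", "A"), nrow = 3,
                 dimnames = dimnames(m))
  fx <- write_study_fixture(dir, m, demo_info(c("S1", "S2")), pres)

  got <- load_expression(fx$expr, fx$meta, present_path = fx$present)
  expect_identical(dim(got$expression), c(3L, 2L))
  expect_equal(got$expression["bdnf_b", "S2"], 4)
  expect_identical(got$info$sample_id, c("S1", "S2"))
  expect_equal(got$annotation$present_fraction, c(1, 0, 0.5))

  # a sample in the matrix but not the metadata is an error naming it
  colnames(m)[2] <- "S9"
  fx2 <- write_study_fixture(file.path(dir, "b"), m, demo_info("S1"))
  expect_error(load_expression(fx2$expr, fx2$meta), "S9")
  colnames(m)[2] <- "S2"

  # duplicated probe rows are an error naming the probe
  m2 <- m; rownames(m2) <- c("bdnf_a", "bdnf_a", "gapdh")
  ef <- file.path(dir, "dup.tsv")
  write.table(data.frame(probe_id = rownames(m2), m2, check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression(ef, fx$meta), "bdnf_a")

  # a non-numeric cell is an error locating the cell
  m3 <- matrix(c("1.5", "2", "oops", "4", "5", "6"), nrow = 3, byrow = TRUE,
               dimnames = list(c("p1", "p2", "p3"), c("S1", "S2")))
  ef3 <- file.path(dir, "bad.tsv")
  write.table(data.frame(probe_id = rownames(m3), m3, check.names = FALSE),
              ef3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression(ef3, fx$meta), "p2")
})

test_that("present_filter keeps probes strictly above the fraction cutoff", {
  frac <- c(1.0, 0.5, 0.4)
  m <- tiny_matrix(3, 4)
  ann <- data.frame(probe_id = rownames(m), gene_symbol = NA,
                    present_fraction = frac)
  expect_identical(rownames(present_filter(m, ann, 0.5)), rownames(m)[1])

  # min_fraction 0 with all fractions > 0 is the identity
  ann$present_fraction <- c(0.2, 0.9, 0.1)
  expect_identical(present_filter(m, ann, 0), m)

  # six probes, cutoff 0.5: exactly the three with fraction > 0.5 survive
  m6 <- tiny_matrix(6, 4)
  ann6 <- data.frame(probe_id = rownames(m6), gene_symbol = NA,
                     present_fraction = c(0.9, 0.9, 0.6, 0.5, 0.2, 0.0))
  expect_identical(rownames(present_filter(m6, ann6, 0.5)), rownames(m6)[1:3])

  expect_error(present_filter(m6, ann6[-1, ], 0.5), "without annotation")
})

test_that("filtering at two thresholds composes to the stricter threshold", {
  m <- tiny_matrix(20, 5)
  ann <- data.frame(probe_id = rownames(m), gene_symbol = NA,
                    present_fraction = seq(0, 1, length.out = 20))
  for (f in list(c(0.3, 0.7), c(0.7, 0.3), c(0.5, 0.5))) {
    twice <- present_filter(present_filter(m, ann, f[1]), ann, f[2])
    once <- present_filter(m, ann, max(f))
    expect_identical(twice, once)
  }
})

test_that("probe-to-gene summarization follows the weighted and centered-mean conventions", {
  m <- matrix(c(2, 2, 4, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("pA", "pB"), c("S1", "S2")))
  ann <- data.frame(probe_id = c("pA", "pB"), gene_symbol = "bdnf",
                    present_fraction = c(1.0, 0.5))
  got <- summarize_probes_to_genes(m, ann, "weighted_present")
  expect_equal(unname(got["bdnf", ]), c(8 / 3, 8 / 3))

  # single-probe gene is unchanged in either mode (up to centering)
  m1 <- matrix(c(5, 7), nrow = 1, dimnames = list("pX", c("S1", "S2")))
  ann1 <- data.frame(probe_id = "pX", gene_symbol = "actb",
                     present_fraction = 0.8)
  expect_equal(unname(summarize_probes_to_genes(m1, ann1, "weighted_present")["actb", ]),
               c(5, 7))
  expect_equal(unname(summarize_probes_to_genes(m1, ann1, "simple_mean")["actb", ]),
               c(-1, 1))   # centered row

  # three probes, weights 0.2/0.3/0.5: weighted value 2.3 per hand arithmetic
  m3 <- matrix(c(1, 1, 2, 2, 3, 3), nrow = 3, byrow = TRUE,
               dimnames = list(c("p1", "p2", "p3"), c("S1", "S2")))
  ann3 <- data.frame(probe_id = rownames(m3), gene_symbol = "g",
                     present_fraction = c(0.2, 0.3, 0.5))
  expect_equal(unname(summarize_probes_to_genes(m3, ann3, "weighted_present")["g", ]),
               c(2.3, 2.3))
  # centered-mean convention: rows centered then averaged, by hand all zeros
  expect_equal(unname(summarize_probes_to_genes(m3, ann3, "simple_mean")["g", ]),
               c(0, 0))

  # equal weights coincide with the plain mean of raw values
  ann3$present_fraction <- rep(0.7, 3)
  expect_equal(unname(summarize_probes_to_genes(m3, ann3, "weighted_present")["g", ]),
               unname(colMeans(m3)))

  # all-zero weights are an error listing the gene
  ann3$present_fraction <- 0
  expect_error(summarize_probes_to_genes(m3, ann3, "weighted_present"), "g")

  # unannotated probes are dropped with a count
  ann4 <- data.frame(probe_id = rownames(m3), gene_symbol = c("g", NA, "g"),
                     present_fraction = 0.5)
  expect_message(out <- summarize_probes_to_genes(m3, ann4, "weighted_present"),
                 "dropping 1")
  expect_equal(unname(out["g", ]), c(2, 2))
})

test_that("z-scoring standardizes rows and is affine-invariant", {
  m <- matrix(1:3, nrow = 1, dimnames = list("p1", c("S1", "S2", "S3")))
  expect_equal(unname(zscore_rows(m)[1, ]), c(-1, 0, 1))

  z <- zscore_rows(tiny_matrix(8, 5))
  expect_equal(unname(rowMeans(z)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 8), tolerance = 1e-12)
  # idempotence on standardized input
  expect_equal(zscore_rows(z), z, tolerance = 1e-12)

  # invariance under positive per-row affine maps
  m <- tiny_matrix(10, 6)
  a <- runif(10, 0.2, 5); b <- rnorm(10, 0, 10)
  expect_equal(zscore_rows(m * a + b), zscore_rows(m), tolerance = 1e-9)

  mc <- rbind(m, flat = rep(10, 6))
  expect_error(zscore_rows(mc), "flat")
  expect_warning(dropped <- drop_constant_rows(mc), "1 constant row")
  expect_identical(nrow(dropped), 10L)
})

test_that("log fold changes equal mean differences with Welch p-values", {
  m <- tiny_matrix(5, 6)
  treated <- colnames(m)[1:3]; control <- colnames(m)[4:6]

  shifted <- m; shifted[, treated] <- 5; shifted[, control] <- 4
  fc <- log_fold_change(shifted, treated, control)
  expect_equal(fc$log2_fc, rep(1, 5))

  # identical groups: zero fold change, p = 1
  same <- m; same[, control] <- same[, treated]
  fc0 <- log_fold_change(same, treated, control)
  expect_equal(fc0$log2_fc, rep(0, 5))
  expect_equal(fc0$p_value, rep(1, 5))
  expect_true(all(fc0$direction == 0))

  # Welch t and p match the textbook formula on a fixed integer fixture
  fix <- matrix(c(3, 5, 4, 9, 8, 10,
                  1, 1, 2, 2, 3, 5), nrow = 2, byrow = TRUE,
                dimnames = list(c("pA", "pB"), paste0("S", 1:6)))
  fcw <- log_fold_change(fix, paste0("S", 1:3), paste0("S", 4:6))
  for (i in 1:2) {
    o <- oracle_welch(fix[i, 1:3], fix[i, 4:6])
    expect_equal(fcw$t[i], o$t, tolerance = 1e-12)
    expect_equal(fcw$p_value[i], o$p, tolerance = 1e-12)
  }

  # antisymmetry under swapping the groups
  fcr <- log_fold_change(fix, paste0("S", 4:6), paste0("S", 1:3))
  expect_equal(fcr$log2_fc, -fcw$log2_fc)
  expect_equal(fcr$p_value, fcw$p_value)

  expect_error(log_fold_change(m, treated, c(control, treated[1])), "overlap")
  expect_message(one <- log_fold_change(m, treated[1], control), "single sample")
  expect_true(all(is.na(one$p_value)))
})
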