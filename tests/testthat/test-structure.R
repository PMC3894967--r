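# Connectivity, connectivity-state curve, Euclidean distance profile,
# per-probe state correlations and cross-region concordance.

make_scores <- function(z) compute_pca1(z)

test_that("connectivity counts significant cross-correlations per gene", {
  # two duplicated profiles among independent noise: only that pair connects
  base <- withr::with_seed(5, matrix(rnorm(8 * 12), 8, 12))
  raw <- rbind(g_dup1 = base[1, ], g_dup2 = base[1, ] * 2 + 1, base[2:8, ])
  rownames(raw)[3:9] <- paste0("g_noise", 1:7)
  colnames(raw) <- sprintf("S%02d", 1:12)
  z <- zscore_rows(raw)
  tab <- gene_connectivity(z, make_scores(z), alpha = 1e-6)
  expect_equal(tab$n_connections[tab$gene_id == "g_dup1"], 1L)
  expect_equal(tab$n_connections[tab$gene_id == "g_dup2"], 1L)
  expect_true(all(tab$n_connections[grep("noise", tab$gene_id)] == 0))

  # G identical genes: everything connects to everything else
  zi <- zscore_rows(matrix(rep(base[1, ], 6), 6, 12, byrow = TRUE,
                           dimnames = list(paste0("g", 1:6), sprintf("S%02d", 1:12))))
  ti <- gene_connectivity(zi, make_scores(zi))
  expect_true(all(ti$n_connections == 5L))
  expect_true(all(ti$connectivity == 5 / 6))

  expect_error(gene_connectivity(z[, 1:3], make_scores(z), alpha = 0.05),
               ">= 4 samples")
  expect_error(gene_connectivity(z, make_scores(z), max_genes = 1), "max_genes")
})

test_that("connectivity matches the per-pair cor.test oracle on small instances", {
  st <- small_study(seed = 6, n_probes = 60)
  z <- zprep(st$expression$dorsal)[1:15, 1:10]
  z <- zscore_rows(z)   # restandardize the sample subset
  sc <- compute_pca1(z)
  for (alpha in c(0.001, 0.05)) {
    tab <- gene_connectivity(z, sc, alpha = alpha)
    expect_identical(tab$n_connections, oracle_connectivity(z, alpha))
  }
  # per-gene state correlation p-values agree with cor.test too
  for (i in c(1, 7, 15)) {
    ct <- cor.test(z[i, ], sc$pca1)
    expect_equal(tab$r_with_pca1[i], unname(ct$estimate), tolerance = 1e-9)
    expect_equal(tab$p_with_pca1[i], ct$p.value, tolerance = 1e-9)
  }
})

test_that("null connectivity matches the adjacency alpha", {
  hits <- 0; pairs <- 0
  for (seed in 1:20) {
    z <- withr::with_seed(seed, matrix(rnorm(30 * 50), 30, 50))
    dimnames(z) <- list(paste0("g", 1:30), paste0("S", 1:50))
    z <- zscore_rows(z)
    tab <- gene_connectivity(z, make_scores(z), alpha = 0.001)
    hits <- hits + sum(tab$n_connections) / 2
    pairs <- pairs + choose(30, 2)
  }
  expect_lt(hits / pairs, 0.003)   # ~alpha, Poisson-bounded
})

test_that("seeded gene subsampling is reproducible and respects max_genes", {
  st <- small_study(seed = 8, n_probes = 300)
  z <- zprep(st$expression$dorsal)
  sc <- compute_pca1(z)
  t1 <- gene_connectivity(z, sc, max_genes = 50, seed = 3)
  t2 <- gene_connectivity(z, sc, max_genes = 50, seed = 3)
  expect_identical(t1, t2)
  expect_identical(nrow(t1), 50L)
  expect_true(all(t1$connectivity == t1$n_connections / 50))
})

test_that("the connectivity-state curve ranks more connected genes closer to PCA1", {
  # monotone identity: |r with PCA1| equals connectivity
  tab <- data.frame(gene_id = paste0("g", 1:50),
                    n_connections = 0:49, connectivity = (0:49) / 50,
                    r_with_pca1 = (0:49) / 50, p_with_pca1 = 0.5)
  cur <- connectivity_state_curve(tab, n_bins = 5)
  expect_equal(cur$spearman_r, 1)
  expect_identical(cur$bins$n, rep(10L, 5))
  expect_true(all(diff(cur$bins$mean_abs_r) > 0))

  # independent columns: near-zero association
  shuf <- tab
  shuf$r_with_pca1 <- withr::with_seed(2, sample(tab$r_with_pca1))
  expect_lt(abs(connectivity_state_curve(shuf)$spearman_r), 0.35)

  # generated latent-state data: heavy-loaded genes are both more
  # connected and more state-correlated
  st <- small_study(seed = 3, n_probes = 800)
  z <- zprep(st$expression$dorsal)
  sc <- compute_pca1(z)
  conn <- gene_connectivity(z, sc)
  cur2 <- connectivity_state_curve(conn)
  expect_gt(cur2$spearman_r, 0)

  # invariant to the sign of the state score
  flipped <- sc; flipped$pca1 <- -sc$pca1; flipped$loadings <- -sc$loadings
  conn_f <- gene_connectivity(z, flipped)
  expect_equal(connectivity_state_curve(conn_f)$spearman_r, cur2$spearman_r)

  const <- tab; const$connectivity <- 0.5
  expect_warning(one <- connectivity_state_curve(const), "single bin")
  expect_identical(nrow(one$bins), 1L)
})

test_that("distance from the lowest-state transcriptome is linear in PCA1", {
  # exact linearity on rank-1 data
  z <- rank1_z(u = rep(c(1, -1, 1, 1), 5), v = c(-3, -1, 0, 2, 5))
  sc <- compute_pca1(z)
  prof <- euclidean_profile(z, sc)
  expect_equal(unname(prof$distance[prof$reference_sample]), 0)
  expect_equal(prof$linearity_r, 1, tolerance = 1e-12)
  expect_identical(prof$reference_sample,
                   sc$sample_ids[which.min(sc$pca1)])

  # four-sample fixture against hand-computed distances
  zf <- zscore_rows(tiny_matrix(5, 4, seed = 13))
  scf <- compute_pca1(zf)
  pf <- euclidean_profile(zf, scf)
  ref <- pf$reference_sample
  for (s in colnames(zf))
    expect_equal(unname(pf$distance[s]),
                 sqrt(sum((zf[, s] - zf[, ref])^2)), tolerance = 1e-12)
  expect_true(all(pf$distance >= 0))
})

test_that("per-probe state correlations flag perfect and inverted trackers", {
  st <- small_study(seed = 5, n_probes = 100)
  z <- zprep(st$expression$dorsal)
  sc <- compute_pca1(z)
  s0 <- (sc$pca1 - mean(sc$pca1)) / sd(sc$pca1)
  z2 <- rbind(z, tracker = s0, inverse = -s0)
  tab <- pca1_gene_correlations(zscore_rows(z2), compute_pca1(zscore_rows(z2)))
  tr <- tab[tab$probe_id == "tracker", ]
  inv <- tab[tab$probe_id == "inverse", ]
  expect_gt(tr$r, 0.99); expect_true(tr$significant)
  expect_lt(inv$r, -0.99); expect_true(inv$significant)
  expect_equal(tab$r[match(rownames(z2), tab$probe_id)][1:nrow(z)],
               unname(drop(cor(t(z2[1:nrow(z), ]), compute_pca1(zscore_rows(z2))$pca1))),
               tolerance = 1e-9)
})

test_that("regional concordance matches hand enumeration", {
  mk <- function(lfc, p) data.frame(probe_id = paste0("p", seq_along(lfc)),
                                    log2_fc = lfc, t = NA, p_value = p,
                                    direction = sign(lfc))
  # identical tables: perfect agreement
  a <- mk(c(1, -1, 0.5, -2), c(0.01, 0.2, 0.03, 0.5))
  expect_id <- regional_concordance(a, a)
  expect_equal(expect_id$pearson_r_fc, 1)
  expect_equal(expect_id$pct_same_dir_any, 100)
  expect_equal(expect_id$pct_same_dir_both, 100)

  # mirrored tables with everything significant: total disagreement
  b <- mk(-c(1, -1, 0.5, -2), rep(0.001, 4))
  all_sig <- mk(c(1, -1, 0.5, -2), rep(0.001, 4))
  opp <- regional_concordance(all_sig, b)
  expect_equal(opp$pearson_r_fc, -1)
  expect_equal(opp$pct_same_dir_any, 0)
  expect_equal(opp$pct_same_dir_both, 0)

  # ten probes with a known significance/direction pattern, enumerated by hand:
  # probe:        1     2     3     4     5     6     7     8     9    10
  # dorsal lfc:  +1    +1    -1    -1    +1    -1    +1     0    +1    -1
  # ventral lfc: +1    -1    -1    +1    +1    -1    -1    +1    +1    +1
  # dorsal sig:   T     T     T     F     F     F     T     T     F     F
  # ventral sig:  T     F     T     T     F     F     F     T     F     F
  d <- mk(c(1, 1, -1, -1, 1, -1, 1, 0, 1, -1),
          c(.01, .01, .01, .9, .9, .9, .01, .01, .9, .9))
  v <- mk(c(1, -1, -1, 1, 1, -1, -1, 1, 1, 1),
          c(.01, .9, .01, .01, .9, .9, .9, .01, .9, .9))
  got <- regional_concordance(d, v)
  # sig any: probes 1,2,3,4,7,8 -> 60%; sig both: 1,3,8 -> 30%
  expect_equal(got$pct_sig_any, 60)
  expect_equal(got$pct_sig_both, 30)
  # probe 8 undirected (dorsal lfc 0) -> excluded; among sig-any {1,2,3,4,7}:
  # same dir 1,3 -> 40%; among sig-both {1,3}: 100%
  expect_equal(got$n_zero_fc_excluded, 1L)
  expect_equal(got$pct_same_dir_any, 40)
  expect_equal(got$pct_same_dir_both, 100)
  expect_lte(got$pct_sig_both, got$pct_sig_any)

  expect_error(regional_concordance(a, mk(1:3, rep(0.5, 3))), "different probes")
})

test_that("distance linearity improves monotonically as generator noise shrinks", {
  rs <- sapply(c(1.5, 0.5, 0.05), function(ns) {
    st <- generate_study(generator_params(seed = 7, n_probes = 600,
                                          noise_sd = ns))
    z <- zprep(st$expression$dorsal)
    sc <- compute_pca1(z)
    euclidean_profile(z, sc)$linearity_r
  })
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.95)
  # in the exactly noiseless limit the unlinked probes go flat, are
  # dropped, and the profile is perfectly linear
  st0 <- generate_study(generator_params(seed = 7, n_probes = 600,
                                         noise_sd = 0))
  z0 <- zprep(st0$expression$dorsal)
  sc0 <- compute_pca1(z0)
  expect_equal(euclidean_profile(z0, sc0)$linearity_r, 1, tolerance = 1e-9)
})
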