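test_that("M-value transform is a symmetric offset log-ratio", {
  expect_equal(mvalue_transform(500, 500), 0)
  expect_equal(mvalue_transform(3000, 1000), log2(3001 / 1001))
  expect_equal(mvalue_transform(3000, 1000), 1.584, tolerance = 1e-3)
  expect_equal(mvalue_transform(0, 0), 0)
  expect_error(mvalue_transform(-1, 10), "negative")
})

test_that("detection filtering drops probes then samples at strict thresholds", {
  set.seed(1)
  m <- matrix(rnorm(20000), 200, 100,
              dimnames = list(paste0("cg", 1:200), paste0("S", 1:100)))
  dp <- matrix(0, 200, 100, dimnames = dimnames(m))
  out0 <- detection_filter(m, dp)
  expect_identical(out0$m, m)

  dp1 <- dp
  dp1["cg1", 1:6] <- 1        # probe call rate 0.94 < 0.95 -> dropped
  dp1["cg2", 10] <- 1         # 0.99 -> retained; surviving failed call -> NA
  out1 <- detection_filter(m, dp1)
  expect_identical(out1$report$probes_dropped_detection, "cg1")
  expect_true(is.na(out1$m["cg2", "S10"]))
  expect_false("S10" %in% out1$report$samples_dropped_call_rate)

  dp2 <- dp
  dp2[1:4, 1] <- 1            # sample S1 fails 4/200 = 2% > 1% -> dropped
  out2 <- detection_filter(m, dp2)
  expect_identical(out2$report$samples_dropped_call_rate, "S1")
  expect_false("S1" %in% colnames(out2$m))
  expect_length(out2$report$probes_dropped_detection, 0)
})

test_that("KNN imputation fills from nearest probes and never alters observed values", {
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("cg", 1:6), paste0("S", 1:10)))
  expect_identical(knn_impute(m, 10), m)

  # exact duplicate probe: with k = 1 the copy (distance 0) supplies the value
  m2 <- m
  m2[2, ] <- m2[1, ]
  m2[1, 4] <- NA
  imp <- knn_impute(m2, k = 1)
  expect_equal(imp[1, 4], m2[2, 4])

  # constant neighbourhood: all neighbours read 5 at the missing sample
  m3 <- rbind(target = c(NA, 1, 2, 3),
              n1 = c(5, 1.1, 2.1, 3.1),
              n2 = c(5, 0.9, 1.9, 2.9),
              n3 = c(5, 1.0, 2.0, 3.0))
  expect_equal(unname(knn_impute(m3, k = 3)["target", 1]), 5)

  # observed entries are untouched (property over random hole patterns)
  set.seed(9)
  for (rep in 1:20) {
    mm <- matrix(rnorm(80), 8, 10)
    rownames(mm) <- paste0("p", 1:8)
    holes <- matrix(runif(80) < 0.1, 8, 10)
    mm_h <- mm
    mm_h[holes] <- NA
    out <- knn_impute(mm_h, k = 3)
    expect_identical(out[!holes], mm[!holes])
    expect_false(anyNA(out))
  }

  expect_error(knn_impute(m, k = 0), "k must be")
  m_bad <- m
  m_bad[1, ] <- NA
  expect_error(knn_impute(m_bad, 3), "cg1")
})

test_that("EB batch adjustment removes an injected shift and preserves pooled means", {
  set.seed(13)
  G <- 500; n <- 200
  delta <- 0.8
  batch <- rep(1:2, each = n / 2)
  m <- matrix(rnorm(G * n), G, n)
  m[, batch == 2] <- m[, batch == 2] + delta
  rownames(m) <- paste0("cg", seq_len(G))

  adj <- eb_batch_adjust(m, batch)
  # systematic (probe-averaged) residual shift; per-probe differences keep
  # their pre-injection sampling noise
  gap <- abs(mean(rowMeans(adj[, batch == 2]) - rowMeans(adj[, batch == 1])))
  expect_lt(gap, 0.05 * delta)
  # pooled probe means are preserved exactly (recentring step)
  expect_equal(rowMeans(adj), rowMeans(m), tolerance = 1e-6)

  # second pass changes values far less than the first (near-idempotence)
  adj2 <- eb_batch_adjust(adj, batch)
  first_change <- max(abs(adj - m))
  second_change <- max(abs(adj2 - adj))
  expect_lt(second_change, first_change / 10)

  # single level is a no-op; singleton levels are an error naming the level
  expect_equal(eb_batch_adjust(m, rep(1, n)), m, tolerance = 1e-8)
  expect_error(eb_batch_adjust(m, c(rep(1, n - 1), 9)), "9")
})

test_that("EB batch adjustment agrees with an independent ComBat run on shift removal", {
  skip_if_not_installed("sva")
  set.seed(14)
  G <- 200; n <- 100
  batch <- rep(1:2, each = n / 2)
  m <- matrix(rnorm(G * n), G, n)
  m[, batch == 2] <- m[, batch == 2] + 0.6
  rownames(m) <- paste0("cg", seq_len(G))
  ours <- eb_batch_adjust(m, batch)
  theirs <- suppressMessages(sva::ComBat(m, batch))
  gap <- function(x) abs(mean(rowMeans(x[, batch == 2]) -
                                rowMeans(x[, batch == 1])))
  expect_lt(gap(ours), 0.05 * 0.6)
  expect_lt(gap(theirs), 0.05 * 0.6)
  # the two adjusted matrices agree closely probe-wise
  expect_lt(mean(abs(ours - theirs)), 0.05)
})

test_that("3-IQR trimming removes only fence-crossing values in one pass", {
  m <- matrix(rnorm(200), 10, 20)
  rownames(m) <- paste0("cg", 1:10)
  out <- iqr_trim(m, 3)
  expect_identical(out$n_trimmed, 0L)

  # 11-value fixture: quartiles 2.5 / 7.5, fences [-12.5, 22.5]
  row <- c(0:9, 10000)
  m2 <- matrix(row, 1, 11, dimnames = list("cgX", NULL))
  out2 <- iqr_trim(m2, 3)
  expect_identical(out2$n_trimmed, 1L)
  expect_true(is.na(out2$m[1, 11]))
  expect_equal(out2$m[1, 1:10], m2[1, 1:10])

  m3 <- matrix(7, 1, 20, dimnames = list("cgC", NULL))
  expect_identical(iqr_trim(m3, 3)$n_trimmed, 0L)
})

test_that("blacklist filtering removes sex-chromosome and listed probes once", {
  m <- matrix(rnorm(40), 4, 10)
  rownames(m) <- c("cgA", "cgB", "cgC", "cgD")
  info <- data.frame(id = rownames(m),
                     chrom = c("chrX", "chr2", "chr3", "chr4"),
                     pos = 1:4)
  out <- blacklist_filter(m, info, snp_probes = c("cgC"),
                          cross_reactive = c("cgC", "cgD"))
  expect_identical(rownames(out$m), "cgB")
  expect_identical(sort(out$probes_dropped), c("cgA", "cgC", "cgD"))
})

test_that("cell deconvolution recovers pure, mixed and noisy compositions", {
  set.seed(15)
  R <- matrix(rnorm(98 * 7, 0, 2), 98, 7,
              dimnames = list(paste0("ref", 1:98), cell_types()))
  # pure sample
  m1 <- matrix(R[, 3], ncol = 1, dimnames = list(rownames(R), "S1"))
  w1 <- estimate_cell_proportions(m1, R)
  expect_equal(unname(w1[1, 3]), 1, tolerance = 1e-9)

  # noiseless 50/50 mixture
  m2 <- matrix(0.5 * R[, 1] + 0.5 * R[, 2], ncol = 1,
               dimnames = list(rownames(R), "S1"))
  w2 <- estimate_cell_proportions(m2, R)
  expect_equal(unname(w2[1, 1:2]), c(0.5, 0.5), tolerance = 1e-6)

  # non-negativity and unit sum on noisy Dirichlet mixtures
  W <- t(vapply(1:50, function(i) {
    g <- rgamma(7, c(1.8, 16.5, 2.4, 0.9, 1.5, 4.5, 2.4))
    g / sum(g)
  }, numeric(7)))
  M <- R %*% t(W) + matrix(rnorm(98 * 50, 0, 0.1), 98, 50)
  colnames(M) <- paste0("S", 1:50)
  West <- estimate_cell_proportions(M, R)
  expect_true(all(West >= 0))
  expect_equal(unname(rowSums(West)), rep(1, 50), tolerance = 1e-9)
  expect_lt(mean(abs(West - W)), 0.05)

  Rbad <- R
  Rbad[, 2] <- Rbad[, 1]
  expect_error(estimate_cell_proportions(m1, Rbad), "rank")
})

test_that("the methylation QC chain applies its stages in the documented order", {
  sim <- simulate_study(simulation_config(n_samples = 80, seed = 19))
  ds <- sim$dataset
  out <- qc_methylation(
    ds$meth, sim$detection_p,
    batch = setNames(sim$batch$batch, sim$batch$sample_id),
    position = setNames(sim$batch$position, sim$batch$sample_id),
    cpg_info = ds$cpg_info, reference = sim$reference,
    snp_probes = ds$cpg_info$id[1]
  )
  expect_true(ds$cpg_info$id[1] %in% out$report$probes_dropped_blacklist)
  expect_false(ds$cpg_info$id[1] %in% rownames(out$m))
  expect_named(out$report, c("probes_dropped_detection",
                             "samples_dropped_call_rate",
                             "probes_dropped_blacklist",
                             "values_trimmed_count", "imputed_count"))
  expect_equal(unname(rowSums(out$cell_proportions)),
               rep(1, nrow(out$cell_proportions)), tolerance = 1e-9)
})
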