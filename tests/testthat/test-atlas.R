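test_that("tpm_filter keeps transcripts above 10 TPM in more than 6 samples", {
  n <- 94
  tpm <- rbind(
    seven = c(rep(10.5, 7), rep(1, n - 7)),   # > 10 in 7 samples -> kept
    six = c(rep(10.5, 6), rep(1, n - 6)),     # > 10 in 6 samples -> dropped
    edge = c(rep(10, 7), rep(1, n - 7))       # exactly 10 never exceeds
  )
  colnames(tpm) <- paste0("s", seq_len(n))
  atlas <- small_atlas(tpm)
  kept <- rownames(tpm_filter(atlas)$tpm)
  expect_equal(kept, "seven")
  expect_error(tpm_filter(atlas, min_tpm = -1), "min_tpm")
  # empty atlas passes through
  e <- small_atlas(matrix(numeric(0), 0, n,
                          dimnames = list(NULL, colnames(tpm))))
  expect_equal(nrow(tpm_filter(e)$tpm), 0)
})

test_that("tpm_filter matches a brute-force exceedance count and is monotone", {
  set.seed(42)
  tpm <- matrix(rexp(20 * 94, rate = 1 / 12), 20, 94,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:94)))
  atlas <- small_atlas(tpm)
  for (ms in c(3, 6, 10)) {
    kept <- rownames(tpm_filter(atlas, 10, ms)$tpm)
    oracle <- rownames(tpm)[vapply(seq_len(20), function(i)
      sum(tpm[i, ] > 10) > ms, logical(1))]
    expect_equal(kept, oracle)
  }
  k1 <- rownames(tpm_filter(atlas, 10, 6)$tpm)
  k2 <- rownames(tpm_filter(atlas, 15, 6)$tpm)
  k3 <- rownames(tpm_filter(atlas, 10, 12)$tpm)
  expect_true(all(k2 %in% k1))
  expect_true(all(k3 %in% k1))
})

test_that("ppm normalization scales columns to one million and is idempotent", {
  raw <- metabolite_matrix(matrix(c(2, 2, 2, 2,
                                    5, 0, 1, 4,
                                    0, 0, 0, 0), 4, 3,
                                  dimnames = list(paste0("m", 1:4),
                                                  paste0("s", 1:3))))
  expect_warning(ppm <- metabolites_to_ppm(raw), "all-zero")
  expect_true(ppm$normalized)
  expect_equal(ppm$values[, 1], setNames(rep(250000, 4), paste0("m", 1:4)))
  expect_equal(sum(ppm$values[, 2]), 1e6)
  expect_equal(unname(ppm$values[, 3]), rep(0, 4))
  expect_equal(attr(ppm, "zero_columns"), "s3")
  # idempotent on normalized input
  again <- suppressWarnings(metabolites_to_ppm(ppm))
  expect_equal(again$values, ppm$values, tolerance = 1e-12)
  # random matrix: every nonzero column sums to 1e6
  set.seed(1)
  r <- metabolite_matrix(matrix(runif(15), 5, 3,
                                dimnames = list(paste0("m", 1:5),
                                                paste0("s", 1:3))))
  expect_equal(unname(colSums(metabolites_to_ppm(r)$values)), rep(1e6, 3))
  expect_error(metabolite_matrix(matrix(-1, 1, 1)), "non-negative")
})

test_that("replicate correlation recovers exact closed-form values", {
  # two identical replicates -> r = 1; a pair with hand-computable r
  x <- c(1, 5, 9)
  y <- c(2, 4, 9)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tpm <- cbind(a1 = 2^x - 1, a2 = 2^x - 1, b1 = 2^x - 1, b2 = 2^y - 1)
  rownames(tpm) <- paste0("t", 1:3)
  atlas <- small_atlas(tpm, tissues = c("A", "A", "B", "B"),
                       replicates = c(1, 2, 1, 2))
  rc <- replicate_correlation(atlas)
  expect_equal(unname(rc$per_tissue["A"]), 1)
  expect_equal(unname(rc$per_tissue["B"]), r_oracle, tolerance = 1e-12)
  expect_equal(rc$mean, mean(c(1, r_oracle)), tolerance = 1e-12)
  # global affine transform of one replicate leaves r unchanged
  tpm2 <- tpm
  tpm2[, "b2"] <- 2^(2 * y + 3) - 1
  rc2 <- replicate_correlation(small_atlas(tpm2,
                                           tissues = c("A", "A", "B", "B"),
                                           replicates = c(1, 2, 1, 2)))
  expect_equal(unname(rc2$per_tissue["B"]), r_oracle, tolerance = 1e-12)
  # single-replicate tissue excluded with a warning
  atlas3 <- small_atlas(tpm[, 1:3], tissues = c("A", "A", "B"),
                        replicates = c(1, 2, 1))
  expect_warning(rc3 <- replicate_correlation(atlas3), "single replicate")
  expect_named(rc3$per_tissue, "A")
})

test_that("MDS projection respects distance symmetry and duplicates", {
  # three mutually equidistant samples -> equilateral triangle
  set.seed(3)
  base <- scale(matrix(rnorm(300), 100, 3), center = TRUE, scale = FALSE)
  v <- qr.Q(qr(base))   # centered orthonormal columns: pairwise r exactly 0
  tpm <- 2^(v * 2 + 8) - 1
  colnames(tpm) <- paste0("s", 1:3)
  rownames(tpm) <- paste0("t", 1:100)
  atlas <- small_atlas(tpm)
  xy <- mds_projection(atlas)
  d <- dist(xy)
  expect_lt(max(d) - min(d), 1e-6)
  # duplicated samples map to identical coordinates
  tpm2 <- cbind(tpm, s4 = tpm[, 3])
  xy2 <- mds_projection(small_atlas(tpm2))
  expect_equal(xy2["s3", ], xy2["s4", ], tolerance = 1e-9)
  # two correlated groups separate along dimension 1 (positive silhouette)
  g1 <- rnorm(100)
  g2 <- rnorm(100)
  mk <- function(g) 2^(g + rnorm(100, 0, 0.1) + 8)
  tpm3 <- cbind(a1 = mk(g1), a2 = mk(g1), a3 = mk(g1),
                b1 = mk(g2), b2 = mk(g2), b3 = mk(g2))
  rownames(tpm3) <- paste0("t", 1:100)
  xy3 <- mds_projection(small_atlas(tpm3))
  lab <- rep(c(1, 2), each = 3)
  sil <- vapply(1:6, function(i) {
    dd <- as.matrix(dist(xy3))[i, ]
    a <- mean(dd[setdiff(which(lab == lab[i]), i)])
    b <- mean(dd[lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("synthetic default atlas reproduces realistic replicate concordance", {
  rc <- replicate_correlation(the_study()$atlas)
  expect_gt(rc$mean, 0.8)
  expect_lt(rc$mean, 1)
  expect_length(rc$per_tissue, 16)
})
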