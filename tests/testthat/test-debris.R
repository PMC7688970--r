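totals_matrix <- function(totals) {
  # one gene per barcode carrying the whole total: controls rowSums exactly
  m <- Matrix::sparseMatrix(i = seq_along(totals), j = seq_along(totals),
                            x = totals)
  dimnames(m) <- list(paste0("b", seq_along(totals)),
                      paste0("g", seq_along(totals)))
  m
}

test_that("UMI threshold is the largest grid value retaining more than expected", {
  m <- totals_matrix(c(400, 300, 200, 40, 5))
  out <- select_umi_threshold(m, expected_cells = 2)
  expect_equal(out$threshold, 200)   # 3 barcodes >= 200 > 2; at 250 only 2
  expect_equal(sum(out$retained), 3)
  # expected_cells = 0: largest threshold with at least one barcode above
  out0 <- select_umi_threshold(m, expected_cells = 0)
  expect_equal(out0$threshold, 400)
  expect_error(select_umi_threshold(m, expected_cells = 10),
               "fewer barcodes")
})

test_that("dropoff traces are an exact census on the UMI grid", {
  m <- totals_matrix(c(100, 160, 240))
  tr <- compute_dropoff_traces(m, labels = setNames(rep(1, 3),
                                                    rownames(m)))
  expect_equal(tr$thresholds, seq(0, 250, by = 50))
  expect_equal(unname(tr$remaining[1, ]), c(3, 3, 2, 2, 1, 0))
  # all-equal totals: a single step down
  m2 <- totals_matrix(rep(100, 4))
  tr2 <- compute_dropoff_traces(m2, setNames(rep(1, 4), rownames(m2)))
  expect_equal(unname(tr2$remaining[1, ]), c(4, 4, 0, 0))
  # singleton cluster: normalized trace only takes values 1 and 0
  m3 <- totals_matrix(c(100, 300))
  tr3 <- compute_dropoff_traces(m3, setNames(1:2, rownames(m3)))
  expect_true(all(tr3$normalized %in% c(0, 1)))
})

test_that("traces are non-increasing for arbitrary inputs", {
  set.seed(77)
  for (rep in 1:5) {
    totals <- sample(0:2000, 60, replace = TRUE)
    totals[1] <- max(totals) + 1   # avoid all-zero degenerate grid
    m <- totals_matrix(totals)
    labels <- setNames(sample(1:4, 60, replace = TRUE), rownames(m))
    tr <- compute_dropoff_traces(m, labels)
    expect_true(all(apply(tr$remaining, 1, function(r) all(diff(r) <= 0))))
    expect_true(all(tr$normalized[, 1] == 1))
  }
})

test_that("trace classification: extreme dropoff is debris, ties break by id", {
  tr <- structure(list(
    thresholds = seq(0, 200, 50),
    normalized = rbind(`1` = c(1, 0, 0, 0, 0), `2` = c(1, 1, 1, 1, 1))),
    class = "dropoff_traces")
  cls <- classify_trace_groups(tr)
  expect_equal(unname(cls["1"]), "debris")
  expect_equal(unname(cls["2"]), "cells")
  # identical traces: no debris called, with a warning
  tr2 <- structure(list(thresholds = seq(0, 200, 50),
                        normalized = rbind(`1` = rep(1, 5),
                                           `2` = rep(1, 5))),
                   class = "dropoff_traces")
  expect_warning(cls2 <- classify_trace_groups(tr2), "identical")
  expect_true(all(cls2 == "cells"))
  # equal AUC, different shape: the group holding the lower id is debris
  tr3 <- structure(list(thresholds = seq(0, 200, 50),
                        normalized = rbind(`1` = c(1, 1, 0, 0, 0),
                                           `2` = c(1, 0.5, 0.5, 0, 0))),
                   class = "dropoff_traces")
  cls3 <- classify_trace_groups(tr3)
  expect_equal(unname(cls3["1"]), "debris")
})

test_that("two separable blobs are recovered exactly at k = 2", {
  set.seed(12)
  a <- matrix(rpois(40 * 30, 2), 40, 30)
  b <- cbind(matrix(rpois(40 * 15, 60), 40, 15),
             matrix(rpois(40 * 15, 1), 40, 15))
  m <- Matrix::Matrix(rbind(a, b), sparse = TRUE)
  dimnames(m) <- list(paste0("b", 1:80), paste0("g", 1:30))
  cl <- cluster_retained(m, k_range = 2:2)
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$labels[1:40])), 1)
  expect_equal(length(unique(cl$labels[41:80])), 1)
  expect_error(cluster_retained(m, k_range = 1:3), "k_range")
})

test_that("duplicated rows yield a reported degeneracy, not an arbitrary k", {
  m <- Matrix::Matrix(matrix(rep(c(5, 0, 2), each = 30), 30, 3),
                      sparse = TRUE)
  dimnames(m) <- list(paste0("b", 1:30), paste0("g", 1:3))
  expect_warning(cl <- cluster_retained(m, k_range = 2:4), "degenerate")
  expect_true(cl$degenerate)
})

test_that("full debris call partitions the barcodes and removes planted debris", {
  sim <- generate_dataset(scenario_debris(seed = 2))
  n_cells <- sum(!sim$annotation$is_debris)
  dc <- remove_debris(sim$counts, expected_cells = round(1.25 * n_cells))
  expect_equal(length(dc$call), nrow(sim$counts))
  expect_equal(sum(table(dc$call)), nrow(sim$counts))  # partition
  deb <- sim$annotation$is_debris
  expect_gte(mean(dc$call[deb] != "keep"), 0.9)
  expect_lte(mean(dc$call[!deb] != "keep"), 0.05)
  # no removed cluster has median UMI above the kept median
  totals <- Matrix::rowSums(sim$counts)
  kept_med <- median(totals[dc$call == "keep"])
  for (cl in names(dc$cluster_class)[dc$cluster_class == "debris"]) {
    in_cl <- names(dc$cluster_labels)[dc$cluster_labels == as.integer(cl)]
    expect_lt(median(totals[in_cl]), kept_med)
  }
})
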