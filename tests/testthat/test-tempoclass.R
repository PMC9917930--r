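# build a one-timepoint result stub
tp_res <- function(lfc, p_adj, mean_ctrl = 500, mean_trt = 500)
  list(logFC = lfc, p_adj = p_adj, mean_ctrl = mean_ctrl,
       mean_trt = mean_trt)

SIG <- 0.001
NS <- 0.5

test_that("the decision table reproduces the named temporal categories", {
  cc <- classifier_config()
  expect_equal(classify_probe(tp_res(1, SIG), tp_res(1, SIG),
                              tp_res(1, SIG), cc)$category, "LONG_LASTING")
  expect_equal(classify_probe(tp_res(1, SIG), tp_res(0.2, NS),
                              tp_res(-1, SIG), cc)$category, "REVERSAL")
  expect_equal(classify_probe(tp_res(0.1, NS), tp_res(1, SIG),
                              tp_res(0.1, NS), cc)$category, "SECONDARY")
  expect_equal(classify_probe(tp_res(1, SIG), tp_res(1, SIG),
                              tp_res(0.1, NS), cc)$category, "INTERMEDIATE")
  expect_equal(classify_probe(tp_res(1, SIG), tp_res(0.1, NS),
                              tp_res(0.1, NS), cc)$category, "SHORT")
  expect_equal(classify_probe(tp_res(1, SIG), tp_res(0.1, NS),
                              tp_res(1, SIG), cc)$category, "COMPLEX")
  expect_equal(classify_probe(tp_res(1, NS), tp_res(1, NS),
                              tp_res(1, NS), cc)$category, "NULL")
  # a reversal beats long-lasting when a later sign flips
  expect_equal(classify_probe(tp_res(1, SIG), tp_res(-1, SIG),
                              tp_res(1, SIG), cc)$category, "REVERSAL")
  expect_error(classify_probe(list(logFC = 1), tp_res(1, SIG),
                              tp_res(1, SIG), cc), "p_adj")
})

test_that("the decision table is total and mutually exclusive", {
  cc <- classifier_config()
  states <- list(c(NA, NS), c(1, SIG), c(-1, SIG))  # ns, sig+, sig-
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    mk <- function(s) tp_res(if (is.na(s[1])) 0.1 else s[1], s[2])
    call <- classify_probe(mk(states[[i]]), mk(states[[j]]),
                           mk(states[[k]]), cc)
    expect_length(call$category, 1)
    expect_true(call$category %in% c("LONG_LASTING", "INTERMEDIATE",
                                     "SHORT", "REVERSAL", "SECONDARY",
                                     "COMPLEX", "NULL"))
  }
})

test_that("magnitude bins honour the printed thresholds and boundaries", {
  cc <- classifier_config()
  expect_equal(as.character(assign_magnitude_bin(0.32, cc)), "<=25%")
  expect_equal(as.character(assign_magnitude_bin(-0.32, cc)), "<=25%")
  expect_equal(as.character(assign_magnitude_bin(0.33, cc)), "25-50%")
  expect_equal(as.character(assign_magnitude_bin(0.5, cc)), "25-50%")
  expect_equal(as.character(assign_magnitude_bin(0.58, cc)), "25-50%")
  expect_equal(as.character(assign_magnitude_bin(0.9, cc)), "50-100%")
  expect_equal(as.character(assign_magnitude_bin(1.0, cc)), "50-100%")
  expect_equal(as.character(assign_magnitude_bin(1.5, cc)), ">100%")
  expect_error(assign_magnitude_bin(NaN, cc), "finite")
})

test_that("the binning timepoint follows the category", {
  cc <- classifier_config()
  ll <- classify_probe(tp_res(2, SIG), tp_res(1.5, SIG), tp_res(0.7, SIG),
                       cc)
  expect_equal(ll$bin_timepoint, "h9")
  expect_equal(ll$magnitude_bin, "50-100%")
  im <- classify_probe(tp_res(2, SIG), tp_res(0.5, SIG), tp_res(0, NS),
                       cc)
  expect_equal(im$bin_timepoint, "h5")
  expect_equal(im$magnitude_bin, "25-50%")
  sh <- classify_probe(tp_res(1.2, SIG), tp_res(0, NS), tp_res(0, NS), cc)
  expect_equal(sh$bin_timepoint, "h1")
  expect_equal(sh$magnitude_bin, ">100%")
})

test_that("low-intensity flag averages over all compared groups", {
  expect_true(apply_intensity_filter(rep(49.9, 6)))
  expect_false(apply_intensity_filter(c(40, 80)))
  expect_false(apply_intensity_filter(c(100, 100), cutoff = 0))
  expect_error(apply_intensity_filter(c(-1, 2)), ">= 0")
})

test_that("classification is invariant to probe order and monotone in alpha", {
  sr <- small_run()
  calls <- classify_probes(sr$de)
  shuffled <- sr$de$results[sample(nrow(sr$de$results)), ]
  calls2 <- classify_probes(shuffled)
  calls2 <- calls2[match(calls$probe_id, calls2$probe_id), ]
  rownames(calls2) <- NULL
  expect_equal(calls2, calls)
  loose <- classify_probes(sr$de, classifier_config(alpha = 0.2))
  # probes non-NULL at the stricter alpha remain non-NULL when loosened
  strict_non_null <- calls$probe_id[calls$category != "NULL"]
  expect_true(all(loose$category[match(strict_non_null,
                                       loose$probe_id)] != "NULL"))
})

test_that("gene consolidation excludes unusable annotations with reasons", {
  calls <- data.frame(
    probe_id = paste0("p", 1:6),
    category = c("LONG_LASTING", "LONG_LASTING", "LONG_LASTING",
                 "SHORT", "LONG_LASTING", "NULL"),
    stringsAsFactors = FALSE)
  annot <- data.frame(
    probe_id = paste0("p", 1:6),
    status = c("consistent", "consistent", "consistent",
               "consistent", "multi_gene", "inconsistent"),
    consensus_symbol = c("GeneA", "GeneA", "GeneA", "GeneB", NA, NA),
    stringsAsFactors = FALSE)
  out <- consolidate_genes(calls, annot)
  expect_equal(nrow(out$genes), 2)
  a <- out$genes[out$genes$gene == "GeneA", ]
  expect_equal(a$n_probes, 3)
  expect_equal(a$categories, "LONG_LASTING")
  expect_equal(out$excluded[["multi-gene"]], 1L)
  expect_equal(out$excluded[["inconsistent"]], 1L)
  # probes of one gene with split categories keep both
  calls2 <- calls[calls$probe_id %in% c("p1", "p4"), ]
  annot2 <- annot[annot$probe_id %in% c("p1", "p4"), ]
  annot2$consensus_symbol <- "GeneC"
  out2 <- consolidate_genes(calls2, annot2)
  expect_equal(out2$genes$categories, "LONG_LASTING;SHORT")
})

test_that("recovery scoring is exact for perfect calls and strict on IDs", {
  truth <- data.frame(probe_id = paste0("p", 1:10),
                      pattern = rep(c("LONG_LASTING", "SHORT", "NULL",
                                      "SECONDARY", "REVERSAL"), 2),
                      stringsAsFactors = FALSE)
  calls <- data.frame(probe_id = truth$probe_id,
                      category = truth$pattern,
                      stringsAsFactors = FALSE)
  sc <- score_recovery(calls, truth)
  expect_true(all(sc$recall[unique(truth$pattern)] == 1))
  expect_true(all(sc$precision[unique(truth$pattern)] == 1))
  off <- sum(sc$confusion) - sum(diag(sc$confusion[, rownames(sc$confusion)]))
  expect_equal(off, 0)
  calls$probe_id[1] <- "zzz"
  expect_error(score_recovery(calls, truth), "IDs")
})

test_that("planted strong patterns are recovered on bright probes", {
  sr <- small_run()
  calls <- classify_probes(sr$de)
  truth <- sr$sim$truth
  hi <- truth$intensity_class == "high"
  sc <- score_recovery(calls[match(truth$probe_id[hi], calls$probe_id), ],
                       truth[hi, ])
  # ~20 bright probes per pattern in this fixture (binomial SE ~ 0.08);
  # the full-size recovery benchmark lives in the acceptance suite
  expect_gte(sc$recall[["LONG_LASTING"]], 0.85)
  expect_gte(sc$recall[["SHORT"]], 0.85)
  expect_gte(sc$recall[["NULL"]], 0.95)
})
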