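mk_calls <- function(...) {
  rows <- list(...)
  d <- do.call(rbind, lapply(rows, function(r)
    data.frame(transcript_id = r[[1]], conditioning_type = r[[2]],
               time_point = r[[3]], direction = r[[4]],
               logFC = if (r[[4]] == "up") 1 else -1, p_value = 0.01,
               significant = TRUE, stringsAsFactors = FALSE)))
  d
}

map4 <- data.frame(transcript_id = c("g1_t1", "g1_t2", "g2_t1", "g3_t1"),
                   gene_id = c("g1", "g1", "g2", "g3"),
                   stringsAsFactors = FALSE)

test_that("gene summaries pool time points and keep splice variants apart", {
  calls <- mk_calls(list("g1_t1", "Glo-LTM-long", "15m", "up"),
                    list("g1_t1", "Glo-LTM-long", "4h", "up"),
                    list("g1_t2", "Glo-ARM", "1h", "down"))
  s <- summarize_gene_de(calls, map4)
  row <- s[s$transcript_id == "g1_t1", ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$time_points, "15m,4h")
  expect_setequal(s$conditioning_type[s$gene_id == "g1"],
                  c("Glo-LTM-long", "Glo-ARM"))
  # insignificant calls vanish; missing mappings are an error
  none <- calls; none$significant <- FALSE
  expect_identical(nrow(summarize_gene_de(none, map4)), 0L)
  expect_error(summarize_gene_de(mk_calls(list("zz_t1", "Glo-ARM", "1h", "up")),
                                 map4), "mapping")
})

test_that("the opposing predicate quantifies over all shared transcripts", {
  s <- summarize_gene_de(mk_calls(list("g1_t1", "A", "1h", "up"),
                                  list("g1_t1", "B", "1h", "down")), map4)
  expect_true(detect_opposing(s, "A", "B"))
  s2 <- summarize_gene_de(mk_calls(list("g1_t1", "A", "1h", "up"),
                                   list("g1_t1", "B", "1h", "up")), map4)
  expect_false(detect_opposing(s2, "A", "B"))
  s3 <- summarize_gene_de(mk_calls(list("g1_t1", "A", "1h", "up"),
                                   list("g1_t1", "B", "1h", "up"),
                                   list("g1_t2", "A", "1h", "up"),
                                   list("g1_t2", "B", "1h", "down")), map4)
  expect_false(detect_opposing(s3, "A", "B"))
  # DE in only one type is never opposing; nor are disjoint variant sets
  s4 <- summarize_gene_de(mk_calls(list("g1_t1", "A", "1h", "up")), map4)
  expect_false(detect_opposing(s4, "A", "B"))
  s5 <- summarize_gene_de(mk_calls(list("g1_t1", "A", "1h", "up"),
                                   list("g1_t2", "B", "1h", "down")), map4)
  expect_false(detect_opposing(s5, "A", "B"))
  # a transcript DE in both directions within one type blocks the rule
  s6 <- summarize_gene_de(mk_calls(list("g1_t1", "A", "1h", "up"),
                                   list("g1_t1", "A", "4h", "down"),
                                   list("g1_t1", "B", "1h", "down")), map4)
  expect_false(detect_opposing(s6, "A", "B"))
})

test_that("the three retention rules fire as specified", {
  ltm <- c("Glo-LTM-short", "Glo-LTM-long")
  # rule 1: nothing in ARM
  s <- summarize_gene_de(mk_calls(list("g2_t1", "Glo-LTM-long", "1h", "up")),
                         map4)
  c1 <- apply_ltm_filter(s, ltm, "Glo-ARM")
  expect_identical(c1$rule, "absent_in_arm")
  expect_identical(c1$ltm_type, "Glo-LTM-long")
  # rule 2: same transcript, opposite directions
  s <- summarize_gene_de(mk_calls(list("g2_t1", "Glo-LTM-long", "1h", "up"),
                                  list("g2_t1", "Glo-ARM", "1h", "down")),
                         map4)
  expect_identical(apply_ltm_filter(s, ltm, "Glo-ARM")$rule, "opposing")
  # rule 3 vs exclusion: variant A shared with ARM in one LTM type,
  # variant B alone in the other
  s <- summarize_gene_de(mk_calls(list("g1_t1", "Glo-LTM-short", "1h", "down"),
                                  list("g1_t1", "Glo-ARM", "1h", "down"),
                                  list("g1_t2", "Glo-LTM-long", "1h", "down")),
                         map4)
  c3 <- apply_ltm_filter(s, ltm, "Glo-ARM")
  expect_identical(c3$ltm_type, "Glo-LTM-long")
  expect_identical(c3$rule, "splice_variant")
  expect_false("Glo-LTM-short" %in% c3$ltm_type)
  # shared same-direction only: excluded outright
  s <- summarize_gene_de(mk_calls(list("g2_t1", "Glo-LTM-long", "1h", "down"),
                                  list("g2_t1", "Glo-ARM", "1h", "down")),
                         map4)
  expect_identical(nrow(apply_ltm_filter(s, ltm, "Glo-ARM")), 0L)
})

test_that("every retained gene re-evaluates to its recorded rule", {
  b <- simulate_bundle(small_config(seed = 19, n_genes = 400))
  s <- summarize_gene_de(truth_calls(b$ref), b$ref$tx2gene)
  cand <- apply_ltm_filter(s, c("Glo-LTM-short", "Glo-LTM-long"), "Glo-ARM")
  expect_gt(nrow(cand), 0)
  for (i in seq_len(nrow(cand))) {
    sg <- s[s$gene_id == cand$gene_id[i], ]
    arm_tx <- sg$transcript_id[sg$conditioning_type == "Glo-ARM"]
    ltm_tx <- sg$transcript_id[sg$conditioning_type == cand$ltm_type[i]]
    ok <- switch(cand$rule[i],
      absent_in_arm = length(arm_tx) == 0,
      opposing = detect_opposing(sg, cand$ltm_type[i], "Glo-ARM"),
      splice_variant = length(arm_tx) > 0 &&
        !length(intersect(ltm_tx, arm_tx)))
    expect_true(ok, info = paste(cand$gene_id[i], cand$rule[i]))
  }
})

test_that("truth-bypassed calls recover the planted gene roles exactly", {
  b <- simulate_bundle(small_config(seed = 23, n_genes = 600))
  tr <- b$ref$truth
  s <- summarize_gene_de(truth_calls(b$ref), b$ref$tx2gene)
  cand <- apply_ltm_filter(s, c("Glo-LTM-short", "Glo-LTM-long"), "Glo-ARM")
  role <- tapply(tr$role, tr$gene_id, `[`, 1)
  want <- c(ltm_only = "absent_in_arm", opposing = "opposing",
            splice_specific = "splice_variant")
  for (r in names(want)) {
    gs <- names(role)[role == r]
    got <- cand[cand$gene_id %in% gs, ]
    expect_setequal(unique(got$gene_id), gs)
    expect_true(all(got$rule == want[[r]]))
  }
  for (r in c("arm_only", "shared_same_direction", "null"))
    expect_identical(sum(unique(cand$gene_id) %in%
                           names(role)[role == r]), 0L)
})

test_that("venn regions match a brute-force membership tabulation", {
  v <- compute_overlaps(list(s1 = c("A", "B"), s2 = c("B", "C")))
  expect_identical(v$count[v$region == "s1"], 1L)
  expect_identical(v$count[v$region == "s2"], 1L)
  expect_identical(v$count[v$region == "s1&s2"], 1L)
  same <- replicate(3, paste0("g", 1:7), simplify = FALSE)
  names(same) <- c("a", "b", "c")
  v3 <- compute_overlaps(same)
  expect_identical(v3$count[v3$region == "a&b&c"], 7L)
  expect_identical(sum(v3$count), 7L)

  set.seed(61)
  sets <- list(A = sample(paste0("g", 1:120), 50),
               B = sample(paste0("g", 1:120), 60),
               C = sample(paste0("g", 1:120), 70))
  v <- compute_overlaps(sets)
  uni <- unique(unlist(sets))
  for (i in seq_len(nrow(v))) {
    labs <- strsplit(v$region[i], "&", fixed = TRUE)[[1]]
    inside <- Reduce(intersect, sets[labs])
    outside <- unique(unlist(sets[setdiff(names(sets), labs)]))
    expect_identical(v$count[i], length(setdiff(inside, outside)))
  }
  expect_identical(sum(v$count), length(uni))
  # order and duplicates do not matter
  sets2 <- lapply(sets, function(s) sample(rep(s, 2)))
  expect_identical(compute_overlaps(sets2), v)
})

test_that("ortholog maps project genes onto shared groups", {
  orth <- data.frame(gene_id = c("ga1", "gb1", "ga2", "gb2"),
                     ortholog_group = c("OG1", "OG1", "OG2", "OG2"))
  v <- compute_overlaps(list(A = c("ga1", "ga2", "ga3"),
                             B = c("gb1", "gb3")), orth)
  expect_identical(v$count[v$region == "A&B"], 1L)  # OG1
  expect_identical(v$count[v$region == "A"], 2L)    # OG2, ga3
  expect_identical(v$count[v$region == "B"], 1L)    # gb3
})
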