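th <- annotation_thresholds()

hit <- function(q = "t1", s = "P1", db = "proteome", orient = "sense",
                ident = 0.99, qcov = NA_real_, scov = NA_real_) {
  data.frame(query_id = q, subject_id = s, subject_db = db,
             orientation = orient, identity = ident, query_cov = qcov,
             subject_cov = scov, q_start = 0L, q_end = 100L,
             s_start = 0L, s_end = 100L, stringsAsFactors = FALSE)
}

test_that("the sequential sieve classifies canonical cases", {
  expect_identical(classify_transcript(hit(scov = 0.75), th)$structural_class,
                   "sense")
  none <- classify_transcript(hit()[0, ], th, transcript_id = "t9")
  expect_identical(none$structural_class, "unknown")
  both <- classify_transcript(
    rbind(hit(s = "sx", db = "self_transcriptome", orient = "antisense",
              ident = 0.96, qcov = 0.85),
          hit(orient = "antisense", scov = 0.55)),
    th, sense_set = "sx")
  expect_identical(both$structural_class, "antisense")
  expect_true(both$antisense_to_protein && both$antisense_to_sense)
  expect_identical(both$sense_partners, "sx")
  # precedence: qualifying sense evidence wins over antisense evidence
  mixed <- classify_transcript(
    rbind(hit(scov = 0.7), hit(orient = "antisense", scov = 0.9)), th)
  expect_identical(mixed$structural_class, "sense")
  expect_error(classify_transcript(rbind(hit(q = "a"), hit(q = "b")), th),
               "mix")
})

test_that("threshold comparisons are strict at every boundary", {
  at <- function(h) classify_transcript(h, th,
                                        sense_set = "sx")$structural_class
  expect_identical(at(hit(orient = "antisense", scov = 0.50)), "unknown")
  expect_identical(at(hit(scov = 0.60)), "unknown")
  expect_identical(at(hit(s = "sx", db = "self_transcriptome",
                          orient = "antisense", ident = 0.95, qcov = 0.85)),
                   "unknown")
  expect_identical(at(hit(s = "sx", db = "self_transcriptome",
                          orient = "antisense", ident = 0.96, qcov = 0.80)),
                   "unknown")
  expect_identical(at(hit(db = "genome", ident = 0.96, qcov = 0.80)),
                   "unknown")
  expect_identical(at(hit(db = "genome", ident = 0.95, qcov = 0.85)),
                   "unknown")
  # epsilon above each threshold flips the class
  expect_identical(at(hit(scov = 0.600001)), "sense")
  expect_identical(at(hit(orient = "antisense", scov = 0.500001)),
                   "antisense")
  expect_identical(at(hit(db = "nt", ident = 0.950001, qcov = 0.800001)),
                   "lncRNA")
})

test_that("noise-free fixture hits recover every planted class", {
  b <- simulate_bundle(small_config(seed = 4, n_genes = 250))
  ann <- annotate_transcriptome(b$hits, b$ref$tx2gene, th)
  tr <- b$ref$truth
  expect_identical(ann$transcript_id, tr$transcript_id)
  expect_identical(ann$structural_class, unname(class4(tr$class)))
  # decoys sitting exactly on a threshold fall through to unknown,
  # decoys a quarter-margin above qualify
  at_rows <- grepl("_at$", tr$decoy_kind)
  expect_true(all(ann$structural_class[which(at_rows)] == "unknown"))
  ab_rows <- grepl("_above$", tr$decoy_kind)
  expect_identical(ann$structural_class[which(ab_rows)],
                   unname(class4(tr$class[which(ab_rows)])))
  # antisense-to-sense links point at the planted partners
  a2s <- tr$class == "antisense_to_sense" & !tr$is_decoy
  expect_identical(ann$sense_partners[a2s], tr$partner[a2s])
})

test_that("an empty hits table yields all-unknown annotations", {
  map <- data.frame(transcript_id = paste0("t", 1:4),
                    gene_id = paste0("g", 1:4), length = 500L)
  ann <- annotate_transcriptome(hit()[0, ], map, th)
  expect_identical(nrow(ann), 4L)
  expect_true(all(ann$structural_class == "unknown"))
  frac <- table(ann$structural_class) / nrow(ann)
  expect_equal(sum(frac), 1)
  expect_error(annotate_transcriptome(hit(q = "zz"), map, th), "absent")
})

test_that("the vectorised annotator matches the literal rule oracle", {
  for (seed in c(101, 102, 103)) {
    hits <- random_hits(50, seed)
    map <- data.frame(transcript_id = paste0("x", 1:50),
                      gene_id = paste0("g", 1:50), length = 500L)
    ann <- annotate_transcriptome(hits, map, th)
    expect_identical(ann$structural_class, annotate_oracle(hits, map, th))
  }
})

test_that("raising a threshold never grows an earlier class", {
  hits <- random_hits(50, 7)
  map <- data.frame(transcript_id = paste0("x", 1:50),
                    gene_id = paste0("g", 1:50), length = 500L)
  n_sense <- sapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(cv) {
    a <- annotate_transcriptome(hits, map,
                                annotation_thresholds(sense_protein_cov = cv))
    sum(a$structural_class == "sense")
  })
  expect_true(all(diff(n_sense) <= 0))
})

test_that("zone assignment follows interval intersection", {
  expect_setequal(classify_antisense_zones(c(850, 1000), c(200, 800), 1000),
                  "three_prime_utr")
  expect_setequal(classify_antisense_zones(c(0, 1000), c(200, 800), 1000),
                  c("five_prime_utr", "cds", "three_prime_utr"))
  expect_setequal(classify_antisense_zones(c(150, 250), c(200, 800), 1000),
                  c("five_prime_utr", "cds"))
  expect_error(classify_antisense_zones(c(150, 250), c(0, 1200), 1000),
               "CDS")
  expect_error(classify_antisense_zones(c(900, 1100), c(200, 800), 1000),
               "outside")
  # a CDS spanning the whole transcript leaves no UTR zone to hit
  expect_setequal(classify_antisense_zones(c(10, 900), c(0, 1000), 1000),
                  "cds")
})

test_that("zone sets of a partitioned interval union to the whole", {
  set.seed(31)
  for (i in 1:20) {
    len <- sample(500:1500, 1)
    cs <- sample(50:200, 1); ce <- sample((cs + 100):(len - 50), 1)
    a <- sample(0:(len - 10), 1); b <- sample((a + 2):len, 1)
    cut <- sample((a + 1):(b - 1), 1)
    whole <- classify_antisense_zones(c(a, b), c(cs, ce), len)
    parts <- union(classify_antisense_zones(c(a, cut), c(cs, ce), len),
                   classify_antisense_zones(c(cut, b), c(cs, ce), len))
    expect_setequal(parts, whole)
  }
})

test_that("fixture zone sets are recovered through the annotator", {
  b <- simulate_bundle(small_config(seed = 12, n_genes = 300))
  ann <- annotate_transcriptome(b$hits, b$ref$tx2gene, th)
  tr <- b$ref$truth
  # partner protein coverage decides eligibility; where the annotator
  # reports zones they must equal the planted zone set
  a2s <- which(!tr$is_decoy & tr$class == "antisense_to_sense")
  reported <- a2s[nzchar(ann$zone_set[a2s])]
  expect_gt(length(reported), 0)
  for (i in reported) {
    expect_setequal(strsplit(ann$zone_set[i], ",")[[1]],
                    strsplit(tr$zone_set[i], ",")[[1]])
  }
})
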