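test_that("extract_signature picks the 3'-most eligible site", {
  # single site well upstream of the poly(A) run
  s1 <- paste0("AA", "GATC", strrep("T", 22), strrep("A", 15))
  expect_equal(extract_signature(s1, 21), paste0("GATC", strrep("T", 17)))

  # two eligible sites: the downstream one wins
  s2 <- paste0(plant_gatc(120, c(20, 70)), strrep("A", 20))
  expect_equal(extract_signature(s2, 21), substr(s2, 70, 90))

  # no GATC at all
  expect_true(is.na(extract_signature(paste0(filler(80), strrep("A", 20)))))

  # a site too close to the poly(A) run is ineligible
  s3 <- paste0(filler(50), "GATC", strrep("T", 5), strrep("A", 20))
  expect_true(is.na(extract_signature(s3, 21)))

  # sequences without a poly(A) run use their full length (decoys)
  s4 <- plant_gatc(100, 60)
  expect_equal(extract_signature(s4, 21), substr(s4, 60, 80))

  expect_error(extract_signature("GATCNNNN"), "non-ACGT")
  expect_error(extract_signature("GATCAAAA", signature_length = 4), "signature_length")
})

test_that("signature database enumerates and flags occurrences", {
  # three eligible sense sites; 3'-most must be flagged exactly once
  tx <- make_transcriptome(data.frame(
    transcript_id = "T1.1", gene_id = "G1",
    sequence = paste0(plant_gatc(300, c(30, 120, 200)), strrep("A", 20)),
    polya_start = 301L, stringsAsFactors = FALSE))
  db <- build_signature_database(tx, 21)
  sense <- db$records[db$records$strand == "+", ]
  expect_equal(nrow(sense), 3L)
  expect_equal(sum(sense$is_three_prime_most), 1L)
  expect_equal(sense$offset[sense$is_three_prime_most], 199L)  # 0-based
  expect_equal(sense$category[order(sense$offset)], c("2", "2", "1"))
  # GATC is palindromic: each sense site has an antisense twin
  expect_equal(sum(db$records$strand == "-"), 3L)
  expect_true(all(db$records$category[db$records$strand == "-"] == "4"))

  # lookup of an absent signature is empty
  expect_null(db$index[[paste0("GATC", strrep("G", 17))]])
})

test_that("a signature shared by two genes lists both occurrences", {
  shared <- plant_gatc(40, 10, phase = 2)
  tx <- make_transcriptome(data.frame(
    transcript_id = c("A.1", "B.1"), gene_id = c("A", "B"),
    sequence = paste0(c(paste0(filler(60), shared),
                        paste0(shared, filler(60, phase = 1))), strrep("A", 20)),
    polya_start = 101L, stringsAsFactors = FALSE))
  db <- build_signature_database(tx, 21)
  tag <- substr(shared, 10, 30)
  expect_equal(length(db$index[[tag]]), 2L)
  expect_equal(map_and_classify(tag, db)$tag_class, factor("multi", mapping_categories))
})

test_that("class rules: sense/antisense, body/flank, locus-level multi", {
  # annotated end at 200; sequence continues as genomic 3' flank.
  # site positions chosen with distinct offsets mod 3 so the periodic filler
  # gives each site a distinct signature string
  seq1 <- plant_gatc(320, c(50, 151, 240))
  tx <- make_transcriptome(data.frame(
    transcript_id = c("G1.1", "G1.2"), gene_id = "G1",
    sequence = c(seq1, substr(seq1, 1, 100)),
    polya_start = c(201L, 81L), stringsAsFactors = FALSE))
  db <- build_signature_database(tx, 21, flank_bp = 1000)

  tag_at <- function(p) substr(seq1, p, p + 20)
  # 151 is the 3'-most body site of G1.1 -> class 1
  expect_equal(as.character(map_and_classify(tag_at(151), db)$tag_class), "1")
  # 50 is internal in G1.1 BUT the 3'-most body site of isoform G1.2
  # (annotated end 80): same gene, best class wins -> class 1
  m50 <- map_and_classify(tag_at(50), db)
  expect_equal(as.character(m50$tag_class), "1")
  expect_equal(m50$gene_id, "G1")
  # 240 lies beyond the annotated end within the flank window -> class 3
  expect_equal(as.character(map_and_classify(tag_at(240), db)$tag_class), "3")
  # antisense twin of the site at 50: forward span [33, 53] inside the body
  anti_tag <- substr(revcomp_chr(seq1), nchar(seq1) - 53 + 1, nchar(seq1) - 33 + 1)
  m_anti <- map_and_classify(anti_tag, db)
  expect_equal(as.character(m_anti$tag_class), "4")
  # antisense twin of the flank site at 240 -> class 5
  anti_flank <- substr(revcomp_chr(seq1), nchar(seq1) - 243 + 1,
                       nchar(seq1) - 223 + 1)
  expect_equal(as.character(map_and_classify(anti_flank, db)$tag_class), "5")
  # unknown signature -> unmapped; malformed tag -> error
  expect_equal(as.character(map_and_classify(paste0("GATC", strrep("G", 17)),
                                             db)$tag_class), "unmapped")
  expect_error(map_and_classify("TTTT", db), "GATC")
})

test_that("flank window is bounded by flank_bp", {
  seq1 <- plant_gatc(400, 350)
  tx <- make_transcriptome(data.frame(
    transcript_id = "G1.1", gene_id = "G1", sequence = seq1,
    polya_start = 101L, stringsAsFactors = FALSE))
  near <- build_signature_database(tx, 21, flank_bp = 300)
  far <- build_signature_database(tx, 21, flank_bp = 100)
  tag <- substr(seq1, 350, 370)
  expect_equal(as.character(map_and_classify(tag, near)$tag_class), "3")
  expect_equal(as.character(map_and_classify(tag, far)$tag_class), "unmapped")
})

test_that("decoy hits are unannotated; cross-locus hits are multi", {
  shared <- plant_gatc(40, 5, phase = 2)
  tx <- make_transcriptome(
    data.frame(transcript_id = "G1.1", gene_id = "G1",
               sequence = paste0(filler(80), shared, strrep("A", 20)),
               polya_start = 121L, stringsAsFactors = FALSE),
    decoys = data.frame(decoy_id = c("D1", "D2"),
                        sequence = c(plant_gatc(120, 40, phase = 1),
                                     paste0(filler(50, phase = 1), shared)),
                        stringsAsFactors = FALSE))
  db <- build_signature_database(tx, 21)
  d1_tag <- substr(tx$decoys$sequence[1], 40, 60)
  expect_equal(as.character(map_and_classify(d1_tag, db)$tag_class), "unannotated")
  # same signature in a transcript and a decoy: two loci -> multi
  shared_tag <- substr(shared, 5, 25)
  expect_equal(as.character(map_and_classify(shared_tag, db)$tag_class), "multi")
})

test_that("simulated tags round-trip to class 1 and summaries normalise", {
  cfg <- tiny_config(n_genes = 150L, isoform_prob = 0.2, decoy_frac = 0,
                     n_decoys = 0L, seed = 21L)
  tx <- generate_transcriptome(cfg)
  truth <- simulate_expression(tx, cfg)
  libs <- simulate_mpss_libraries(tx, truth, cfg)
  db <- build_signature_database(tx, cfg$signature_length)
  tags <- sort(unique(unlist(lapply(libs, function(l) names(l$counts)))))
  mapped <- map_and_classify(tags, db)
  expect_true(all(mapped$tag_class == "1"))
  expect_true(all(!is.na(mapped$gene_id)))
  # the mapped source is a transcript of the gene that truly emitted the tag
  tt <- true_tag_status(tx, truth)
  expect_equal(mapped$gene_id, tt$gene_id[match(mapped$tag, tt$tag)])

  s <- mapping_summary(mapped)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(unname(s["1"]), 1)
  expect_error(mapping_summary(mapped[0, ]), "degenerate")

  # classification is a pure function of (tag, db)
  expect_identical(mapped, map_and_classify(tags, db))
})
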