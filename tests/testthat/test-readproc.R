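bc_samples <- data.frame(
  id = c("s1", "s2"),
  barcode1 = c("AAAAAAAA", "CCCCCCCC"),
  barcode2 = c("GGGGGGGG", "TTTTTTTT"),
  stringsAsFactors = FALSE)

test_that("demultiplexing tolerates one error per barcode, no more", {
  expect_equal(demultiplex("AAAAAAAA", "GGGGGGGG", bc_samples), "s1")
  expect_equal(demultiplex("AAAAAAAT", "GGGGGGGG", bc_samples), "s1")
  expect_equal(demultiplex("AAAAAAAT", "GGGGGGGA", bc_samples), "s1")
  expect_equal(demultiplex("AAAAAATT", "GGGGGGGG", bc_samples),
               NA_character_)
  expect_equal(demultiplex("CCCCCCCC", "GGGGGGGG", bc_samples),
               NA_character_)   # mixed pair matches no single sample
  close <- data.frame(id = c("a", "b"),
                      barcode1 = c("AAAAAAAA", "AAAAAAAT"),
                      barcode2 = c("GGGGGGGG", "GGGGGGGC"))
  expect_error(demultiplex("AAAAAAAA", "GGGGGGGG", close), "mismatches apart")
})

test_that("generated barcode designs always validate", {
  for (seed in 1:3) {
    set.seed(seed)
    bc <- make_barcodes(12)
    bc$id <- sprintf("s%02d", 1:12)
    expect_true(validate_barcodes(bc))
  }
})

make_pair <- function(smmip, panel, umi = "ACGTAACGTA", off1 = 0, off2 = 0,
                      mm1 = 0) {
  sm <- panel$smmips[panel$smmips$id == smmip, ]
  tg <- panel$targets[panel$targets$id == sm$target_id, ]
  insert <- if (sm$tile == "minus")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tg$seq)))
  else tg$seq
  lig <- sm$lig_arm
  if (mm1 > 0) {
    ch <- substr(lig, 1, 1)
    substr(lig, 1, 1) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  }
  r1 <- paste0(substr(umi, 1, 5), strrep("T", off1), lig,
               substr(insert, 1, 25))
  r2 <- paste0(substr(umi, 6, 10), strrep("T", off2), sm$ext_arm,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(insert, 26, 50)))))
  list(r1 = r1, r2 = r2)
}

test_that("read pairs are assigned within the 5 bp margin, inclusive", {
  id <- .tiny_panel$smmips$id[1]
  p0 <- make_pair(id, .tiny_panel)
  a <- assign_read_pairs(p0$r1, p0$r2, .tiny_panel)
  expect_equal(a$smmip, id)
  expect_equal(a$offset1, 0L)
  expect_equal(a$quality, 42L)
  p5 <- make_pair(id, .tiny_panel, off1 = 5)
  expect_equal(assign_read_pairs(p5$r1, p5$r2, .tiny_panel)$smmip, id)
  p6 <- make_pair(id, .tiny_panel, off1 = 6)
  a6 <- assign_read_pairs(p6$r1, p6$r2, .tiny_panel)
  expect_true(is.na(a6$smmip))
  expect_equal(a6$reason, "no_arm_match")
})

test_that("one arm mismatch is tolerated and lowers the pair quality", {
  id <- .tiny_panel$smmips$id[2]
  pm <- make_pair(id, .tiny_panel, mm1 = 1)
  a <- assign_read_pairs(pm$r1, pm$r2, .tiny_panel)
  expect_equal(a$smmip, id)
  expect_equal(a$quality, 28L)
  # mates from different smMIPs disagree
  other <- make_pair(.tiny_panel$smmips$id[3], .tiny_panel)
  x <- assign_read_pairs(pm$r1, other$r2, .tiny_panel)
  expect_true(is.na(x$smmip))
  expect_equal(x$reason, "mate_disagreement")
})

test_that("quality filter is strict at the threshold and needs proper pairs", {
  expect_true(quality_filter(16, TRUE))
  expect_false(quality_filter(15, TRUE))
  expect_false(quality_filter(40, FALSE))
})

test_that("UMI collapse keeps one molecule per exact tag and target", {
  asg <- data.frame(sample = "s1", smmip = c("p1", "p1", "p1", "p2", "p1"),
                    umi = c("AAAAACCCCC", "AAAAACCCCC", "AAAAACCCCT",
                            "AAAAACCCCC", "NAAAACCCCC"),
                    stringsAsFactors = FALSE)
  out <- deduplicate(asg)
  expect_equal(nrow(out), 3L)                 # exact-key collapse
  expect_equal(attr(out, "dedup_discarded_n"), 1L)
  # idempotent
  expect_equal(nrow(deduplicate(out)), 3L)
  # order-insensitive in totals
  out2 <- deduplicate(asg[rev(seq_len(nrow(asg))), ])
  expect_equal(nrow(out2), 3L)
})

test_that("counting fills zeros and conserves molecules", {
  samples <- data.frame(id = c("s1", "s2"), tissue = "t",
                        condition = "normal", digested = TRUE)
  mol <- data.frame(sample = "s1",
                    smmip = rep(.tiny_panel$smmips$id[1], 3))
  x <- count_molecules(mol, .tiny_panel, samples)
  expect_equal(x$counts[.tiny_panel$smmips$id[1], "s1"], 3L)
  expect_equal(sum(x$counts), 3L)
  expect_equal(sum(x$counts[, "s2"]), 0L)
  expect_equal(ncol(x$counts), 2L)
})

test_that("pipeline counts are invariant to read order and reconcile tallies", {
  s <- tiny_samples(n_tumor = 2, n_normal = 2, n_blood = 0,
                    n_undigested = 1)
  set.seed(19)
  s <- cbind(s, make_barcodes(nrow(s)))
  cfg <- sim_config(s, seed = 19, n_molecules = 60,
                    pcr_duplication_mean = 2, read_error_rate = 0.002)
  sim <- simulate_reads(.tiny_panel, cfg)
  pr <- process_reads(sim$reads$r1, sim$reads$r2, sim$reads$i1, sim$reads$i2,
                      .tiny_panel, s)
  o <- sample(nrow(sim$reads))
  pr2 <- process_reads(sim$reads$r1[o], sim$reads$r2[o], sim$reads$i1[o],
                       sim$reads$i2[o], .tiny_panel, s)
  expect_identical(pr$counts$counts, pr2$counts$counts)
  t <- pr$tally
  expect_equal(t[["demultiplexed"]] + t[["unassigned_barcode"]], t[["total"]])
  expect_lte(t[["unique_molecules"]], t[["total"]])
  expect_equal(t[["assigned"]] + t[["no_arm_match"]] +
                 t[["mate_disagreement"]], t[["demultiplexed"]])
})

test_that("read-level simulation round-trips exactly through the pipeline", {
  s <- tiny_samples(n_tumor = 2, n_normal = 2, n_blood = 1,
                    n_undigested = 1)
  set.seed(23)
  s <- cbind(s, make_barcodes(nrow(s)))
  cfg <- sim_config(s, seed = 23, n_molecules = 80,
                    pcr_duplication_mean = 3, read_error_rate = 0)
  sim <- simulate_reads(.tiny_panel, cfg)
  pr <- process_reads(sim$reads$r1, sim$reads$r2, sim$reads$i1, sim$reads$i2,
                      .tiny_panel, s)
  expect_identical(pr$counts$counts, sim$counts$counts)
})
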