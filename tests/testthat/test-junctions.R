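test_that("build_junction_library assembles 27+27 junctions on the sense
           strand", {
  genome <- toy_three_exon_genome()
  tx <- toy_three_exon_tx()
  alu <- c(300L, 360L)
  lib <- build_junction_library(tx, alu, genome)
  expect_equal(nrow(lib), 3)
  expect_equal(nchar(lib$seq), rep(54L, 3))
  expect_equal(lib$boundary, rep(27L, 3))
  expect_false(any(lib$truncated))
  g <- function(s, e) fetch_sequence(genome, "chrA", s, e)
  up <- lib[lib$role == "UPSTREAM", "seq"]
  dn <- lib[lib$role == "DOWNSTREAM", "seq"]
  sk <- lib[lib$role == "SKIPPING", "seq"]
  expect_equal(up, paste0(g(193, 220), g(300, 327)))
  expect_equal(dn, paste0(g(333, 360), g(460, 487)))
  expect_equal(sk, paste0(g(193, 220), g(460, 487)))
})

test_that("short exons truncate junction segments with a flag", {
  genome <- toy_three_exon_genome()
  tx <- toy_three_exon_tx()
  lib <- build_junction_library(tx, c(300L, 320L), genome)  # 20-bp exon
  up <- lib[lib$role == "UPSTREAM", ]
  dn <- lib[lib$role == "DOWNSTREAM", ]
  expect_equal(nchar(up$seq), 27 + 20)
  expect_equal(nchar(dn$seq), 20 + 27)
  expect_true(up$truncated && dn$truncated)
  expect_equal(dn$boundary, 20L)
  expect_false(lib[lib$role == "SKIPPING", "truncated"])
})

test_that("minus-strand junctions are built in transcript orientation", {
  genome <- toy_three_exon_genome()
  txm <- transcript_model("txM", "gA", "chrA", "-",
                          toy_three_exon_tx()$exons,
                          cds_start = 0L, cds_end = 520L)
  lib <- build_junction_library(txm, c(300L, 360L), genome)
  rc <- function(s, e) fetch_sequence(genome, "chrA", s, e, "-")
  # 5' flank of a minus-strand transcript is the genomically-downstream exon
  expect_equal(lib[lib$role == "UPSTREAM", "seq"],
               paste0(rc(460, 487), rc(333, 360)))
  expect_equal(lib[lib$role == "SKIPPING", "seq"],
               paste0(rc(460, 487), rc(193, 220)))
})

test_that("match_reads counts unique hits, drops multi-mapped and
           mismatch-heavy reads", {
  genome <- toy_three_exon_genome()
  tx <- toy_three_exon_tx()
  lib <- build_junction_library(tx, c(300L, 360L), genome)
  up <- lib$seq[lib$role == "UPSTREAM"]
  read_exact <- substr(up, 1, 30)
  read_2mm <- read_exact
  substr(read_2mm, 2, 2) <- if (substr(read_2mm, 2, 2) == "A") "C" else "A"
  substr(read_2mm, 5, 5) <- if (substr(read_2mm, 5, 5) == "A") "C" else "A"
  read_3mm <- read_2mm
  substr(read_3mm, 9, 9) <- if (substr(read_3mm, 9, 9) == "A") "C" else "A"
  out <- match_reads(c(read_exact, read_2mm, read_3mm, "ACGT"), lib,
                     read_prefix_length = 30)
  expect_equal(out$UJC, 2L)
  expect_equal(out$DJC + out$SJC, 0L)
  expect_equal(attr(out, "n_unmapped"), 1L)
  expect_equal(attr(out, "n_short"), 1L)

  # a read matching two junctions equally well is discarded as multi-mapped:
  # duplicate the UPSTREAM junction under a second exon id
  dup <- lib[lib$role == "UPSTREAM", ]
  dup$exon_id <- "chrA:900-960:+"
  lib_dup <- combine_junction_libraries(lib, dup)
  out2 <- match_reads(read_exact, lib_dup, read_prefix_length = 30)
  expect_equal(attr(out2, "n_multi"), 1L)
  expect_equal(sum(out2[, c("UJC", "DJC", "SJC")]), 0L)
})

test_that("match_reads with zero mismatches equals exact substring search", {
  sim <- shared_sim()
  lib <- sim_junction_library(sim)
  cts <- jc_table(jc_row(sim$truth$exon_id[1], "s", 8L, 6L, 7L),
                  jc_row(sim$truth$exon_id[2], "s", 5L, 9L, 4L))
  reads <- simulate_junction_reads(cts, lib, read_length = 50, seed = 17)$s
  got <- match_reads(reads, lib, read_prefix_length = 50, max_mismatches = 0)
  for (r in reads) {
    n_hit <- sum(vapply(lib$seq, function(j) {
      length(oracle_substring_positions(r, j)) > 0
    }, logical(1)))
    expect_gte(n_hit, 1)
  }
  m <- merge(cts, got, by = "exon_id", suffixes = c("_true", "_got"))
  expect_equal(m$UJC_got, m$UJC_true)
  expect_equal(m$DJC_got, m$DJC_true)
  expect_equal(m$SJC_got, m$SJC_true)
})

test_that("compute_psi implements the averaged-junction estimator", {
  p <- compute_psi(jc_table(jc_row("e", "s", 10L, 10L, 10L),
                            jc_row("e2", "s", 20L, 0L, 0L),
                            jc_row("e3", "s", 7L, 9L, 4L),
                            jc_row("e4", "s", 0L, 0L, 0L)))
  expect_equal(p$psi, c(0.5, 1.0, 8 / 12, NA))
  expect_equal(p$covered, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(compute_psi(jc_row("e", "s", -1L, 0L, 0L)), "non-negative")
})

test_that("psi is scale-invariant and bounded", {
  set.seed(31)
  for (i in 1:20) {
    u <- sample(0:50, 1); d <- sample(0:50, 1); s <- sample(0:50, 1)
    k <- sample(2:9, 1)
    p1 <- compute_psi(jc_row("e", "s", u, d, s))$psi
    p2 <- compute_psi(jc_row("e", "s", k * u, k * d, k * s))$psi
    expect_equal(p1, p2)
    if (!is.na(p1)) expect_true(p1 >= 0 && p1 <= 1)
  }
})

test_that("psi estimates are unbiased under binomial junction sampling", {
  sim <- shared_sim()
  ex1 <- sim$truth$exon_id[1]
  psi_true <- sim$truth$psi_tissue1[1]
  est <- vapply(1:40, function(s) {
    cts <- simulate_junction_counts(sim, depth = 500, assay = "rna", seed = s)
    p <- compute_psi(cts)
    p$psi[p$exon_id == ex1 & p$sample == "tissue1"]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - psi_true), 3 * se)
})

test_that("select_high_inclusion applies the inclusive psi and coverage
           gates", {
  p <- compute_psi(jc_table(
    jc_row("hit", "t1", 10L, 10L, 40L),    # psi ~0.2 here
    jc_row("hit", "t2", 33L, 33L, 67L),    # psi = 0.33 exactly, covered
    jc_row("low", "t1", 4L, 4L, 2L),       # psi 0.67 but max junction < 10
    jc_row("none", "t1", 0L, 0L, 0L)))     # undefined everywhere
  expect_equal(select_high_inclusion(p), "hit")
})

test_that("differential splicing calls require effect size and FDR", {
  # identical counts: delta 0, never called
  cts <- jc_table(jc_row("e", "a", 90L, 90L, 10L),
                  jc_row("e", "b", 90L, 90L, 10L))
  r <- differential_splicing(cts)
  expect_equal(r$tests$delta_psi, 0)
  expect_equal(r$called, character(0))

  # (I,S) = (90,10) vs (40,60): delta 0.5, Fisher p as the oracle computes
  cts2 <- jc_table(jc_row("e", "a", 90L, 90L, 10L),
                   jc_row("e", "b", 40L, 40L, 60L))
  r2 <- differential_splicing(cts2)
  expect_equal(r2$tests$delta_psi, 0.5)
  expect_equal(r2$tests$p, oracle_fisher_p(90, 10, 40, 60), tolerance = 1e-9)
  expect_equal(r2$called, "e")

  # tiny delta with overwhelming depth: significant but below the 10% gate
  cts3 <- jc_table(jc_row("e", "a", 50000L, 50000L, 50000L),
                   jc_row("e", "b", 45000L, 45000L, 55000L))
  r3 <- differential_splicing(cts3)
  expect_lt(r3$tests$q, 0.10)
  expect_lt(abs(r3$tests$delta_psi), 0.10)
  expect_equal(r3$called, character(0))

  expect_error(differential_splicing(jc_row("e", "a", 1L, 1L, 1L)), "2 samples")
})

test_that("combine_exon_lists is a deduplicating union", {
  expect_length(combine_exon_lists(c("a", "b", "c"), c("d", "e", "f", "g")), 7)
  expect_equal(combine_exon_lists(c("a", "b"), c("a", "b")), c("a", "b"))
  set.seed(13)
  for (i in 1:10) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    expect_length(combine_exon_lists(a, b),
                  length(a) + length(b) - length(intersect(a, b)))
  }
})
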