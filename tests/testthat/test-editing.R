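test_that("filter_editing_sites applies the edited-evidence and
           group-coverage rules", {
  e <- rbind(rep(4L, 9),                       # max edited 4: removed
             c(5L, rep(0L, 8)),                # one library at 5: kept
             c(0L, 0L, 0L, rep(6L, 6)),        # no EV coverage: removed
             rep(6L, 9))
  u <- rbind(rep(10L, 9),
             rep(10L, 9),
             c(0L, 0L, 0L, rep(10L, 6)),
             rep(10L, 9))
  x <- toy_editing_counts(e, u)
  f <- filter_editing_sites(x)
  expect_equal(nrow(f$e), 2)
  expect_equal(f$sites$site_id, c("chrZ:20:+", "chrZ:40:+"))
})

test_that("merged_editing_levels pools replicates", {
  e <- rbind(c(5L, 5L, 5L, 3L, 7L, 2L, 0L, 0L, 0L))
  u <- rbind(c(5L, 5L, 5L, 10L, 18L, 10L, 10L, 10L, 10L))
  x <- toy_editing_counts(e, u)
  expect_equal(merged_editing_levels(x, "EV")$level, 0.5)
  expect_equal(merged_editing_levels(x, "EV")$total, 30)
  expect_equal(merged_editing_levels(x, "SHORT")$level, 12 / 50)
  expect_equal(merged_editing_levels(x, "LONG")$level, 0)
  # merged level equals the count-weighted mean of replicate levels
  tot <- c(13, 25, 12)
  lev <- c(3, 7, 2) / tot
  expect_equal(merged_editing_levels(x, "SHORT")$level,
               sum(lev * tot) / sum(tot))
})

test_that("global_editing_comparison gates on coverage and uses the paired
           Wilcoxon test", {
  set.seed(5)
  n <- 10
  base <- round(runif(n, 0.2, 0.6), 2)
  # SHORT gains i extra edited reads at site i: distinct positive
  # level differences i/100, so the exact signed-rank null applies
  mk <- function() {
    e <- matrix(0L, n, 9); u <- matrix(0L, n, 9)
    grp <- c(rep("EV", 3), rep("SHORT", 3), rep("LONG", 3))
    for (j in 1:9) {
      e[, j] <- as.integer(round(100 * base)) +
        if (grp[j] == "SHORT") seq_len(n) else 0L
      u[, j] <- 100L - e[, j]
    }
    toy_editing_counts(e, u)
  }
  x <- mk()
  # identical groups -> all differences zero -> p = 1
  same <- global_editing_comparison(x, "EV", "LONG")
  expect_equal(same$p, 1)
  # constant +0.1 shift: all-positive differences, exact enumeration oracle
  r <- global_editing_comparison(x, "SHORT", "EV")
  d <- merged_editing_levels(x, "SHORT")$level -
    merged_editing_levels(x, "EV")$level
  expect_equal(r$p, oracle_signed_rank_p(d), tolerance = 1e-10)
  expect_equal(r$n_sites, n)
  # coverage gate: sites below 50 total in one group are excluded
  low <- x
  low$u[1, 1:3] <- 0L
  low$e[1, 1:3] <- 1L
  expect_equal(global_editing_comparison(low, "SHORT", "EV")$n_sites, n - 1)
  one <- toy_editing_counts(matrix(20L, 1, 9), matrix(20L, 1, 9))
  expect_error(global_editing_comparison(one, "EV", "SHORT"),
               "fewer than 2")
})

test_that("differential_editing combines per-replicate Fisher tests", {
  # identical counts in treatment and control: all p = 1, not differential
  e <- rbind(rep(10L, 9), c(rep(5L, 3), rep(30L, 3), rep(5L, 3)))
  u <- rbind(rep(40L, 9), c(rep(95L, 3), rep(70L, 3), rep(95L, 3)))
  x <- toy_editing_counts(e, u)
  r <- differential_editing(x, "SHORT")
  null_row <- r[r$site_id == "chrZ:10:+", ]
  expect_equal(null_row$p_rep1, 1)
  expect_equal(null_row$p_combined, 1)
  expect_false(null_row$differential)
  # (30,70) vs EV (5,95) in all three replicates: oracle-combined call
  eff <- r[r$site_id == "chrZ:20:+", ]
  p1 <- oracle_fisher_p(30, 70, 5, 95)
  expect_equal(eff$p_rep1, p1, tolerance = 1e-9)
  expect_equal(eff$p_combined, oracle_uniform_product_tail(rep(p1, 3)),
               tolerance = 1e-9)
  expect_true(eff$differential)
})

test_that("zero-coverage replicate pairs contribute p = 1 with a flag", {
  e <- rbind(c(0L, 6L, 6L, 30L, 30L, 30L, 6L, 6L, 6L))
  u <- rbind(c(0L, 40L, 40L, 70L, 70L, 70L, 40L, 40L, 40L))
  x <- toy_editing_counts(e, u)
  r <- differential_editing(x, "SHORT")
  expect_equal(r$p_rep1, 1)
  expect_equal(r$n_zero_coverage, 1L)
  # pooled-EV pairing still uses the two covered EV replicates
  r2 <- differential_editing(x, "SHORT", pairing = "pooled")
  expect_lt(r2$p_rep1, 1)
})

test_that("classify_specificity implements the confidence rules
           symmetrically", {
  mk <- function(q) data.frame(site_id = paste0("s", seq_along(q)), q = q)
  qs <- c(0.05, 0.05, 0.05, 0.5, 0.95)
  ql <- c(0.05, 0.95, 0.50, 0.05, 0.05)
  r <- classify_specificity(mk(qs), mk(ql))
  expect_equal(r$classification,
               c("COMMON", "HIGH_CONF_SHORT", "LOW_CONF_SHORT",
                 "LOW_CONF_LONG", "HIGH_CONF_LONG"))
  # swapping the isoform labels mirrors the classification
  r2 <- classify_specificity(mk(ql), mk(qs))
  mirror <- sub("SHORT", "@", r$classification)
  mirror <- sub("LONG", "SHORT", mirror)
  mirror <- sub("@", "LONG", mirror)
  expect_equal(r2$classification, mirror)
  # missing q on one side: site skipped with a tally
  r3 <- classify_specificity(mk(c(0.05, 0.05)), mk(0.05)[1, , drop = FALSE])
  expect_equal(nrow(r3), 1)
  expect_equal(attr(r3, "n_skipped"), 1L)
})

test_that("planted editing effects are recovered and the null is
           controlled", {
  cfg <- sim_config(seed = 3, editing = list(n_sites = 150L,
                                             coverage_mean = 200,
                                             coverage_size = 10))
  simed <- simulate_editing_counts(cfg, seed = 3)
  f <- filter_editing_sites(simed$counts)
  ds <- differential_editing(f, "SHORT")
  dl <- differential_editing(f, "LONG")
  tt <- merge(merge(ds[, c("site_id", "q")], dl[, c("site_id", "q")],
                    by = "site_id", suffixes = c("_s", "_l")),
              simed$truth, by = "site_id")
  sens_short <- mean(tt$q_s[tt$class %in% c("common", "short_specific")] <= 0.1)
  sens_long <- mean(tt$q_l[tt$class %in% c("common", "long_specific")] <= 0.1)
  expect_gte(sens_short, 0.8)
  expect_gte(sens_long, 0.8)
  # null sites rarely called
  fp <- mean(tt$q_s[tt$class == "null"] <= 0.1)
  expect_lte(fp, 0.15)
})
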